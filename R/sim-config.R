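#' Configuration for the synthetic study generator
#'
#' Defines every knob of the simulated diapause-induction experiment: the
#' reference complement (scaffolds, gene models, proteins, pathways), the
#' contig-set artefact rates (redundancy, fragmentation, UTR-only pieces,
#' chimeras, intergenic slices) and the 2x2 photoperiod-by-blood-meal
#' sequencing design (16 libraries = 2 photoperiods x 2 blood-meal states x
#' 4 replicates; read length 101 bp, mean insert 203 bp). The seed fully
#' determines every generated artefact.
#'
#' @param seed Integer RNG seed; all generator outputs are a pure function
#'   of the configuration including this seed.
#' @param n_scaffolds Number of genomic scaffolds.
#' @param n_genes Number of gene models.
#' @param gene_length_range Coding-sequence length range in bp (rounded to
#'   codons internally).
#' @param utr_length_range 5'/3' UTR length range in bp.
#' @param intron_count_range Introns per gene (inclusive range).
#' @param intron_length_range Intron length range in bp.
#' @param n_stages Number of life stages contributing contig sets.
#' @param contig_redundancy_rate Probability a base contig receives a
#'   (near-)duplicate copy (>= 99\% identity).
#' @param fragment_rate Probability a transcript is emitted as two
#'   overlapping fragments instead of one full-length contig.
#' @param utr_contig_rate Probability a gene/stage also emits a UTR-only
#'   fragment.
#' @param chimera_rate Probability a base contig spawns a two-gene chimera.
#' @param intergenic_rate Fraction of base contigs added as intergenic
#'   scaffold slices (exercises the unannotated-genomic category).
#' @param n_libraries Number of sequencing libraries; must be 4 x replicates
#'   of the 2x2 design (default 16).
#' @param mean_library_size Mean read pairs per library.
#' @param nb_dispersion Negative-binomial dispersion of per-gene counts.
#' @param effect_log2fc Named vector of planted log2 effect sizes for
#'   `photoperiod`, `bloodmeal`, `interaction`.
#' @param frac_de Named vector: fraction of genes carrying each effect.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment (insert) size model in bp.
#' @param contamination_rate Fraction of pairs carrying vector/adapter
#'   contamination.
#' @param quality_decay List of phred-decay parameters: `q_start`, `q_end`
#'   (plateau and tail phred), `midpoint` (fractional read position of the
#'   logistic drop), `steepness`, `sd` (per-read offset), `base_sd`
#'   (per-base jitter).
#' @param protein_reference_fraction Fraction of genes with a protein in
#'   the reference set (the remainder emulate lineage-specific genes only
#'   discoverable through the genome path).
#' @param n_pathways,pathway_size_range Pathway-map shape.
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 6L,
                       n_genes = 200L,
                       gene_length_range = c(900L, 2400L),
                       utr_length_range = c(120L, 300L),
                       intron_count_range = c(0L, 2L),
                       intron_length_range = c(50L, 500L),
                       n_stages = 4L,
                       contig_redundancy_rate = 0.3,
                       fragment_rate = 0.4,
                       utr_contig_rate = 0.15,
                       chimera_rate = 0.05,
                       intergenic_rate = 0.05,
                       n_libraries = 16L,
                       mean_library_size = 20000L,
                       nb_dispersion = 0.1,
                       effect_log2fc = c(photoperiod = 2, bloodmeal = 2,
                                         interaction = 2),
                       frac_de = c(photoperiod = 0.10, bloodmeal = 0.10,
                                   interaction = 0.05),
                       read_length = 101L,
                       insert_mean = 203L,
                       insert_sd = 20,
                       contamination_rate = 0.02,
                       quality_decay = list(q_start = 38, q_end = 22,
                                            midpoint = 0.85, steepness = 18,
                                            sd = 2, base_sd = 1),
                       protein_reference_fraction = 0.85,
                       n_pathways = 15L,
                       pathway_size_range = c(8L, 20L)) {
  cfg <- list(seed = check_count(seed, "seed"),
              n_scaffolds = check_count(n_scaffolds, "n_scaffolds", 1L),
              n_genes = check_count(n_genes, "n_genes"),
              gene_length_range = gene_length_range,
              utr_length_range = utr_length_range,
              intron_count_range = intron_count_range,
              intron_length_range = intron_length_range,
              n_stages = check_count(n_stages, "n_stages", 1L),
              contig_redundancy_rate =
                check_fraction(contig_redundancy_rate, "contig_redundancy_rate"),
              fragment_rate = check_fraction(fragment_rate, "fragment_rate"),
              utr_contig_rate = check_fraction(utr_contig_rate, "utr_contig_rate"),
              chimera_rate = check_fraction(chimera_rate, "chimera_rate"),
              intergenic_rate = check_fraction(intergenic_rate, "intergenic_rate"),
              n_libraries = check_count(n_libraries, "n_libraries", 4L),
              mean_library_size = check_count(mean_library_size,
                                              "mean_library_size"),
              nb_dispersion = nb_dispersion,
              effect_log2fc = effect_log2fc,
              frac_de = frac_de,
              read_length = check_count(read_length, "read_length", 20L),
              insert_mean = check_count(insert_mean, "insert_mean", 1L),
              insert_sd = check_positive(insert_sd, "insert_sd"),
              contamination_rate = check_fraction(contamination_rate,
                                                  "contamination_rate"),
              quality_decay = quality_decay,
              protein_reference_fraction =
                check_fraction(protein_reference_fraction,
                               "protein_reference_fraction"),
              n_pathways = check_count(n_pathways, "n_pathways"),
              pathway_size_range = pathway_size_range)
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0) {
    stop("invalid `nb_dispersion`: must be >= 0", call. = FALSE)
  }
  for (nm in c("photoperiod", "bloodmeal", "interaction")) {
    if (!nm %in% names(cfg$effect_log2fc)) {
      stop("invalid `effect_log2fc`: missing entry for ", nm, call. = FALSE)
    }
    if (!nm %in% names(cfg$frac_de)) {
      stop("invalid `frac_de`: missing entry for ", nm, call. = FALSE)
    }
  }
  check_fraction(cfg$frac_de, "frac_de")
  if (cfg$n_libraries %% 4L != 0L) {
    stop("invalid `n_libraries`: must be a multiple of 4 ",
         "(2 photoperiods x 2 blood-meal states x replicates)", call. = FALSE)
  }
  for (nm in c("gene_length_range", "utr_length_range", "intron_count_range",
               "intron_length_range", "pathway_size_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || any(r < 0) || r[1] > r[2]) {
      stop("invalid `", nm, "`: must be a non-decreasing length-2 range",
           call. = FALSE)
    }
  }
  cfg$stage_names <- c("adult", "oocyte", "embryo", "pharate_larva",
                       paste0("stage", seq_len(max(0, n_stages - 4))))[
                         seq_len(cfg$n_stages)]
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_genes, "genes on",
      x$n_scaffolds, "scaffolds |", x$n_libraries, "libraries x",
      x$mean_library_size, "pairs | dispersion", x$nb_dispersion, "\n")
  invisible(x)
}
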