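# End-to-end orchestration: synthetic inputs -> cleaning -> digital
# normalization -> consolidation -> hybrid re-assembly/annotation ->
# quantification -> differential expression -> pathway enrichment, with a
# machine-readable manifest of parameters, realized data-dependent
# thresholds and output digests.

required_inputs <- c("scaffolds", "proteins", "gene_models", "pathways",
                     "vector_db", "adapters")

#' Run the full desk-scale pipeline
#'
#' Generates (or loads) the synthetic study inputs, then executes read
#' cleaning (vector/adapter screening, quality trimming), digital
#' normalization (recorded as the assembly input; quantification uses the
#' cleaned, un-normalized pairs), within-stage contig consolidation, the
#' protein- and genome-reference-guided re-assembly, unigene
#' quantification, the four pairwise DE contrasts plus the interaction
#' test, MDS, and length-bias-corrected pathway enrichment for the two
#' photoperiod contrasts. Every stage's parameters and realized
#' data-dependent thresholds are recorded in a JSON manifest.
#'
#' @param sim A [sim_config()] defining the study (also carries the seed).
#' @param outdir Output directory.
#' @param input_dir Optional directory with pre-generated inputs (the
#'   files written by [write_truth()] plus a `reads/` subdirectory with
#'   the FASTQ files, `design.tsv`); referenced files are checked before
#'   any stage runs.
#' @param screen,trim,diginorm Stage policies.
#' @param enrichment_resamples Resamples for the enrichment stage.
#' @param keep_fastq Keep intermediate cleaned FASTQ tibbles in the
#'   returned object (default FALSE to save memory).
#' @return A `tx_pipeline` list with the truth set, per-stage results and
#'   the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(sim = sim_config(), outdir = tempfile("tx_run"),
                         input_dir = NULL,
                         screen = screen_policy(), trim = trim_policy(),
                         diginorm = diginorm_policy(),
                         enrichment_resamples = 20000L,
                         keep_fastq = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = sim$seed,
                   parameters = list(
                     screen = unclass(screen), trim = unclass(trim),
                     diginorm = unclass(diginorm),
                     enrichment_resamples = enrichment_resamples),
                   stages = list())
  t0 <- Sys.time()

  # ---- inputs ----
  truth <- generate_references(sim)
  if (is.null(input_dir)) {
    input_dir <- file.path(outdir, "inputs")
    write_truth(truth, input_dir)
    reads <- generate_reads(truth, sim, file.path(input_dir, "reads"))
    contig_sets <- generate_contig_sets(truth, sim)
    contig_paths <- vapply(split(contig_sets$contigs,
                                 contig_sets$contigs$stage),
                           function(cs) {
                             p <- file.path(input_dir,
                                            paste0("contigs_", cs$stage[1],
                                                   ".fasta"))
                             write_fasta(setNames(cs$seq, cs$contig_id), p)
                             p
                           }, character(1))
  } else {
    contig_paths <- list.files(input_dir, "^contigs_.*\\.fasta$",
                               full.names = TRUE)
  }
  paths <- c(setNames(file.path(input_dir,
                                c("scaffolds.fasta", "proteins.fasta",
                                  "gene_models.tsv", "pathways.tsv",
                                  "vector.fasta", "adapters.fasta")),
                      required_inputs),
             design = file.path(input_dir, "reads", "design.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing pipeline input: ", missing[1], call. = FALSE)
  }
  scaffolds <- read_fasta(paths["scaffolds"])
  proteins <- read_fasta(paths["proteins"])
  gene_models <- read_gene_models(paths["gene_models"])
  pathway_map <- read_pathways(paths["pathways"])
  vec_db <- read_fasta(paths["vector_db"])
  adapters <- read_fasta(paths["adapters"])
  design <- read_design(paths["design"])
  fastq1 <- file.path(input_dir, "reads",
                      paste0(design$library_id, "_1.fastq"))
  fastq2 <- file.path(input_dir, "reads",
                      paste0(design$library_id, "_2.fastq"))
  missing_fq <- c(fastq1, fastq2)[!file.exists(c(fastq1, fastq2))]
  if (length(missing_fq) > 0) {
    stop("missing pipeline input: ", missing_fq[1], call. = FALSE)
  }
  manifest$stages$inputs <- list(files = as.list(paths),
                                 n_genes = nrow(gene_models),
                                 n_scaffolds = length(scaffolds))

  # ---- cleaning + digital normalization ----
  cleaned <- list(); clean_stats <- list()
  for (i in seq_along(design$library_id)) {
    lib <- design$library_id[i]
    pairs <- read_fastq_pairs(fastq1[i], fastq2[i])
    sc <- screen_contaminants(pairs, vec_db, adapters, screen)
    qt <- quality_trim_pairs(sc$retained, trim)
    dn <- digital_normalize(qt$pairs, diginorm)
    cleaned[[lib]] <- qt$pairs
    clean_stats[[lib]] <- tibble::tibble(
      library_id = lib, raw_pairs = nrow(pairs),
      screened_out = nrow(pairs) - nrow(sc$retained),
      trim_dropped = qt$n_dropped, clean_pairs = nrow(qt$pairs),
      diginorm_pairs = nrow(dn))
  }
  clean_stats <- dplyr::bind_rows(clean_stats)
  manifest$stages$cleaning <- as.list(colSums(clean_stats[-1]))

  # ---- consolidation (per-stage de-duplication) ----
  all_contigs <- purrr::map_dfr(contig_paths, function(p) {
    stage <- sub("^contigs_(.*)\\.fasta$", "\\1", basename(p))
    s <- read_fasta(p)
    tibble::tibble(contig_id = names(s), stage = stage, seq = unname(s))
  })
  reps <- purrr::map_dfr(split(all_contigs, all_contigs$stage),
                         function(cs) cluster_within_stage(cs)$representatives)
  manifest$stages$consolidation <- list(input_contigs = nrow(all_contigs),
                                        representatives = nrow(reps))

  # ---- hybrid re-assembly / annotation ----
  prot <- protein_reassemble(reps, proteins)
  retained_members <- prot$members$member_id[
    prot$members$contig_id %in% prot$retained$contig_id]
  # chimeric contigs are discarded outright, not passed to the genome path
  chimeric_members <- prot$members$member_id[prot$members$contig_id %in%
    prot$discarded$contig_id[prot$discarded$reason == "chimeric"]]
  genome_input <- reps[!reps$contig_id %in%
                         c(retained_members, chimeric_members), ,
                       drop = FALSE]
  gen <- genome_reassemble(genome_input, scaffolds, gene_models)
  final <- build_final_assembly(prot$retained, gen$retained,
                                reference_gene_ids = gene_models$gene_id)
  unigenes <- final$unigenes
  write_fasta(setNames(unigenes$seq, unigenes$unigene_id),
              file.path(outdir, "unigenes.fasta"))
  readr::write_tsv(unigenes[, c("unigene_id", "category", "reference_id",
                                "annotation_identity")],
                   file.path(outdir, "annotation.tsv"), progress = FALSE)
  assembly_stats <- dplyr::bind_rows(
    dplyr::mutate(contig_stats(all_contigs$seq), set = "input_contigs"),
    dplyr::mutate(contig_stats(prot$retained$seq), set = "protein_path"),
    if (nrow(gen$retained) > 0)
      dplyr::mutate(contig_stats(gen$retained$seq), set = "genome_path"),
    dplyr::mutate(contig_stats(unigenes$seq), set = "final_assembly"))
  readr::write_tsv(assembly_stats, file.path(outdir, "assembly_stats.tsv"),
                   progress = FALSE)
  manifest$stages$reassembly <- list(
    protein_retained = nrow(prot$retained),
    genome_retained = nrow(gen$retained),
    genome_identity_cutoffs = as.list(gen$identity_cutoffs),
    gene_models_protein = final$accounting$n_protein,
    gene_models_genome = final$accounting$n_genome,
    gene_models_union = final$accounting$n_union,
    gene_models_intersection = final$accounting$n_intersection,
    union_fraction_pct = final$accounting$union_fraction_pct)

  # ---- quantification (unigene-level, collapsed by reference) ----
  quant <- quantify_libraries(cleaned, unigenes,
                              insert_mean = sim$insert_mean)
  gene_of <- ifelse(unigenes$category == "unannotated_genomic",
                    unigenes$unigene_id, unigenes$reference_id)
  counts <- rowsum(quant$counts, group = gene_of)
  readr::write_tsv(tibble::tibble(unigene_id = rownames(counts),
                                  tibble::as_tibble(counts)),
                   file.path(outdir, "counts.tsv"), progress = FALSE)
  manifest$stages$quantification <- list(
    mapped_fraction = mean(quant$summary$fraction),
    total_pairs = sum(quant$summary$total_pairs),
    mapped_pairs = sum(quant$summary$mapped_pairs))

  # ---- differential expression ----
  norm_factors <- tmm_factors(counts)
  eff_lib <- colSums(counts) * norm_factors
  filt <- filter_low(counts, eff_lib)
  disp <- estimate_dispersion(filt$counts, design, lib_sizes = eff_lib)
  contrasts <- list(bloodmeal_LD = c("LD.BM", "LD.NB"),
                    bloodmeal_SD = c("SD.BM", "SD.NB"),
                    photoperiod_NB = c("SD.NB", "LD.NB"),
                    photoperiod_BM = c("SD.BM", "LD.BM"))
  de <- lapply(contrasts, function(ct)
    nb_pairwise_test(filt$counts, design, ct, dispersion = disp))
  for (nm in names(de)) {
    readr::write_tsv(de[[nm]]$table,
                     file.path(outdir, paste0("de_", nm, ".tsv")),
                     progress = FALSE)
  }
  inter <- interaction_test(filt$counts, design, dispersion = disp)
  readr::write_tsv(inter$table, file.path(outdir, "de_interaction.tsv"),
                   progress = FALSE)
  mds <- mds_coordinates(filt$counts, design, lib_sizes = eff_lib)
  manifest$stages$diffexpr <- c(
    list(n_filtered = filt$n_kept, common_dispersion = disp$common),
    setNames(lapply(de, function(d) sum(d$table$is_de)),
             paste0("n_de_", names(de))))

  # ---- pathway enrichment (photoperiod contrasts) ----
  gene_len <- vapply(split(nchar(unigenes$seq), gene_of), max, numeric(1))
  enrich <- list()
  for (nm in c("photoperiod_NB", "photoperiod_BM")) {
    det <- tibble::tibble(gene_id = de[[nm]]$table$unigene_id,
                          is_de = de[[nm]]$table$is_de)
    enrich[[nm]] <- length_bias_enrichment(
      det, gene_len, pathway_map, n_resamples = enrichment_resamples,
      seed = sim$seed + 7000L)
    readr::write_tsv(enrich[[nm]],
                     file.path(outdir, paste0("enrichment_", nm, ".tsv")),
                     progress = FALSE)
  }
  manifest$stages$enrichment <- lapply(enrich, function(e)
    list(n_enriched = sum(e$enriched),
         enriched = as.list(e$pathway_id[e$enriched])))

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out_files <- list.files(outdir, "\\.(tsv|fasta)$", full.names = TRUE)
  manifest$output_digests <- as.list(tools::md5sum(out_files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(truth = truth, design = design,
                 clean_stats = clean_stats,
                 cleaned = if (keep_fastq) cleaned else NULL,
                 representatives = reps, protein = prot, genome = gen,
                 assembly = final, assembly_stats = assembly_stats,
                 quant = quant, counts = counts, filtered = filt,
                 dispersion = disp, de = de, interaction = inter,
                 mds = mds, enrichment = enrich, manifest = manifest,
                 outdir = outdir),
            class = "tx_pipeline")
}

#' @export
print.tx_pipeline <- function(x, ...) {
  cat("<tx_pipeline>", nrow(x$assembly$unigenes), "unigenes;",
      x$manifest$stages$quantification$mapped_pairs, "mapped pairs;",
      paste(names(x$de), vapply(x$de, function(d) sum(d$table$is_de),
                                numeric(1)), collapse = ", "),
      "DE genes\n")
  invisible(x)
}
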