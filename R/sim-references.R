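# Synthetic reference complement: scaffolds with spliced gene models,
# in-frame protein translations, transcripts with UTRs, planted expression
# truth and a pathway map.

CELL_LEVELS <- c("SD.BM", "SD.NB", "LD.BM", "LD.NB")

#' Generate the synthetic reference truth set
#'
#' Builds genomic scaffolds carrying non-overlapping spliced gene models
#' (0-2 introns each), the matching spliced transcripts (5' UTR + CDS +
#' 3' UTR), in-frame protein translations of the coding portions, per-gene
#' expected expression under the four photoperiod x blood-meal conditions
#' with planted main and interaction effects, a pathway-membership map with
#' one deliberately DE-enriched pathway, and synthetic vector/adapter
#' contaminant sequences.
#'
#' @param config A [sim_config()].
#' @return A `truth_set` list: `scaffolds`, `gene_models`, `transcripts`,
#'   `proteins`, `utr5`, `utr3`, `condition_means`, `de_truth`,
#'   `pathway_map`, `vector_db`, `adapters`, `config`.
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes

  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))

  genes <- vector("list", ng)
  if (ng > 0) {
    for (i in seq_len(ng)) {
      n_inner <- sample(seq(config$gene_length_range[1],
                            config$gene_length_range[2]) %/% 3, 1) - 2L
      cds <- paste0("ATG", paste(sample(codons, n_inner, replace = TRUE),
                                 collapse = ""), "TAA")
      n_intr <- sample(config$intron_count_range[1]:config$intron_count_range[2], 1)
      exon_seqs <- cds
      if (n_intr > 0) {
        cuts <- sort(sample(seq(100, nchar(cds) - 100), n_intr))
        bounds <- c(0, cuts, nchar(cds))
        exon_seqs <- substring(cds, bounds[-length(bounds)] + 1, bounds[-1])
      }
      introns <- if (n_intr > 0) {
        paste0("GT", random_dna(sample(config$intron_length_range[1]:
                                         config$intron_length_range[2],
                                       n_intr, replace = TRUE) - 4L), "AG")
      } else character(0)
      genic <- exon_seqs[1]
      if (n_intr > 0) {
        for (j in seq_len(n_intr)) {
          genic <- paste0(genic, introns[j], exon_seqs[j + 1])
        }
      }
      utr5 <- random_dna(sample(config$utr_length_range[1]:
                                  config$utr_length_range[2], 1))
      utr3 <- random_dna(sample(config$utr_length_range[1]:
                                  config$utr_length_range[2], 1))
      genes[[i]] <- list(cds = cds, genic = genic, utr5 = utr5, utr3 = utr3)
    }
  }

  gene_ids <- sprintf("g%04d", seq_len(ng))
  scaffold_ids <- sprintf("scaf%02d", seq_len(config$n_scaffolds))
  scaf_assign <- if (ng > 0) ((seq_len(ng) - 1L) %% config$n_scaffolds) + 1L else integer(0)

  scaffolds <- character(config$n_scaffolds)
  models <- vector("list", ng)
  for (s in seq_len(config$n_scaffolds)) {
    seqs <- character(0)
    offset <- 0L
    for (i in which(scaf_assign == s)) {
      gap <- random_dna(sample(1200:2500, 1))
      g <- genes[[i]]
      region <- paste0(g$utr5, g$genic, g$utr3)
      strand <- sample(c("+", "-"), 1)
      placed <- if (strand == "+") region else revcomp(region)
      offset <- offset + nchar(gap)
      lead <- if (strand == "+") nchar(g$utr5) else nchar(g$utr3)
      models[[i]] <- tibble::tibble(
        gene_id = gene_ids[i], scaffold = scaffold_ids[s],
        start = offset + lead + 1L,
        end = offset + lead + nchar(g$genic),
        strand = strand)
      seqs <- c(seqs, gap, placed)
      offset <- offset + nchar(region)
    }
    # reserved intergenic tail, well clear (> 1 kb) of any gene model
    scaffolds[s] <- paste0(paste(seqs, collapse = ""), random_dna(4000L))
  }
  names(scaffolds) <- scaffold_ids

  gene_models <- if (ng > 0) dplyr::bind_rows(models) else
    tibble::tibble(gene_id = character(), scaffold = character(),
                   start = integer(), end = integer(), strand = character())

  transcripts <- setNames(vapply(genes, function(g)
    paste0(g$utr5, g$cds, g$utr3), character(1)), gene_ids)
  proteins <- setNames(vapply(genes, function(g) {
    sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAString(g$cds))))
  }, character(1)), gene_ids)
  # genes lacking a reference protein (lineage-specific; genome path only)
  n_prot <- round(config$protein_reference_fraction * ng)
  protein_genes <- sort(sample(gene_ids, n_prot))
  proteins <- proteins[protein_genes]

  # planted expression truth: disjoint effect gene sets, random directions
  base_mean <- rlnorm(ng, log(60), 1.0)
  n_eff <- round(config$frac_de * ng)
  pool <- sample(gene_ids)
  eff_sets <- list(photoperiod = character(0), bloodmeal = character(0),
                   interaction = character(0))
  taken <- 0
  for (nm in names(eff_sets)) {
    k <- min(n_eff[[nm]], max(0, length(pool) - taken))
    eff_sets[[nm]] <- pool[seq_len(k) + taken]
    taken <- taken + k
  }
  de_truth <- tibble::tibble(gene_id = gene_ids, effect = "none", log2fc = 0)
  for (nm in names(eff_sets)) {
    idx <- match(eff_sets[[nm]], gene_ids)
    if (length(idx) > 0) {
      de_truth$effect[idx] <- nm
      de_truth$log2fc[idx] <- config$effect_log2fc[[nm]] *
        sample(c(-1, 1), length(idx), replace = TRUE)
    }
  }

  condition_means <- matrix(base_mean, nrow = ng, ncol = 4,
                            dimnames = list(gene_ids, CELL_LEVELS))
  if (ng > 0) {
    is_sd <- c(1, 1, 0, 0); is_bm <- c(1, 0, 1, 0)
    for (i in seq_len(ng)) {
      lfc <- de_truth$log2fc[i]
      mult <- switch(de_truth$effect[i],
                     photoperiod = 2^(lfc * is_sd),
                     bloodmeal   = 2^(lfc * is_bm),
                     interaction = 2^(lfc * is_sd * is_bm),
                     rep(1, 4))
      condition_means[i, ] <- condition_means[i, ] * mult
    }
  }

  # pathway map; pathway 1 is deliberately enriched in photoperiod-DE genes
  pathway_map <- tibble::tibble(pathway_id = character(), gene_id = character())
  if (ng > 0 && config$n_pathways > 0) {
    rows <- list()
    pp <- eff_sets$photoperiod
    planted <- unique(c(head(pp, 12),
                        sample(setdiff(gene_ids, pp),
                               min(3, max(0, ng - length(pp))))))
    rows[[1]] <- tibble::tibble(pathway_id = "path01", gene_id = planted)
    for (p in seq_len(config$n_pathways - 1L)) {
      size <- sample(config$pathway_size_range[1]:config$pathway_size_range[2], 1)
      rows[[p + 1]] <- tibble::tibble(
        pathway_id = sprintf("path%02d", p + 1L),
        gene_id = sample(gene_ids, min(size, ng)))
    }
    pathway_map <- dplyr::bind_rows(rows)
  }

  vector_db <- setNames(random_dna(c(800L, 800L)), c("synthVec1", "synthVec2"))
  adapters <- setNames(random_dna(c(33L, 33L)),
                       c("synthAdapter1", "synthAdapter2"))

  structure(list(scaffolds = scaffolds, gene_models = gene_models,
                 transcripts = transcripts, proteins = proteins,
                 utr5 = setNames(vapply(genes, `[[`, character(1), "utr5"),
                                 gene_ids),
                 utr3 = setNames(vapply(genes, `[[`, character(1), "utr3"),
                                 gene_ids),
                 protein_genes = protein_genes,
                 condition_means = condition_means, de_truth = de_truth,
                 pathway_map = pathway_map, vector_db = vector_db,
                 adapters = adapters, config = config),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set>", length(x$transcripts), "genes on",
      length(x$scaffolds), "scaffolds;",
      dplyr::n_distinct(x$pathway_map$pathway_id), "pathways\n")
  invisible(x)
}

#' Write the reference side of a truth set to disk
#'
#' Emits scaffolds, proteins, transcripts (FASTA), gene models (GFF-like
#' TSV), pathway map (TSV) and contaminant databases (FASTA).
#'
#' @param truth A `truth_set`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    scaffolds = file.path(dir, "scaffolds.fasta"),
    proteins = file.path(dir, "proteins.fasta"),
    transcripts = file.path(dir, "transcripts.fasta"),
    gene_models = file.path(dir, "gene_models.tsv"),
    pathways = file.path(dir, "pathways.tsv"),
    vector_db = file.path(dir, "vector.fasta"),
    adapters = file.path(dir, "adapters.fasta"))
  write_fasta(truth$scaffolds, paths["scaffolds"])
  write_fasta(truth$proteins, paths["proteins"])
  write_fasta(truth$transcripts, paths["transcripts"])
  write_gene_models(truth$gene_models, paths["gene_models"])
  readr::write_tsv(truth$pathway_map, paths["pathways"], progress = FALSE)
  write_fasta(truth$vector_db, paths["vector_db"])
  write_fasta(truth$adapters, paths["adapters"])
  invisible(paths)
}
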