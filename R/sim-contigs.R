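# Per-stage contig sets with planted assembly artefacts: duplicates,
# overlapping fragments, UTR-only pieces, two-gene chimeras and intergenic
# slices, each carrying a truth label.

#' Generate per-stage contig sets with truth labels
#'
#' Emulates the multi-stage de novo assemblies feeding the hybrid
#' re-assembly: each gene appears in at least one life stage, as either one
#' full-length transcript contig or two overlapping fragments; additional
#' contigs are planted as (near-)duplicates (>= 99\% identity), UTR-only
#' fragments lying adjacent to their gene model, two-gene chimeras, and
#' intergenic scaffold slices. Every emitted contig carries a truth label.
#'
#' @param truth A `truth_set` from [generate_references()].
#' @param config The same [sim_config()].
#' @return List with `contigs` (tibble: contig_id, stage, seq, length) and
#'   `labels` (tibble: contig_id, stage, class, gene_id, gene_id_2,
#'   duplicate_of), where class is one of full, fragment, utr, chimera,
#'   intergenic, duplicate.
#' @export
generate_contig_sets <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  gene_ids <- names(truth$transcripts)
  ng <- length(gene_ids)
  stages <- config$stage_names
  rows <- list(); labs <- list(); counter <- 0L
  seq_by_id <- new.env(parent = emptyenv())

  emit <- function(stage, seq, class, gene_id = NA_character_,
                   gene_id_2 = NA_character_, duplicate_of = NA_character_) {
    counter <<- counter + 1L
    id <- sprintf("%s_c%05d", stage, counter)
    rows[[counter]] <<- tibble::tibble(contig_id = id, stage = stage,
                                       seq = seq, length = nchar(seq))
    labs[[counter]] <<- tibble::tibble(contig_id = id, stage = stage,
                                       class = class, gene_id = gene_id,
                                       gene_id_2 = gene_id_2,
                                       duplicate_of = duplicate_of)
    assign(id, seq, envir = seq_by_id)
    id
  }

  if (ng > 0) {
    guaranteed <- stages[((seq_len(ng) - 1L) %% length(stages)) + 1L]
    for (st in stages) {
      in_stage <- which(guaranteed == st | runif(ng) < 0.4)
      base_ids <- character(0)
      base_gene <- character(0)
      for (i in in_stage) {
        tx <- truth$transcripts[i]
        L <- nchar(tx)
        if (runif(1) < config$fragment_rate && L >= 400) {
          m1 <- floor(L * runif(1, 0.55, 0.75))
          m2 <- floor(L * runif(1, 0.30, 0.45))
          id1 <- emit(st, substr(tx, 1, m1), "fragment", gene_ids[i])
          id2 <- emit(st, substr(tx, m2, L), "fragment", gene_ids[i])
          base_ids <- c(base_ids, id1, id2)
          base_gene <- c(base_gene, gene_ids[i], gene_ids[i])
        } else {
          id <- emit(st, unname(tx), "full", gene_ids[i])
          base_ids <- c(base_ids, id)
          base_gene <- c(base_gene, gene_ids[i])
        }
        if (runif(1) < config$utr_contig_rate) {
          # genomic fragment flanking the gene model (within 1 kb), the
          # shape of a potential-UTR contig: near a model but not
          # contained in any transcript
          gm <- truth$gene_models[i, ]
          lead <- if (gm$strand == "+") nchar(truth$utr5[i]) else
            nchar(truth$utr3[i])
          region_start <- gm$start - lead
          gap <- sample(0:300, 1)
          len <- sample(80:250, 1)
          end_pos <- region_start - gap - 1L
          start_pos <- end_pos - len + 1L
          if (start_pos >= 1) {
            emit(st, substr(truth$scaffolds[[gm$scaffold]], start_pos,
                            end_pos), "utr", gene_ids[i])
          }
        }
      }
      # duplicates of base contigs
      n_base <- length(base_ids)
      if (n_base > 0) {
        dup <- which(runif(n_base) < config$contig_redundancy_rate)
        for (j in dup) {
          seq <- get(base_ids[j], envir = seq_by_id)
          if (runif(1) < 0.5) seq <- mutate_seq(seq, 0.003)
          emit(st, seq, "duplicate", base_gene[j],
               duplicate_of = base_ids[j])
        }
        # two-gene chimeras
        if (ng >= 2) {
          chim <- which(runif(n_base) < config$chimera_rate)
          for (j in chim) {
            g1 <- base_gene[j]
            g2 <- sample(setdiff(gene_ids, g1), 1)
            t1 <- truth$transcripts[g1]; t2 <- truth$transcripts[g2]
            # each side carries >= 300 bp of coding sequence, the shape of
            # a mis-joined assembly chimera detectable from both parents
            cds1 <- nchar(t1) - nchar(truth$utr5[g1]) - nchar(truth$utr3[g1])
            cds2 <- nchar(t2) - nchar(truth$utr5[g2]) - nchar(truth$utr3[g2])
            a <- nchar(truth$utr5[g1]) + sample(300:min(800, cds1), 1)
            b <- nchar(truth$utr3[g2]) + sample(300:min(800, cds2), 1)
            emit(st, paste0(substr(t1, 1, a),
                            substr(t2, nchar(t2) - b + 1L, nchar(t2))),
                 "chimera", g1, gene_id_2 = g2)
          }
        }
        # intergenic slices from the reserved scaffold tails
        n_inter <- round(config$intergenic_rate * n_base)
        for (j in seq_len(n_inter)) {
          sc <- truth$scaffolds[[sample(length(truth$scaffolds), 1)]]
          len <- sample(200:500, 1)
          centre <- nchar(sc) - 2000L
          emit(st, substr(sc, centre, centre + len - 1L), "intergenic")
        }
      }
    }
  }

  contigs <- if (counter > 0) dplyr::bind_rows(rows) else
    tibble::tibble(contig_id = character(), stage = character(),
                   seq = character(), length = integer())
  labels <- if (counter > 0) dplyr::bind_rows(labs) else
    tibble::tibble(contig_id = character(), stage = character(),
                   class = character(), gene_id = character(),
                   gene_id_2 = character(), duplicate_of = character())
  list(contigs = contigs, labels = labels)
}
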