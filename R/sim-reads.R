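# Paired-end read simulation: negative-binomial per-library gene counts
# under the 2x2 factorial design, uniform fragment placement with normal
# insert sizes, vector/adapter contamination and 3'-degrading qualities.

#' Generate the 16-library paired-end sequencing experiment
#'
#' Draws per-library, per-gene fragment counts from a negative binomial
#' whose mean is the library-size-scaled condition mean (planted
#' photoperiod, blood-meal and interaction effects), places fragments
#' uniformly along transcripts with normally distributed insert sizes,
#' plants vector-insert and adapter-read-through contamination at the
#' configured rate, and degrades 3' qualities with a logistic phred decay.
#' Read ids encode their provenance (`<lib>:<gene>:<n>` or
#' `<lib>:vec:<n>` / `<lib>:adp:<n>`), so every read is traceable.
#'
#' @param truth A `truth_set`.
#' @param config The same [sim_config()].
#' @param outdir Directory for the FASTQ files and design table.
#' @return List with `design` (tibble), `files` (tibble: library_id,
#'   fastq_1, fastq_2), `true_counts` (gene x library matrix of planted
#'   fragment counts), and `skipped_genes`.
#' @export
generate_reads <- function(truth, config, outdir) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  set.seed(config$seed + 2000L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rl <- config$read_length
  n_rep <- config$n_libraries %/% 4L

  design <- tidyr::expand_grid(photoperiod = c("SD", "LD"),
                               bloodmeal = c("BM", "NB"),
                               replicate = seq_len(n_rep))
  design <- tibble::tibble(
    library_id = sprintf("lib%02d", seq_len(nrow(design))), design)

  tx <- truth$transcripts
  txlen <- nchar(tx)
  usable <- txlen >= max(rl, 1L)
  skipped <- names(tx)[!usable]
  if (length(skipped) > 0) {
    warning("skipping ", length(skipped),
            " gene(s) with transcripts shorter than the read length: ",
            paste(head(skipped, 5), collapse = ", "))
  }

  lib_sizes <- round(config$mean_library_size *
                       rlnorm(config$n_libraries, 0, 0.1))
  true_counts <- matrix(0L, nrow = length(tx), ncol = config$n_libraries,
                        dimnames = list(names(tx), design$library_id))
  files <- tibble::tibble(library_id = design$library_id,
                          fastq_1 = file.path(outdir, paste0(design$library_id,
                                                             "_1.fastq")),
                          fastq_2 = file.path(outdir, paste0(design$library_id,
                                                             "_2.fastq")))

  qd <- config$quality_decay
  profile <- qd$q_end + (qd$q_start - qd$q_end) /
    (1 + exp(qd$steepness * ((seq_len(rl) / rl) - qd$midpoint)))

  qual_strings <- function(n) {
    if (n == 0) return(character(0))
    q <- matrix(profile, nrow = n, ncol = rl, byrow = TRUE) +
      rnorm(n, 0, qd$sd) + matrix(rnorm(n * rl, 0, qd$base_sd), nrow = n)
    q <- pmin(pmax(round(q), 2L), 40L)
    big <- rawToChar(as.raw(33L + as.integer(t(q))))
    substring(big, seq(1L, by = rl, length.out = n),
              seq(rl, by = rl, length.out = n))
  }

  sample_fragments <- function(seqs, lens, n_per) {
    # returns mate1/mate2 sequences for fragments drawn from seqs
    gi <- rep(seq_along(seqs), n_per)
    m <- length(gi)
    if (m == 0) return(list(seq1 = character(0), seq2 = character(0),
                            src = integer(0)))
    ins <- round(rnorm(m, config$insert_mean, config$insert_sd))
    ins <- pmin(pmax(ins, rl), lens[gi])
    start <- floor(runif(m) * (lens[gi] - ins + 1)) + 1L
    s1 <- substring(seqs[gi], start, start + rl - 1L)
    s2 <- revcomp(substring(seqs[gi], start + ins - rl, start + ins - 1L))
    list(seq1 = s1, seq2 = s2, src = gi)
  }

  for (l in seq_len(config$n_libraries)) {
    cell <- paste(design$photoperiod[l], design$bloodmeal[l], sep = ".")
    w <- truth$condition_means[, cell]
    w[!usable] <- 0
    mu <- if (sum(w) > 0) lib_sizes[l] * w / sum(w) else rep(0, length(w))
    counts <- if (config$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    counts[!usable] <- 0L
    true_counts[, l] <- counts

    fr <- sample_fragments(tx, txlen, counts)
    n_real <- length(fr$src)
    ids <- if (n_real > 0) {
      sprintf("%s:%s:%06d", design$library_id[l], names(tx)[fr$src],
              seq_len(n_real))
    } else character(0)
    seq1 <- fr$seq1; seq2 <- fr$seq2

    # contamination: half vector-insert pairs, half adapter read-through
    if (n_real > 0 && config$contamination_rate > 0) {
      contam <- which(runif(n_real) < config$contamination_rate)
      if (length(contam) > 0) {
        vec_pairs <- contam[seq_len(length(contam) %/% 2)]
        adp_pairs <- setdiff(contam, vec_pairs)
        if (length(vec_pairs) > 0) {
          vf <- sample_fragments(truth$vector_db, nchar(truth$vector_db),
                                 tabulate(sample(length(truth$vector_db),
                                                 length(vec_pairs),
                                                 replace = TRUE),
                                          length(truth$vector_db)))
          seq1[vec_pairs] <- vf$seq1
          seq2[vec_pairs] <- vf$seq2
          ids[vec_pairs] <- sprintf("%s:vec:%06d", design$library_id[l],
                                    vec_pairs)
        }
        if (length(adp_pairs) > 0) {
          ad <- truth$adapters[1 + (seq_along(adp_pairs) %% 2)]
          keep <- rl - 30L
          seq1[adp_pairs] <- paste0(substr(seq1[adp_pairs], 1, keep),
                                    substr(ad, 1, 30))
          ids[adp_pairs] <- sprintf("%s:adp:%06d", design$library_id[l],
                                    adp_pairs)
        }
      }
    }

    # unstranded protocol: mates swap orientation for half the fragments
    if (n_real > 0) {
      swap <- runif(n_real) < 0.5
      tmp <- seq1[swap]; seq1[swap] <- seq2[swap]; seq2[swap] <- tmp
    }

    pairs <- tibble::tibble(pair_id = ids, seq1 = seq1,
                            qual1 = qual_strings(n_real),
                            seq2 = seq2, qual2 = qual_strings(n_real))
    write_fastq_pairs(pairs, files$fastq_1[l], files$fastq_2[l])
  }

  readr::write_tsv(design, file.path(outdir, "design.tsv"), progress = FALSE)
  counts_out <- tibble::tibble(gene_id = rownames(true_counts),
                               tibble::as_tibble(true_counts))
  readr::write_tsv(counts_out, file.path(outdir, "true_counts.tsv"),
                   progress = FALSE)
  list(design = design, files = files, true_counts = true_counts,
       skipped_genes = skipped)
}
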