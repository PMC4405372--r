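# Read cleaning: contaminant screening, quality trimming, and digital
# normalization by median k-mer coverage.

#' Contaminant screening policy
#'
#' Removal thresholds for database (vector/rRNA-style) and adapter
#' screening: a read is removed when it has a local alignment to any
#' database sequence meeting both the identity and score cutoff for that
#' database class. Local alignments are scored with match +1, mismatch -1,
#' gap -2 (so a score of 18 demands at least 18 net matching bases).
#'
#' @param db_identity_min Identity fraction for the vector database (0.95).
#' @param db_score_min Alignment score cutoff for the vector database (18).
#' @param adapter_identity_min Identity fraction for adapters (1.00).
#' @param adapter_score_min Alignment score cutoff for adapters (18).
#' @param remove_mate Remove the mate of a contaminated read as well
#'   (always the case in this paired pipeline).
#' @return A `screen_policy` list.
#' @export
screen_policy <- function(db_identity_min = 0.95, db_score_min = 18,
                          adapter_identity_min = 1.00, adapter_score_min = 18,
                          remove_mate = TRUE) {
  check_fraction(db_identity_min, "db_identity_min")
  check_fraction(adapter_identity_min, "adapter_identity_min")
  check_positive(db_score_min, "db_score_min")
  check_positive(adapter_score_min, "adapter_score_min")
  structure(list(db_identity_min = db_identity_min,
                 db_score_min = db_score_min,
                 adapter_identity_min = adapter_identity_min,
                 adapter_score_min = adapter_score_min,
                 remove_mate = isTRUE(remove_mate)), class = "screen_policy")
}

#' Quality trimming policy
#'
#' Retains the longest contiguous run of bases with phred strictly greater
#' than `min_phred`; the read is discarded if that run is not strictly
#' longer than `min_len`.
#'
#' @param min_len Minimum retained length in bp (strict `>`, default 50).
#' @param min_phred Minimum phred quality (strict `>`, default 30).
#' @return A `trim_policy` list.
#' @export
trim_policy <- function(min_len = 50L, min_phred = 30L) {
  min_len <- check_count(min_len, "min_len", 1L)
  if (!is.numeric(min_phred) || min_phred < 0 || min_phred > 41) {
    stop("invalid `min_phred`: must be in [0, 41]", call. = FALSE)
  }
  structure(list(min_len = min_len, min_phred = as.integer(min_phred)),
            class = "trim_policy")
}

#' Digital normalization policy
#'
#' @param k K-mer size (default 20).
#' @param coverage_cutoff Median k-mer abundance cutoff (default 20).
#' @return A `diginorm_policy` list.
#' @export
diginorm_policy <- function(k = 20L, coverage_cutoff = 20L) {
  structure(list(k = check_count(k, "k", 1L),
                 coverage_cutoff = check_count(coverage_cutoff,
                                               "coverage_cutoff", 1L)),
            class = "diginorm_policy")
}

# Best local alignment of each read against a contaminant database, using
# an exact seed-word prefilter (ssaha2-style word hashing) followed by
# Smith-Waterman verification on a window around the seed.
screen_hits <- function(reads, db, identity_min, score_min, seed_k = 13L) {
  empty <- tibble::tibble(read_index = integer(), target = character(),
                          identity = double(), score = double())
  if (length(db) == 0 || length(reads) == 0) return(empty)
  db_all <- c(db, setNames(revcomp(db), paste0(names(db), "_rc")))
  dbk <- kmer_table(unname(db_all), seed_k)
  dbk <- dbk[!duplicated(paste(dbk$kmer, dbk$seq_index)), ]
  dict <- unique(dbk$kmer)
  dict <- dict[!grepl("[^ACGT]", dict)]
  if (length(dict) == 0) return(empty)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(dict))
  hit_list <- Biostrings::vwhichPDict(pd, Biostrings::DNAStringSet(reads))
  flagged <- which(lengths(hit_list) > 0)
  if (length(flagged) == 0) return(empty)

  cand <- tibble::tibble(
    read_index = rep(flagged, lengths(hit_list[flagged])),
    kmer = dict[unlist(hit_list[flagged], use.names = FALSE)])
  cand <- dplyr::inner_join(cand, dbk, by = "kmer",
                            relationship = "many-to-many")
  # one seed per (read, database sequence): the first k-mer occurrence
  cand <- cand[!duplicated(paste(cand$read_index, cand$seq_index)), ]

  rlen <- nchar(reads)[cand$read_index]
  w_start <- pmax(cand$pos - rlen, 1L)
  w_end <- pmin(cand$pos + seed_k + rlen, nchar(db_all)[cand$seq_index])
  windows <- substring(unname(db_all)[cand$seq_index], w_start, w_end)
  sw <- .sw_local(reads[cand$read_index], windows, 1, -1, -2)
  identity <- ifelse(sw[, 3] > 0, sw[, 2] / sw[, 3], 0)
  keep <- sw[, 1] >= score_min & identity >= identity_min
  tibble::tibble(read_index = cand$read_index[keep],
                 target = sub("_rc$", "", names(db_all)[cand$seq_index[keep]]),
                 identity = identity[keep], score = sw[keep, 1]) %>%
    dplyr::arrange(.data$read_index, dplyr::desc(.data$score)) %>%
    dplyr::distinct(.data$read_index, .keep_all = TRUE)
}

#' Screen read pairs against vector and adapter databases
#'
#' A pair is removed when either mate has a qualifying local alignment to
#' any vector-database sequence (identity >= 95\%, score >= 18 by default)
#' or to any adapter (identity 100\%, score >= 18). Contaminated reads are
#' removed together with their mates. Candidate reads are found with an
#' exact 13-bp word prefilter before Smith-Waterman verification.
#'
#' @param pairs Tibble from [read_fastq_pairs()].
#' @param vec_db Named character vector of vector/contaminant sequences
#'   (may be empty).
#' @param adapters Named character vector of adapter sequences.
#' @param policy A [screen_policy()].
#' @return List with `retained` (pairs tibble) and `log` (tibble:
#'   pair_id, mate, database, target, identity, score).
#' @export
screen_contaminants <- function(pairs, vec_db = character(),
                                adapters = character(),
                                policy = screen_policy()) {
  stopifnot(inherits(policy, "screen_policy"))
  log_empty <- tibble::tibble(pair_id = character(), mate = integer(),
                              database = character(), target = character(),
                              identity = double(), score = double())
  if (nrow(pairs) == 0 || (length(vec_db) == 0 && length(adapters) == 0)) {
    return(list(retained = pairs, log = log_empty))
  }
  logs <- list()
  removed <- rep(FALSE, nrow(pairs))
  for (mate in 1:2) {
    reads <- pairs[[paste0("seq", mate)]]
    vh <- screen_hits(reads, vec_db, policy$db_identity_min,
                      policy$db_score_min)
    ah <- screen_hits(reads, adapters, policy$adapter_identity_min,
                      policy$adapter_score_min)
    if (nrow(vh) > 0) {
      logs[[length(logs) + 1]] <- tibble::tibble(
        pair_id = pairs$pair_id[vh$read_index], mate = mate,
        database = "vector", target = vh$target,
        identity = vh$identity, score = vh$score)
      removed[vh$read_index] <- TRUE
    }
    if (nrow(ah) > 0) {
      logs[[length(logs) + 1]] <- tibble::tibble(
        pair_id = pairs$pair_id[ah$read_index], mate = mate,
        database = "adapter", target = ah$target,
        identity = ah$identity, score = ah$score)
      removed[ah$read_index] <- TRUE
    }
  }
  list(retained = pairs[!removed, , drop = FALSE],
       log = if (length(logs) > 0) dplyr::bind_rows(logs) else log_empty)
}

#' Quality-trim reads to their longest high-quality run
#'
#' Keeps, for each read, the longest contiguous run of bases whose phred
#' quality is strictly greater than `min_phred` (leftmost run on ties);
#' reads whose best run is not strictly longer than `min_len` are
#' discarded.
#'
#' @param reads Tibble with `id`, `seq`, `qual` (phred-33).
#' @param policy A [trim_policy()].
#' @return Tibble of retained, trimmed reads (same columns).
#' @export
quality_trim <- function(reads, policy = trim_policy()) {
  stopifnot(inherits(policy, "trim_policy"))
  if (nrow(reads) == 0) return(reads)
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence/quality length mismatch at record ",
         which(nchar(reads$seq) != nchar(reads$qual))[1], call. = FALSE)
  }
  runs <- .hq_runs(reads$qual, policy$min_phred, 33L)
  keep <- runs[, 2] > policy$min_len
  out <- reads[keep, , drop = FALSE]
  s <- runs[keep, 1]; e <- s + runs[keep, 2] - 1L
  out$seq <- substring(out$seq, s, e)
  out$qual <- substring(out$qual, s, e)
  out
}

#' Quality-trim read pairs, keeping pairs whose mates both survive
#'
#' @param pairs Pairs tibble.
#' @param policy A [trim_policy()].
#' @return List with `pairs` (trimmed surviving pairs) and `n_dropped`.
#' @export
quality_trim_pairs <- function(pairs, policy = trim_policy()) {
  r1 <- quality_trim(tibble::tibble(id = pairs$pair_id, seq = pairs$seq1,
                                    qual = pairs$qual1), policy)
  r2 <- quality_trim(tibble::tibble(id = pairs$pair_id, seq = pairs$seq2,
                                    qual = pairs$qual2), policy)
  keep <- intersect(r1$id, r2$id)
  out <- tibble::tibble(pair_id = keep,
                        seq1 = r1$seq[match(keep, r1$id)],
                        qual1 = r1$qual[match(keep, r1$id)],
                        seq2 = r2$seq[match(keep, r2$id)],
                        qual2 = r2$qual[match(keep, r2$id)])
  list(pairs = out, n_dropped = nrow(pairs) - nrow(out))
}

#' Digital normalization by median k-mer abundance
#'
#' Streaming rule: a read (or pair) is kept iff the median abundance of its
#' canonical k-mers in the running exact counter is below the coverage
#' cutoff; kept reads' k-mers then increment the counter. For pairs the
#' pair is kept when either mate is below the cutoff, and both mates of a
#' kept pair feed the counter. Order-dependent and deterministic for a
#' fixed input order. Reads shorter than k are kept unconditionally.
#'
#' @param reads Either a single-end tibble with a `seq` column or a pairs
#'   tibble with `seq1`/`seq2`.
#' @param policy A [diginorm_policy()].
#' @return The retained subset of `reads` (a subsequence of the input).
#' @export
digital_normalize <- function(reads, policy = diginorm_policy()) {
  stopifnot(inherits(policy, "diginorm_policy"))
  if (nrow(reads) == 0) return(reads)
  if (all(c("seq1", "seq2") %in% names(reads))) {
    keep <- .dgn_keep_pairs(reads$seq1, reads$seq2, policy$k,
                            policy$coverage_cutoff)
  } else {
    keep <- .dgn_keep_single(reads$seq, policy$k, policy$coverage_cutoff)
  }
  reads[keep, , drop = FALSE]
}
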