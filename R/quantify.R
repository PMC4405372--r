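# Unigene quantification: concordant paired-end mapping by exact-word
# seeding with Hamming verification, and expectation-maximization
# allocation of multi-mapping pairs to unigene-level expected counts.

#' Build an exact-word index over a unigene set
#'
#' @param unigenes Tibble with `unigene_id`, `seq`.
#' @param k Seed word length (default 25).
#' @return A `tx_index` list (word table plus sequences).
#' @export
build_index <- function(unigenes, k = 25L) {
  if (nrow(unigenes) == 0) stop("empty unigene index", call. = FALSE)
  tab <- kmer_table(unigenes$seq, k)
  structure(list(words = tibble::tibble(kmer = tab$kmer,
                                        uindex = tab$seq_index,
                                        pos = tab$pos),
                 seqs = unigenes$seq, ids = unigenes$unigene_id, k = k),
            class = "tx_index")
}

# Candidate alignments of single reads (both orientations) against the
# index: exact seed at read start, then full-length Hamming verification.
map_mates <- function(seqs, index, max_mismatch) {
  k <- index$k
  n <- length(seqs)
  cand <- tibble::tibble(read_index = rep(seq_len(n), 2),
                         orient = rep(c("f", "r"), each = n),
                         oriented = c(seqs, revcomp(seqs)))
  cand <- cand[nchar(cand$oriented) >= k, , drop = FALSE]
  cand$kmer <- substr(cand$oriented, 1, k)
  hits <- dplyr::inner_join(cand, index$words, by = "kmer",
                            relationship = "many-to-many")
  if (nrow(hits) == 0) {
    return(tibble::tibble(read_index = integer(), orient = character(),
                          uindex = integer(), pos = integer()))
  }
  len <- nchar(hits$oriented)
  target <- substring(index$seqs[hits$uindex], hits$pos,
                      hits$pos + len - 1L)
  mm <- .hamming(hits$oriented, target)
  ok <- mm >= 0 & mm <= max_mismatch
  tibble::tibble(read_index = hits$read_index[ok], orient = hits$orient[ok],
                 uindex = hits$uindex[ok], pos = hits$pos[ok],
                 read_len = len[ok]) %>%
    dplyr::distinct()
}

#' Map read pairs to unigenes (concordant candidate sets)
#'
#' For each pair, finds the set of unigenes on which both mates align in
#' opposite orientations (forward-reverse) with an implied fragment length
#' inside `insert_bounds`. Alignment is exact-word seeding at the read
#' start followed by full-length verification with at most `max_mismatch`
#' mismatches.
#'
#' @param pairs Pairs tibble (`pair_id`, `seq1`, `seq2`, ...).
#' @param index A `tx_index` from [build_index()], or a unigene tibble.
#' @param max_mismatch Maximum mismatches per mate (default 0).
#' @param insert_bounds Allowed fragment length range in bp.
#' @return List with `candidates` (tibble: pair_id, unigene_id),
#'   `n_mapped`, `n_unmapped` and `unmapped` (pair ids).
#' @export
map_pairs <- function(pairs, index, max_mismatch = 0L,
                      insert_bounds = c(80L, 600L)) {
  if (!inherits(index, "tx_index")) index <- build_index(index)
  if (nrow(pairs) == 0) {
    return(list(candidates = tibble::tibble(pair_id = character(),
                                            unigene_id = character()),
                n_mapped = 0L, n_unmapped = 0L, unmapped = character(0)))
  }
  h1 <- map_mates(pairs$seq1, index, max_mismatch)
  h2 <- map_mates(pairs$seq2, index, max_mismatch)
  j <- dplyr::inner_join(h1, h2, by = c("read_index", "uindex"),
                         suffix = c("_1", "_2"),
                         relationship = "many-to-many")
  j <- j[j$orient_1 != j$orient_2, , drop = FALSE]
  if (nrow(j) > 0) {
    left_f <- ifelse(j$orient_1 == "f", j$pos_1 <= j$pos_2,
                     j$pos_2 <= j$pos_1)
    frag <- pmax(j$pos_1 + j$read_len_1, j$pos_2 + j$read_len_2) -
      pmin(j$pos_1, j$pos_2)
    ok <- left_f & frag >= insert_bounds[1] & frag <= insert_bounds[2]
    j <- j[ok, , drop = FALSE]
  }
  cand <- tibble::tibble(pair_id = pairs$pair_id[j$read_index],
                         unigene_id = index$ids[j$uindex]) %>%
    dplyr::distinct()
  mapped_ids <- unique(cand$pair_id)
  list(candidates = cand,
       n_mapped = length(mapped_ids),
       n_unmapped = nrow(pairs) - length(mapped_ids),
       unmapped = setdiff(pairs$pair_id, mapped_ids))
}

#' Expectation-maximization allocation of multi-mapping pairs
#'
#' Fractionally assigns each pair over its candidate unigenes in
#' proportion to unigene abundance divided by effective length
#' (`max(1, length - insert_mean + 1)`), re-estimating abundances from the
#' fractional counts until convergence (`max |delta theta| < tol`).
#' Unique pairs stay where they are; expected counts sum exactly to the
#' number of mapped pairs.
#'
#' @param candidates Candidate tibble from [map_pairs()].
#' @param unigene_lengths Named vector of unigene lengths in bp.
#' @param insert_mean Mean fragment length for the effective-length
#'   correction (default 203).
#' @param tol Convergence tolerance on abundances (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return Tibble with `unigene_id`, `expected_count`, `effective_length`,
#'   `theta`.
#' @export
em_quantify <- function(candidates, unigene_lengths, insert_mean = 203,
                        tol = 1e-8, max_iter = 1000L) {
  ids <- names(unigene_lengths)
  eff <- pmax(1, unigene_lengths - insert_mean + 1)
  out <- tibble::tibble(unigene_id = ids, expected_count = 0,
                        effective_length = unname(eff), theta = 0)
  if (nrow(candidates) == 0) return(out)

  # equivalence classes: pairs sharing one candidate set
  sets <- split(match(candidates$unigene_id, ids), candidates$pair_id)
  keys <- vapply(sets, function(s) paste(sort(s), collapse = ","),
                 character(1))
  class_n <- table(keys)
  class_sets <- lapply(names(class_n), function(k)
    as.integer(strsplit(k, ",")[[1]]))
  n_c <- as.numeric(class_n)
  total <- sum(n_c)

  nu <- length(ids)
  theta <- rep(1 / nu, nu)
  for (it in seq_len(max_iter)) {
    frac <- numeric(nu)
    for (ci in seq_along(class_sets)) {
      s <- class_sets[[ci]]
      w <- theta[s] / eff[s]
      if (sum(w) == 0) w <- rep(1, length(s))
      frac[s] <- frac[s] + n_c[ci] * w / sum(w)
    }
    new_theta <- frac / total
    delta <- max(abs(new_theta - theta))
    theta <- new_theta
    if (delta < tol) break
  }
  frac <- numeric(nu)
  for (ci in seq_along(class_sets)) {
    s <- class_sets[[ci]]
    w <- theta[s] / eff[s]
    if (sum(w) == 0) w <- rep(1, length(s))
    frac[s] <- frac[s] + n_c[ci] * w / sum(w)
  }
  out$expected_count <- frac
  out$theta <- theta
  out
}

#' Quantify all libraries of an experiment
#'
#' Maps each library's cleaned pairs to the unigene set and produces the
#' unigene-by-library expected-count matrix plus a mapping summary.
#'
#' @param pair_list Named list of pairs tibbles (one per library).
#' @param unigenes Tibble with `unigene_id`, `seq`.
#' @param insert_mean Mean fragment length (bp) for effective lengths.
#' @param ... Passed to [map_pairs()].
#' @return List with `counts` (matrix), `effective_lengths`, and
#'   `summary` (tibble: library_id, total_pairs, mapped_pairs, fraction).
#' @export
quantify_libraries <- function(pair_list, unigenes, insert_mean = 203, ...) {
  index <- build_index(unigenes)
  lens <- setNames(nchar(unigenes$seq), unigenes$unigene_id)
  counts <- matrix(0, nrow = nrow(unigenes), ncol = length(pair_list),
                   dimnames = list(unigenes$unigene_id, names(pair_list)))
  summaries <- list()
  for (lib in names(pair_list)) {
    mp <- map_pairs(pair_list[[lib]], index, ...)
    em <- em_quantify(mp$candidates, lens, insert_mean = insert_mean)
    counts[, lib] <- em$expected_count
    summaries[[lib]] <- tibble::tibble(
      library_id = lib, total_pairs = nrow(pair_list[[lib]]),
      mapped_pairs = mp$n_mapped,
      fraction = ifelse(nrow(pair_list[[lib]]) > 0,
                        mp$n_mapped / nrow(pair_list[[lib]]), NA_real_))
  }
  list(counts = counts, effective_lengths = pmax(1, lens - insert_mean + 1),
       summary = dplyr::bind_rows(summaries))
}
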