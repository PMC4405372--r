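# Genome-reference-guided re-assembly: BLASTN seed search, spliced
# alignment by collinear HSP chaining (target-side gaps as introns),
# percentile retention, locus merging, chimera removal and
# gene-model/UTR/unannotated classification.

# Chain collinear HSPs of one (query, scaffold, strand) into a spliced
# alignment: maximize total bit score subject to near-monotone query order
# (<= max_q_overlap bp overlap) and intron-sized target gaps.
chain_group <- function(h, max_intron, max_q_overlap = 30L) {
  # on the minus strand the target runs backwards along the query; flip
  # the target axis so collinearity is always "both increasing"
  minus <- h$strand[1] == "-"
  h$.row <- seq_len(nrow(h))
  t_lo <- if (minus) -h$t_end else h$t_start
  t_hi <- if (minus) -h$t_start else h$t_end
  o <- order(h$q_start, t_lo)
  h <- h[o, , drop = FALSE]
  t_lo <- t_lo[o]; t_hi <- t_hi[o]
  n <- nrow(h)
  score <- h$bit_score
  prev <- rep(0L, n)
  if (n > 1) {
    for (i in 2:n) {
      for (j in seq_len(i - 1)) {
        if (h$q_start[i] + max_q_overlap < h$q_end[j]) next
        gap_t <- t_lo[i] - t_hi[j]
        if (gap_t < -max_q_overlap || gap_t > max_intron) next
        cand <- score[j] + h$bit_score[i]
        if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
      }
    }
  }
  best_end <- which.max(score)
  path <- integer(0); i <- best_end
  while (i != 0L) { path <- c(i, path); i <- prev[i] }
  hp <- h[path, , drop = FALSE]
  used <- h$.row[path]
  q_iv <- cbind(hp$q_start, hp$q_end)
  q_iv <- q_iv[order(q_iv[, 1]), , drop = FALSE]
  covered <- 0L; cur_s <- q_iv[1, 1]; cur_e <- q_iv[1, 2]
  if (nrow(q_iv) > 1) {
    for (r in 2:nrow(q_iv)) {
      if (q_iv[r, 1] <= cur_e) cur_e <- max(cur_e, q_iv[r, 2]) else {
        covered <- covered + cur_e - cur_s; cur_s <- q_iv[r, 1]; cur_e <- q_iv[r, 2]
      }
    }
  }
  covered <- covered + cur_e - cur_s
  list(chain = tibble::tibble(
    scaffold = hp$target_id[1], strand = hp$strand[1],
    q_start = min(hp$q_start), q_end = max(hp$q_end),
    t_start = min(hp$t_start), t_end = max(hp$t_end),
    q_covered = covered,
    identity = sum(hp$identity * hp$aligned_length) / sum(hp$aligned_length),
    score = sum(hp$bit_score), e_value = min(hp$e_value),
    n_hsps = nrow(hp)), used = used)
}

# Extract up to max_chains disjoint chains from one (query, scaffold,
# strand) HSP group, so distinct loci (e.g. the two parents of a
# same-scaffold chimera) each surface as a chain.
chain_group_multi <- function(h, max_intron, max_chains = 3L) {
  out <- list()
  remaining <- h
  for (i in seq_len(max_chains)) {
    if (nrow(remaining) == 0) break
    cg <- chain_group(remaining, max_intron)
    out[[i]] <- cg$chain
    remaining <- remaining[-cg$used, , drop = FALSE]
  }
  dplyr::bind_rows(out)
}

#' Spliced alignment of contigs to genomic scaffolds
#'
#' Seed-matches contigs to scaffolds with BLASTN (e-value <= `e_max`) and
#' chains collinear HSPs on each (scaffold, strand), allowing target-side
#' gaps up to `max_intron` bp as introns. Chain identity is the
#' alignment-length-weighted mean HSP identity; coverage is the fraction of
#' the contig covered by chained HSPs.
#'
#' @param contigs Tibble with `contig_id`, `seq`.
#' @param scaffolds Named character vector of scaffold sequences.
#' @param e_max BLASTN e-value cutoff (default 1e-6).
#' @param max_intron Maximum intron (target gap) length in bp.
#' @return Tibble of chains (possibly several loci per contig), ranked by
#'   score within contig: columns query_id, scaffold, strand, q_start,
#'   q_end, t_start, t_end (0-based half-open), q_covered, coverage,
#'   identity, score, e_value, n_hsps, rank.
#' @export
spliced_align <- function(contigs, scaffolds, e_max = 1e-6,
                          max_intron = 2000L) {
  hits <- run_blast(setNames(contigs$seq, contigs$contig_id), scaffolds,
                    "blastn", e_max)
  if (nrow(hits) == 0) {
    return(tibble::tibble(query_id = character(), scaffold = character(),
                          strand = character(), q_start = integer(),
                          q_end = integer(), t_start = integer(),
                          t_end = integer(), q_covered = integer(),
                          coverage = double(), identity = double(),
                          score = double(), e_value = double(),
                          n_hsps = integer(), rank = integer()))
  }
  qlen <- setNames(nchar(contigs$seq), contigs$contig_id)
  parts <- split(hits, paste(hits$query_id, hits$target_id, hits$strand))
  chains <- purrr::map_dfr(parts, function(h) {
    cg <- chain_group_multi(h, max_intron)
    cg$query_id <- h$query_id[1]
    cg
  })
  chains <- chains %>%
    dplyr::mutate(coverage = .data$q_covered / qlen[.data$query_id]) %>%
    dplyr::arrange(.data$query_id, dplyr::desc(.data$score),
                   .data$scaffold, .data$t_start) %>%
    dplyr::group_by(.data$query_id) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup()
  chains
}

# Retain the ceiling(frac * n) highest-identity rows (plus ties at the
# realized cutoff); returns indices and the realized identity cutoff.
percentile_retain <- function(identity, frac = 0.95) {
  n <- length(identity)
  if (n == 0) return(list(keep = logical(0), cutoff = NA_real_))
  n_keep <- ceiling(frac * n)
  cutoff <- sort(identity, decreasing = TRUE)[n_keep]
  list(keep = identity >= cutoff, cutoff = cutoff)
}

# Group loci: same scaffold, overlapping target spans (single-linkage).
locus_groups <- function(best) {
  best <- best[order(best$scaffold, best$t_start), , drop = FALSE]
  grp <- integer(nrow(best)); g <- 0L
  cur_scaf <- ""; cur_end <- -Inf
  for (i in seq_len(nrow(best))) {
    if (best$scaffold[i] != cur_scaf || best$t_start[i] >= cur_end) {
      g <- g + 1L
      cur_scaf <- best$scaffold[i]; cur_end <- best$t_end[i]
    } else {
      cur_end <- max(cur_end, best$t_end[i])
    }
    grp[i] <- g
  }
  split(best$query_id, grp)
}

classify_contig <- function(chain, models, utr_max_dist, utr_min_cov) {
  m <- models[models$scaffold == chain$scaffold, , drop = FALSE]
  # chain t interval is 0-based half-open; models are 1-based inclusive
  t_lo <- chain$t_start + 1L; t_hi <- chain$t_end
  if (nrow(m) > 0) {
    ov <- pmin(t_hi, m$end) - pmax(t_lo, m$start) + 1L
    if (any(ov > 0)) {
      ref <- m$gene_id[which.max(ov)]
      return(list(category = "gene_model_annotated", reference_id = ref))
    }
    dist <- pmax(m$start - t_hi, t_lo - m$end)
    near <- which(dist <= utr_max_dist)
    if (length(near) > 0 && chain$coverage >= utr_min_cov) {
      ref <- m$gene_id[near[which.min(dist[near])]]
      return(list(category = "utr", reference_id = ref))
    }
  }
  list(category = "unannotated_genomic", reference_id = chain$scaffold)
}

# Chimera rule on chained loci: a secondary locus chain whose query span
# extends > min_outside bp beyond the primary chain's query span with
# identity above the threshold flags the contig.
chain_chimera <- function(chains, mode = "relative", min_outside = 50L,
                          identity_ratio = 0.8) {
  prim <- chains[chains$rank == 1, , drop = FALSE]
  sec <- chains[chains$rank > 1, , drop = FALSE]
  if (nrow(sec) == 0) {
    return(setNames(rep(FALSE, nrow(prim)), prim$query_id))
  }
  s <- dplyr::left_join(sec, prim %>%
                          dplyr::select("query_id", p_qs = "q_start",
                                        p_qe = "q_end", p_id = "identity"),
                        by = "query_id")
  overlap <- pmax(0L, pmin(s$q_end, s$p_qe) - pmax(s$q_start, s$p_qs))
  outside <- (s$q_end - s$q_start) - overlap
  cutoff <- if (mode == "relative") identity_ratio * s$p_id else identity_ratio
  flagged <- unique(s$query_id[outside > min_outside & s$identity > cutoff])
  setNames(prim$query_id %in% flagged, prim$query_id)
}

#' Genome-reference-guided re-assembly and classification
#'
#' Pipeline for contigs not retained by the protein path: spliced-align to
#' scaffolds, retain the top `retain_frac` of contigs by alignment
#' identity (the realized identity cutoff is a data-dependent output,
#' recorded in the result), merge contigs sharing an overlapping genomic
#' locus, re-align and re-filter the merged set, drop chimeras, and
#' classify each retained contig as `gene_model_annotated` (overlapping a
#' gene model), `utr` (within `utr_max_dist` bp of a model with at least
#' `utr_min_cov` of its length aligned) or `unannotated_genomic`.
#'
#' @param contigs Tibble with `contig_id`, `seq`.
#' @param scaffolds Named character vector of scaffolds.
#' @param gene_models Gene-model tibble (`gene_id`, `scaffold`, `start`,
#'   `end`, `strand`; 1-based inclusive).
#' @param e_max BLASTN e-value cutoff.
#' @param retain_frac Fraction retained by the percentile rule (0.95).
#' @param merge_identity,min_overlap Merge thresholds (see
#'   [merge_overlapping()]).
#' @param max_intron Maximum intron size for chaining.
#' @param utr_max_dist,utr_min_cov UTR classification rule (1 kb, 90\%).
#' @param chimera_mode Passed to the chain-level chimera rule.
#' @return List with `retained` (tibble: contig_id, seq, category,
#'   reference_id, identity, coverage), `discarded` (contig_id, reason),
#'   `members`, and `identity_cutoffs` (realized first/second-pass
#'   cutoffs).
#' @export
genome_reassemble <- function(contigs, scaffolds, gene_models,
                              e_max = 1e-6, retain_frac = 0.95,
                              merge_identity = 0.95, min_overlap = 40L,
                              max_intron = 2000L, utr_max_dist = 1000L,
                              utr_min_cov = 0.90,
                              chimera_mode = c("relative", "absolute")) {
  chimera_mode <- match.arg(chimera_mode)
  discards <- list()
  empty <- list(retained = tibble::tibble(contig_id = character(),
                                          seq = character(),
                                          category = character(),
                                          reference_id = character(),
                                          identity = double(),
                                          coverage = double()),
                discarded = tibble::tibble(contig_id = character(),
                                           reason = character()),
                members = tibble::tibble(contig_id = character(),
                                         member_id = character()),
                identity_cutoffs = c(NA_real_, NA_real_))
  if (nrow(contigs) == 0) return(empty)

  chains <- spliced_align(contigs, scaffolds, e_max, max_intron)
  no_hit <- setdiff(contigs$contig_id, chains$query_id)
  if (length(no_hit) > 0) {
    discards$no_hit <- tibble::tibble(contig_id = no_hit,
                                      reason = "no_genomic_hit")
  }
  best <- chains[chains$rank == 1, , drop = FALSE]
  if (nrow(best) == 0) {
    empty$discarded <- dplyr::bind_rows(discards)
    return(empty)
  }
  p1 <- percentile_retain(best$identity, retain_frac)
  if (any(!p1$keep)) {
    discards$p1 <- tibble::tibble(contig_id = best$query_id[!p1$keep],
                                  reason = "below_identity_percentile")
  }
  best <- best[p1$keep, , drop = FALSE]

  seqs <- setNames(contigs$seq, contigs$contig_id)
  groups <- locus_groups(best)
  merged_rows <- list(); member_rows <- list()
  group_span <- list()
  for (g in seq_along(groups)) {
    ids <- groups[[g]]
    m <- merge_overlapping(tibble::tibble(contig_id = ids, seq = seqs[ids]),
                           overlap_identity_min = merge_identity,
                           min_overlap = min_overlap)
    merged_rows[[g]] <- m$contigs
    member_rows[[g]] <- m$members
    sp <- best[best$query_id %in% ids, , drop = FALSE]
    for (id in m$contigs$contig_id) {
      group_span[[id]] <- list(scaffold = sp$scaffold[1],
                               t_start = min(sp$t_start),
                               t_end = max(sp$t_end))
    }
  }
  merged <- dplyr::bind_rows(merged_rows)
  members <- dplyr::bind_rows(member_rows)

  re <- spliced_align(merged, scaffolds, e_max, max_intron)
  lost <- setdiff(merged$contig_id, re$query_id)
  if (length(lost) > 0) {
    discards$lost <- tibble::tibble(contig_id = lost,
                                    reason = "lost_alignment")
  }
  re_best <- re[re$rank == 1, , drop = FALSE]
  same_locus <- vapply(seq_len(nrow(re_best)), function(i) {
    sp <- group_span[[re_best$query_id[i]]]
    re_best$scaffold[i] == sp$scaffold &&
      re_best$t_start[i] < sp$t_end && re_best$t_end[i] > sp$t_start
  }, logical(1))
  if (any(!same_locus)) {
    discards$moved <- tibble::tibble(
      contig_id = re_best$query_id[!same_locus],
      reason = "annotation_changed")
  }
  re_best <- re_best[same_locus, , drop = FALSE]

  p2 <- percentile_retain(re_best$identity, retain_frac)
  if (any(!p2$keep)) {
    discards$p2 <- tibble::tibble(contig_id = re_best$query_id[!p2$keep],
                                  reason = "below_identity_percentile")
  }
  re_best <- re_best[p2$keep, , drop = FALSE]

  chim <- chain_chimera(re[re$query_id %in% re_best$query_id, , drop = FALSE],
                        mode = chimera_mode)
  chim_ids <- names(chim)[chim]
  if (length(chim_ids) > 0) {
    discards$chim <- tibble::tibble(contig_id = chim_ids,
                                    reason = "chimeric")
    re_best <- re_best[!re_best$query_id %in% chim_ids, , drop = FALSE]
  }

  merged_seqs <- setNames(merged$seq, merged$contig_id)
  cls <- lapply(seq_len(nrow(re_best)), function(i)
    classify_contig(re_best[i, ], gene_models, utr_max_dist, utr_min_cov))
  retained <- tibble::tibble(
    contig_id = re_best$query_id,
    seq = unname(merged_seqs[re_best$query_id]),
    category = vapply(cls, `[[`, character(1), "category"),
    reference_id = vapply(cls, `[[`, character(1), "reference_id"),
    identity = re_best$identity,
    coverage = re_best$coverage)
  list(retained = retained,
       discarded = if (length(discards) > 0) dplyr::bind_rows(discards) else
         tibble::tibble(contig_id = character(), reason = character()),
       members = members,
       identity_cutoffs = c(first = p1$cutoff, second = p2$cutoff))
}
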