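# Protein-reference-guided re-assembly: translated best hits, CAP3-style
# within-reference merging, annotation verification, identity filtering and
# chimera removal.

#' Translated best hits of contigs against a protein reference set
#'
#' Six-frame translated local search (BLASTX) of each contig against the
#' non-redundant protein set; hits with e-value above `e_max` are not
#' reported. The best hit per contig is the lowest e-value, with ties
#' broken by bit score then target id.
#'
#' @param contigs Tibble with `contig_id`, `seq`.
#' @param proteins Named character vector of protein sequences.
#' @param e_max E-value cutoff (default 1e-6).
#' @return List with `hits` (all HSPs), `best` (one row per matched
#'   contig) and `unmatched` (contig ids without a qualifying hit).
#' @export
translated_best_hits <- function(contigs, proteins, e_max = 1e-6) {
  long_enough <- nchar(contigs$seq) >= 3
  hits <- if (any(long_enough) && length(proteins) > 0) {
    run_blast(setNames(contigs$seq[long_enough],
                       contigs$contig_id[long_enough]),
              proteins, "blastx", e_max)
  } else empty_hits()
  hits <- hits[hits$e_value <= e_max, , drop = FALSE]
  list(hits = hits, best = best_hits(hits),
       unmatched = setdiff(contigs$contig_id, hits$query_id))
}

#' Flag chimeric contigs from their alignment hit sets
#'
#' A contig is chimeric when some non-primary hit extends more than
#' `min_outside` bp beyond the primary (best) hit's query interval and its
#' identity exceeds `identity_ratio` times the primary hit's identity
#' (`mode = "relative"`, the default) or an absolute identity of
#' `identity_ratio` (`mode = "absolute"`). Contigs with no hits are not
#' chimeric.
#'
#' @param hits Hit tibble (as from [run_blast()]) covering one or more
#'   query contigs.
#' @param mode `"relative"` or `"absolute"` interpretation of the identity
#'   threshold.
#' @param min_outside Minimum bp of the secondary alignment outside the
#'   primary query interval (strict `>`, default 50).
#' @param identity_ratio Identity threshold factor (default 0.8).
#' @return Tibble with `query_id`, `chimeric`.
#' @export
detect_chimera <- function(hits, mode = c("relative", "absolute"),
                           min_outside = 50L, identity_ratio = 0.8) {
  mode <- match.arg(mode)
  if (nrow(hits) == 0) {
    return(tibble::tibble(query_id = character(), chimeric = logical()))
  }
  prim <- best_hits(hits)
  h <- dplyr::left_join(hits, prim %>%
                          dplyr::select("query_id", p_start = "q_start",
                                        p_end = "q_end", p_id = "identity",
                                        p_target = "target_id",
                                        p_score = "bit_score"),
                        by = "query_id")
  overlap <- pmax(0L, pmin(h$q_end, h$p_end) - pmax(h$q_start, h$p_start))
  outside <- (h$q_end - h$q_start) - overlap
  cutoff <- if (mode == "relative") identity_ratio * h$p_id else identity_ratio
  is_primary <- h$q_start == h$p_start & h$q_end == h$p_end &
    h$target_id == h$p_target & h$bit_score == h$p_score
  flag <- !is_primary & outside > min_outside & h$identity > cutoff
  h %>%
    dplyr::mutate(flag = flag) %>%
    dplyr::group_by(.data$query_id) %>%
    dplyr::summarise(chimeric = any(.data$flag), .groups = "drop")
}

#' Protein-reference-guided re-assembly
#'
#' Groups contigs by their best protein reference, merges overlapping
#' group members (overlap identity > `merge_identity`), re-aligns the
#' merged contigs, and retains only those whose best hit still matches the
#' group's original reference at e-value <= `e_max` with identity >
#' `identity_min`; contigs flagged by the chimera rule are then discarded.
#' Every discard is logged with a reason (`annotation_changed`,
#' `low_identity`, `lost_alignment`, `chimeric`).
#'
#' @param contigs Tibble with `contig_id`, `seq`.
#' @param proteins Named character vector of protein sequences.
#' @param e_max E-value cutoff (default 1e-6).
#' @param identity_min Minimum identity to the matching reference (strict
#'   `>`, default 0.70).
#' @param merge_identity Overlap identity required for merging (strict
#'   `>`, default 0.95).
#' @param min_overlap Minimum merge overlap in bp (default 40).
#' @param chimera_mode Passed to [detect_chimera()].
#' @return List with `retained` (tibble: contig_id, seq, reference_id,
#'   identity, e_value), `discarded` (tibble: contig_id, reason),
#'   `members` (merged-to-input mapping) and `unmatched` (contig ids with
#'   no initial protein hit, the genome path's input).
#' @export
protein_reassemble <- function(contigs, proteins, e_max = 1e-6,
                               identity_min = 0.70, merge_identity = 0.95,
                               min_overlap = 40L,
                               chimera_mode = c("relative", "absolute")) {
  chimera_mode <- match.arg(chimera_mode)
  tb <- translated_best_hits(contigs, proteins, e_max)
  if (nrow(tb$best) == 0) {
    return(list(retained = tibble::tibble(contig_id = character(),
                                          seq = character(),
                                          reference_id = character(),
                                          identity = double(),
                                          e_value = double()),
                discarded = tibble::tibble(contig_id = character(),
                                           reason = character()),
                members = tibble::tibble(contig_id = character(),
                                         member_id = character()),
                unmatched = tb$unmatched))
  }
  seqs <- setNames(contigs$seq, contigs$contig_id)
  groups <- split(tb$best$query_id, tb$best$target_id)

  merged_rows <- list(); member_rows <- list(); group_ref <- character(0)
  for (ref in names(groups)) {
    ids <- groups[[ref]]
    m <- merge_overlapping(tibble::tibble(contig_id = ids, seq = seqs[ids]),
                           overlap_identity_min = merge_identity,
                           min_overlap = min_overlap)
    merged_rows[[ref]] <- m$contigs
    member_rows[[ref]] <- m$members
    group_ref <- c(group_ref, setNames(rep(ref, nrow(m$contigs)),
                                       m$contigs$contig_id))
  }
  merged <- dplyr::bind_rows(merged_rows)
  members <- dplyr::bind_rows(member_rows)

  re <- translated_best_hits(merged, proteins, e_max)
  best <- re$best
  discards <- list()
  lost <- setdiff(merged$contig_id, best$query_id)
  if (length(lost) > 0) {
    discards$lost <- tibble::tibble(contig_id = lost,
                                    reason = "lost_alignment")
  }
  best$orig_ref <- unname(group_ref[best$query_id])
  changed <- best$target_id != best$orig_ref
  low <- !changed & best$identity <= identity_min
  if (any(changed)) {
    discards$changed <- tibble::tibble(contig_id = best$query_id[changed],
                                       reason = "annotation_changed")
  }
  if (any(low)) {
    discards$low <- tibble::tibble(contig_id = best$query_id[low],
                                   reason = "low_identity")
  }
  ok <- best[!changed & !low, , drop = FALSE]

  chim <- detect_chimera(re$hits[re$hits$query_id %in% ok$query_id, ,
                                 drop = FALSE], mode = chimera_mode)
  chim_ids <- chim$query_id[chim$chimeric]
  if (length(chim_ids) > 0) {
    discards$chim <- tibble::tibble(contig_id = chim_ids,
                                    reason = "chimeric")
    ok <- ok[!ok$query_id %in% chim_ids, , drop = FALSE]
  }

  merged_seqs <- setNames(merged$seq, merged$contig_id)
  list(retained = tibble::tibble(contig_id = ok$query_id,
                                 seq = unname(merged_seqs[ok$query_id]),
                                 reference_id = ok$target_id,
                                 identity = ok$identity,
                                 e_value = ok$e_value),
       discarded = if (length(discards) > 0) dplyr::bind_rows(discards) else
         tibble::tibble(contig_id = character(), reason = character()),
       members = members,
       unmatched = tb$unmatched)
}
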