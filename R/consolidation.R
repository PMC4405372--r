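# Within-stage redundancy elimination and the overlap-consensus merge
# primitive shared by the protein- and genome-guided re-assembly paths.

nuc_mat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

# Identity between two sequences over the alignable region, computed as
# matching bases of the best local alignment divided by the shorter
# sequence's length (CD-HIT-EST convention for contained fragments).
pair_identity <- function(a, b) {
  # exact containment short-circuits the DP
  short <- if (nchar(a) <= nchar(b)) a else b
  long <- if (nchar(a) <= nchar(b)) b else a
  if (regexpr(short, long, fixed = TRUE) > 0) return(1)
  sw <- .sw_local(a, b, 1, -1, -2)
  sw[, 2] / pmin(nchar(a), nchar(b))
}

#' Cluster contigs within a life stage and keep the longest representatives
#'
#' Greedy longest-first clustering: contigs are sorted by decreasing length
#' (ties by lexicographically smaller id); each contig joins the first
#' existing representative to which its identity over the shorter
#' sequence's alignable region meets the threshold, otherwise it founds a
#' new cluster. Representatives are therefore always the longest member.
#' Candidate representatives are pre-selected by shared exact 20-mers.
#'
#' @param contigs Tibble with `contig_id`, `seq` (and optionally `stage`,
#'   which must be a single value).
#' @param identity_threshold Identity fraction (default 0.99).
#' @return List with `representatives` (tibble subset of `contigs`) and
#'   `clusters` (tibble: representative_id, member_id, identity).
#' @export
cluster_within_stage <- function(contigs, identity_threshold = 0.99) {
  check_fraction(identity_threshold, "identity_threshold")
  if ("stage" %in% names(contigs) && dplyr::n_distinct(contigs$stage) > 1) {
    stop("contigs must share one stage label", call. = FALSE)
  }
  if (nrow(contigs) == 0) {
    return(list(representatives = contigs,
                clusters = tibble::tibble(representative_id = character(),
                                          member_id = character(),
                                          identity = double())))
  }
  ord <- order(-nchar(contigs$seq), contigs$contig_id)
  contigs <- contigs[ord, , drop = FALSE]
  k <- 20L
  kmer_env <- new.env(parent = emptyenv())
  rep_idx <- integer(0)
  assign_rep <- integer(nrow(contigs))
  identities <- numeric(nrow(contigs))

  contig_kmers <- function(seq, step = 1L) {
    n <- nchar(seq)
    if (n < k) return(substr(seq, 1, n))
    unique(substring(seq, seq(1L, n - k + 1L, by = step),
                     seq(k, n, by = step)))
  }

  for (i in seq_len(nrow(contigs))) {
    query_kmers <- contig_kmers(contigs$seq[i], step = 1L)
    cand <- unique(unlist(lapply(query_kmers, function(km) {
      if (exists(km, envir = kmer_env, inherits = FALSE)) {
        get(km, envir = kmer_env)
      } else integer(0)
    }), use.names = FALSE))
    cand <- sort(cand)
    joined <- FALSE
    for (r in cand) {
      id <- pair_identity(contigs$seq[i], contigs$seq[r])
      if (id >= identity_threshold) {
        assign_rep[i] <- r
        identities[i] <- id
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      assign_rep[i] <- i
      identities[i] <- 1
      rep_idx <- c(rep_idx, i)
      for (km in contig_kmers(contigs$seq[i], step = 10L)) {
        prev <- if (exists(km, envir = kmer_env, inherits = FALSE)) {
          get(km, envir = kmer_env)
        } else integer(0)
        assign(km, c(prev, i), envir = kmer_env)
      }
    }
  }

  list(representatives = contigs[rep_idx, , drop = FALSE],
       clusters = tibble::tibble(
         representative_id = contigs$contig_id[assign_rep],
         member_id = contigs$contig_id,
         identity = identities))
}

# Exact containment or suffix-prefix overlap (identity 1); NULL if none.
exact_overlap <- function(ida, a, idb, bb, min_overlap) {
  la <- nchar(a); lb <- nchar(bb)
  mk <- function(ps, pe, ss, se) {
    ov <- substr(a, ps, pe)
    list(ids = c(ida, idb), a = a, b = bb, ps = ps, pe = pe, ss = ss,
         se = se, pal = ov, sal = ov, cols = nchar(ov), identity = 1)
  }
  if (lb <= la) {
    p <- regexpr(bb, a, fixed = TRUE)
    if (p > 0) return(mk(p, p + lb - 1L, 1L, lb))
  } else {
    p <- regexpr(a, bb, fixed = TRUE)
    if (p > 0) {
      ov <- a
      return(list(ids = c(ida, idb), a = a, b = bb, ps = 1L, pe = la,
                  ss = p, se = p + la - 1L, pal = ov, sal = ov,
                  cols = la, identity = 1))
    }
  }
  best <- NULL
  # suffix of a / prefix of b
  probe <- substr(bb, 1, min_overlap)
  occ <- gregexpr(probe, a, fixed = TRUE)[[1]]
  if (occ[1] > 0) {
    for (p in occ) {
      len <- la - p + 1L
      if (len < min_overlap || len > lb) next
      if (substr(a, p, la) == substr(bb, 1, len)) {
        if (is.null(best) || len > best$cols) best <- mk(p, la, 1L, len)
      }
    }
  }
  # suffix of b / prefix of a
  probe <- substr(a, 1, min_overlap)
  occ <- gregexpr(probe, bb, fixed = TRUE)[[1]]
  if (occ[1] > 0) {
    for (p in occ) {
      len <- lb - p + 1L
      if (len < min_overlap || len > la) next
      if (substr(bb, p, lb) == substr(a, 1, len)) {
        if (is.null(best) || len > best$cols) {
          ov <- substr(a, 1, len)
          best <- list(ids = c(ida, idb), a = a, b = bb, ps = 1L, pe = len,
                       ss = p, se = lb, pal = ov, sal = ov, cols = len,
                       identity = 1)
        }
      }
    }
  }
  best
}

shares_word <- function(a, b, k = 16L) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  ka <- unique(substring(a, 1:(nchar(a) - k + 1L), k:nchar(a)))
  kb <- unique(substring(b, 1:(nchar(b) - k + 1L), k:nchar(b)))
  any(kb %in% ka)
}

# Best qualifying ends-free overlap between two sequences; NULL if none.
# Exact containment/suffix-prefix overlaps short-circuit the DP.
best_overlap <- function(ida, a, idb, b, identity_min, min_overlap) {
  best <- NULL
  for (orient in c("f", "r")) {
    bb <- if (orient == "f") b else revcomp(b)
    ex <- exact_overlap(ida, a, idb, bb, min_overlap)
    if (!is.null(ex)) {
      if (is.null(best) || ex$cols > best$cols) best <- ex
      next
    }
    if (!shares_word(a, bb)) next
    aln <- Biostrings::pairwiseAlignment(
      a, bb, type = "overlap", substitutionMatrix = nuc_mat(),
      gapOpening = 0, gapExtension = 2)
    pa <- Biostrings::pattern(aln); sa <- Biostrings::subject(aln)
    ps <- BiocGenerics::start(pa); pe <- BiocGenerics::end(pa)
    ss <- BiocGenerics::start(sa); se <- BiocGenerics::end(sa)
    la <- nchar(a); lb <- nchar(bb)
    # at least one sequence must be flush on each side of the overlap
    if ((ps > 1 && ss > 1) || (pe < la && se < lb)) next
    pal <- as.character(pa); sal <- as.character(sa)
    cols <- nchar(pal)
    if (cols < min_overlap) next
    matches <- sum(strsplit(pal, "")[[1]] == strsplit(sal, "")[[1]])
    identity <- matches / cols
    if (identity <= identity_min) next
    cand <- list(ids = c(ida, idb), a = a, b = bb, ps = ps, pe = pe,
                 ss = ss, se = se, pal = pal, sal = sal, cols = cols,
                 identity = identity)
    if (is.null(best) || cols > best$cols) best <- cand
  }
  best
}

merge_two <- function(ov, longer_is_a) {
  ca <- strsplit(ov$pal, "")[[1]]
  cb <- strsplit(ov$sal, "")[[1]]
  cons <- ifelse(ca == cb, ca, ifelse(ca == "-", cb,
                                      ifelse(cb == "-", ca,
                                             if (longer_is_a) ca else cb)))
  cons <- cons[cons != "-"]
  left <- if (ov$ps > 1) substr(ov$a, 1, ov$ps - 1) else
    substr(ov$b, 1, ov$ss - 1)
  right <- if (ov$pe < nchar(ov$a)) substr(ov$a, ov$pe + 1, nchar(ov$a)) else
    substr(ov$b, ov$se + 1, nchar(ov$b))
  paste0(left, paste(cons, collapse = ""), right)
}

#' Merge overlapping contigs to consensus (CAP3-style contract)
#'
#' Iteratively merges the pair with the longest suffix-prefix or
#' containment overlap whose overlap identity exceeds the threshold and
#' whose overlap spans at least `min_overlap` bp, taking the per-column
#' majority (ties resolved from the longer parent), until no qualifying
#' pair remains. Both orientations of each partner are considered. Contigs
#' with no qualifying overlap pass through unchanged.
#'
#' @param group Tibble with `contig_id`, `seq`; the caller is responsible
#'   for grouping contigs by shared reference.
#' @param overlap_identity_min Overlap identity threshold (strict `>`,
#'   default 0.95).
#' @param min_overlap Minimum overlap length in bp (default 40).
#' @return List with `contigs` (merged tibble: contig_id, seq) and
#'   `members` (tibble: contig_id, member_id mapping output to inputs).
#' @export
merge_overlapping <- function(group, overlap_identity_min = 0.95,
                              min_overlap = 40L) {
  check_fraction(overlap_identity_min, "overlap_identity_min")
  seqs <- setNames(as.list(group$seq), group$contig_id)
  members <- setNames(as.list(group$contig_id), group$contig_id)
  repeat {
    ids <- names(seqs)
    if (length(ids) < 2) break
    best <- NULL
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        ov <- best_overlap(ids[i], seqs[[i]], ids[j], seqs[[j]],
                           overlap_identity_min, min_overlap)
        if (!is.null(ov) && (is.null(best) || ov$cols > best$cols)) best <- ov
      }
    }
    if (is.null(best)) break
    la <- nchar(best$a); lb <- nchar(best$b)
    merged <- merge_two(best, longer_is_a = la >= lb)
    keep_id <- if (la >= lb) best$ids[1] else best$ids[2]
    drop_id <- setdiff(best$ids, keep_id)
    members[[keep_id]] <- c(members[[keep_id]], members[[drop_id]])
    members[[drop_id]] <- NULL
    seqs[[drop_id]] <- NULL
    seqs[[keep_id]] <- merged
  }
  list(contigs = tibble::tibble(contig_id = names(seqs),
                                seq = unlist(seqs, use.names = FALSE)),
       members = tibble::tibble(
         contig_id = rep(names(members), lengths(members)),
         member_id = unlist(members, use.names = FALSE)))
}
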