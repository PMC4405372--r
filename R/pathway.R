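# Pathway-level statistics: length-bias-corrected enrichment, exact
# proportion comparisons, Z-score heat-map matrices and the
# diapause-incidence statistic.

#' Length-bias-corrected pathway over-representation
#'
#' Corrects for the selection bias of DE calls toward long transcripts:
#' a monotone non-decreasing probability-weighting function P(DE | length)
#' is fitted to the binary DE flags by isotonic regression on length; for
#' each pathway, the over-representation p-value is the fraction of
#' weighted random gene sets (drawn without replacement with inclusion
#' probability proportional to the fitted weight, of the same size as the
#' observed genome-wide DE set) containing at least the observed number of
#' pathway DE genes, with a +1/(n+1) continuity correction; BH correction
#' across pathways; a pathway is reported enriched when it holds at least
#' `min_de` DE genes and its FDR is below `fdr_cutoff`.
#'
#' @param de Tibble with `gene_id` and logical `is_de` for every measured
#'   gene.
#' @param gene_lengths Named vector of transcript lengths (bp) covering
#'   every gene in `de`.
#' @param pathways Tibble with `pathway_id`, `gene_id` (members outside
#'   the measured universe are ignored; pathways with no measured member
#'   are skipped with a warning).
#' @param n_resamples Number of weighted resamples (default 100,000).
#' @param min_de Minimum DE genes for the enrichment call (default 5).
#' @param fdr_cutoff FDR threshold for the enrichment call (default 0.05).
#' @param seed Optional seed for the resampling stream.
#' @return A `tx_enrichment` tibble: pathway_id, n_pathway,
#'   n_de_in_pathway, p_over, fdr, enriched.
#' @export
length_bias_enrichment <- function(de, gene_lengths, pathways,
                                   n_resamples = 1e5, min_de = 5L,
                                   fdr_cutoff = 0.05, seed = NULL) {
  if (!all(de$gene_id %in% names(gene_lengths))) {
    stop("every measured gene needs a length", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  genes <- de$gene_id
  flags <- as.logical(de$is_de)
  lens <- gene_lengths[genes]
  n_de <- sum(flags)

  # monotone P(DE | length) by isotonic regression, averaged over ties
  ord <- order(lens)
  iso <- isoreg(lens[ord], as.numeric(flags[ord]))
  w <- numeric(length(genes))
  w[ord] <- iso$yf
  w <- pmax(w, 1e-8)

  measured <- split(pathways$gene_id[pathways$gene_id %in% genes],
                    pathways$pathway_id[pathways$gene_id %in% genes])
  skipped <- setdiff(unique(pathways$pathway_id), names(measured))
  if (length(skipped) > 0) {
    warning("skipping pathway(s) with no measured members: ",
            paste(skipped, collapse = ", "))
  }
  if (length(measured) == 0 || n_de == 0) {
    out <- tibble::tibble(pathway_id = names(measured),
                          n_pathway = lengths(measured),
                          n_de_in_pathway = vapply(measured, function(g)
                            sum(flags[match(g, genes)]), integer(1)),
                          p_over = 1, fdr = 1, enriched = FALSE)
    class(out) <- c("tx_enrichment", class(out))
    return(out)
  }

  memb <- vapply(measured, function(g) genes %in% g,
                 logical(length(genes)))
  obs <- as.integer(crossprod(memb, flags))

  exceed <- integer(length(measured))
  n_resamples <- as.integer(n_resamples)
  for (b in seq_len(n_resamples)) {
    s <- sample.int(length(genes), n_de, prob = w)
    cnt <- colSums(memb[s, , drop = FALSE])
    exceed <- exceed + (cnt >= obs)
  }
  p_over <- (exceed + 1) / (n_resamples + 1)
  fdr <- bh_adjust(p_over)
  out <- tibble::tibble(pathway_id = names(measured),
                        n_pathway = unname(lengths(measured)),
                        n_de_in_pathway = obs,
                        p_over = unname(p_over), fdr = unname(fdr),
                        enriched = obs >= min_de & fdr < fdr_cutoff)
  class(out) <- c("tx_enrichment", class(out))
  out
}

#' Two-sided Fisher's exact test for two proportions
#'
#' Exact test of the 2x2 table `[[k1, n1-k1], [k2, n2-k2]]` with
#' two-sidedness by the minimum-likelihood convention: the p-value sums
#' the hypergeometric probabilities of all tables (at fixed margins) no
#' more probable than the observed one.
#'
#' @param k1,n1 Successes and total in the first group.
#' @param k2,n2 Successes and total in the second group.
#' @return The two-sided exact p-value.
#' @export
fisher_proportion_test <- function(k1, n1, k2, n2) {
  counts <- c(k1 = k1, n1 = n1, k2 = k2, n2 = n2)
  if (any(counts < 0) || k1 > n1 || k2 > n2 ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers with k <= n", call. = FALSE)
  }
  k_tot <- k1 + k2
  support <- max(0, k_tot - n2):min(n1, k_tot)
  pr <- dhyper(support, n1, n2, k_tot)
  obs <- dhyper(k1, n1, n2, k_tot)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

#' Row-standardize an expression matrix and order by hierarchical clustering
#'
#' Each row is centered and scaled to unit sample standard deviation
#' (constant rows map to all zeros); rows and columns are ordered by
#' complete-linkage hierarchical clustering of Euclidean distances,
#' giving a deterministic heat-map layout.
#'
#' @param expr Numeric matrix (genes x libraries, >= 2 libraries).
#' @return List with `z` (standardized matrix), `row_order`, `col_order`.
#' @export
zscore_matrix <- function(expr) {
  if (ncol(expr) < 2) stop("need at least 2 libraries", call. = FALSE)
  mu <- rowMeans(expr)
  s <- apply(expr, 1, sd)
  z <- (expr - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  row_order <- if (nrow(z) > 1) hclust(dist(z), method = "complete")$order
  else 1L
  col_order <- if (ncol(z) > 1) hclust(dist(t(z)), method = "complete")$order
  else 1L
  list(z = z, row_order = row_order, col_order = col_order)
}

#' Diapause incidence
#'
#' The fraction of embryonated unhatched (diapause) eggs among all viable
#' eggs: `DI = embryonated_unhatched / (hatched + embryonated_unhatched)`.
#'
#' @param hatched Number of hatched eggs.
#' @param embryonated_unhatched Number of embryonated but unhatched eggs.
#' @return The diapause incidence in `[0, 1]` (vectorized).
#' @export
diapause_incidence <- function(hatched, embryonated_unhatched) {
  if (any(hatched < 0) || any(embryonated_unhatched < 0)) {
    stop("egg counts must be non-negative", call. = FALSE)
  }
  tot <- hatched + embryonated_unhatched
  if (any(tot == 0)) {
    stop("diapause incidence undefined when no viable eggs were observed",
         call. = FALSE)
  }
  embryonated_unhatched / tot
}
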