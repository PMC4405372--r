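# Differential expression under the 2x2 factorial design: TMM
# normalization, low-expression filtering, qCML negative-binomial
# dispersion estimation, the conditional exact test on quantile-adjusted
# pseudo-counts, the GLM likelihood-ratio interaction test, BH correction
# and voom-style MDS.

#' Log2 counts per million
#'
#' @param counts Count matrix (genes x libraries).
#' @param lib_sizes Effective library sizes (default column sums).
#' @param prior Prior count added before the log (default 0.25).
#' @return Matrix of log2 CPM values.
#' @export
log2_cpm <- function(counts, lib_sizes = colSums(counts), prior = 0.25) {
  t(log2(t(counts + prior) / lib_sizes * 1e6))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-library scaling: the reference library
#' is the one whose count upper quartile (library-size scaled) is closest
#' to the mean upper quartile; each library's factor is 2 to the weighted
#' trimmed mean of per-gene log ratios (M) against the reference, trimming
#' 30\% of M and 5\% of A two-sided, with inverse asymptotic binomial
#' variance weights; factors are rescaled to geometric mean 1.
#'
#' @param counts Count matrix (genes x libraries).
#' @param lib_sizes Library sizes (default column sums).
#' @return Named vector of normalization factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts)) {
  if (ncol(counts) < 2) stop("need at least 2 libraries", call. = FALSE)
  zero <- lib_sizes == 0
  if (any(zero)) {
    stop("all-zero library: ", colnames(counts)[zero][1], call. = FALSE)
  }
  uq <- apply(counts, 2, function(y) quantile(y, 0.75)) / lib_sizes
  ref <- which.min(abs(uq - mean(uq)))
  one_factor <- function(j) {
    yo <- counts[, j]; yr <- counts[, ref]
    no <- lib_sizes[j]; nr <- lib_sizes[ref]
    keep <- yo > 0 & yr > 0
    yo <- yo[keep]; yr <- yr[keep]
    if (length(yo) == 0) return(1)
    m <- log2((yo / no) / (yr / nr))
    a <- 0.5 * log2((yo / no) * (yr / nr))
    w <- (no - yo) / (no * yo) + (nr - yr) / (nr * yr)
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
    rm_ <- rank(m); ra <- rank(a)
    sel <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(sel)) return(1)
    2^(sum(w[sel] * m[sel]) / sum(w[sel]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / geometric_mean(f)
  setNames(f, colnames(counts))
}

#' Filter rarely expressed genes
#'
#' Keeps genes whose log2 CPM meets `min_log2cpm` in at least `min_libs`
#' libraries (the smallest group size of the design). Setting
#' `literal = TRUE` instead discards genes with log2 CPM below the cutoff
#' in at least `min_libs` libraries.
#'
#' @param counts Count matrix.
#' @param lib_sizes Effective library sizes (library size x TMM factor).
#' @param min_log2cpm Log2 CPM cutoff (default 1).
#' @param min_libs Library count for the rule (default 4).
#' @param literal Use the literal discard reading (default FALSE).
#' @return List with `counts` (filtered matrix), `n_kept`, `n_discarded`.
#' @export
filter_low <- function(counts, lib_sizes = colSums(counts),
                       min_log2cpm = 1, min_libs = 4L, literal = FALSE) {
  lc <- log2_cpm(counts, lib_sizes)
  keep <- if (literal) {
    rowSums(lc < min_log2cpm) < min_libs
  } else {
    rowSums(lc >= min_log2cpm) >= min_libs
  }
  list(counts = counts[keep, , drop = FALSE], n_kept = sum(keep),
       n_discarded = sum(!keep))
}

# Quantile-quantile mapping of counts to a common library size on the
# negative-binomial scale (pseudo-counts), with a continuity correction.
equalize_counts <- function(counts, lib_sizes, phi) {
  common <- geometric_mean(lib_sizes)
  lambda <- rowSums(counts) / sum(lib_sizes)
  mu_in <- outer(lambda, lib_sizes)
  mu_out <- lambda * common
  p <- if (phi > 0) {
    pnbinom(counts, mu = mu_in, size = 1 / phi) -
      0.5 * dnbinom(counts, mu = mu_in, size = 1 / phi)
  } else {
    ppois(counts, mu_in) - 0.5 * stats::dpois(counts, mu_in)
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  pseudo <- if (phi > 0) {
    qnbinom(p, mu = mu_out, size = 1 / phi)
  } else {
    qpois(p, mu_out)
  }
  pseudo[mu_in == 0] <- 0
  dimnames(pseudo) <- dimnames(counts)
  list(pseudo = pseudo, common_lib_size = common)
}

# Conditional log-likelihood of iid NB replicates given their sum, as a
# function of dispersion phi (r = 1/phi); rows = genes.
cond_ll_matrix <- function(pseudo, groups, phis) {
  out <- matrix(0, nrow = nrow(pseudo), ncol = length(phis))
  for (g in unique(groups)) {
    y <- pseudo[, groups == g, drop = FALSE]
    n <- ncol(y)
    if (n < 2) next
    t_g <- rowSums(y)
    for (k in seq_along(phis)) {
      r <- 1 / phis[k]
      out[, k] <- out[, k] +
        rowSums(lgamma(y + r)) - n * lgamma(r) +
        lgamma(n * r) - lgamma(t_g + n * r)
    }
  }
  out
}

#' Estimate common and tagwise negative-binomial dispersions
#'
#' Quantile-adjusted conditional maximum likelihood: counts are mapped to
#' a common library size (pseudo-counts), and the dispersion maximizing
#' the conditional likelihood given each group's sum is found on a grid;
#' tagwise dispersions maximize the per-gene conditional likelihood plus
#' `prior_n` times the average (shrinkage toward the common value).
#'
#' @param counts Filtered count matrix.
#' @param design Design tibble (groups = photoperiod x bloodmeal cells).
#' @param lib_sizes Effective library sizes (default: column sums times
#'   TMM factors).
#' @param prior_n Shrinkage weight in genes (default 10).
#' @return List with `common`, `tagwise` (named vector), `pseudo` (matrix),
#'   `common_lib_size`, `groups`.
#' @export
estimate_dispersion <- function(counts, design, lib_sizes = NULL,
                                prior_n = 10) {
  validate_design(design)
  design <- design[match(colnames(counts), design$library_id), ]
  groups <- paste(design$photoperiod, design$bloodmeal, sep = ".")
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(counts) * tmm_factors(counts)
  }
  if (min(table(groups)) < 2) {
    warning("some groups have a single replicate; ",
            "tagwise dispersions fall back to the common value")
  }
  counts <- round(counts)
  grid <- seq(0.001, 0.95, length.out = 80)
  phis <- grid / (1 - grid)
  phi <- 0.1
  for (round_i in 1:2) {
    eq <- equalize_counts(counts, lib_sizes, phi)
    cll <- cond_ll_matrix(eq$pseudo, groups, phis)
    tot <- colSums(cll)
    phi <- phis[which.max(tot)]
    # local refinement around the grid maximum
    k <- which.max(tot)
    lo <- phis[max(1, k - 1)]; hi <- phis[min(length(phis), k + 1)]
    op <- optimize(function(ph) {
      sum(cond_ll_matrix(eq$pseudo, groups, ph))
    }, c(lo, hi), maximum = TRUE)
    phi <- op$maximum
  }
  eq <- equalize_counts(counts, lib_sizes, phi)
  cll <- cond_ll_matrix(eq$pseudo, groups, phis)
  shrunk <- cll + prior_n * matrix(colMeans(cll), nrow = nrow(cll),
                                   ncol = ncol(cll), byrow = TRUE)
  tagwise <- phis[apply(shrunk, 1, which.max)]
  list(common = phi,
       tagwise = setNames(tagwise, rownames(counts)),
       pseudo = eq$pseudo, common_lib_size = eq$common_lib_size,
       groups = setNames(groups, colnames(counts)),
       lib_sizes = lib_sizes)
}

# Two-sided conditional NB exact test for equal-size groups
# (minimum-likelihood two-sidedness). Sums of nA / nB iid NB(m, phi)
# replicates are NB with size nA/phi / nB/phi.
nb_exact_p <- function(s_a, n_a, s_b, n_b, phi) {
  t_tot <- s_a + s_b
  if (t_tot == 0) return(1)
  if (t_tot > 2e6) stop("conditional total too large for enumeration",
                        call. = FALSE)
  m <- t_tot / (n_a + n_b)
  a <- 0:t_tot
  lp <- if (phi > 0) {
    dnbinom(a, mu = n_a * m, size = n_a / phi, log = TRUE) +
      dnbinom(t_tot - a, mu = n_b * m, size = n_b / phi, log = TRUE)
  } else {
    dpois(a, n_a * m, log = TRUE) + dpois(t_tot - a, n_b * m, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[s_a + 1] * (1 + 1e-10)])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]` (NA allowed and propagated).
#' @return Adjusted values, order preserved, monotone in the step-up
#'   sense, never smaller than the input.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  x <- p[ok]
  n <- length(x)
  if (n > 0) {
    o <- order(x)
    adj <- pmin(1, rev(cummin(rev(x[o] * n / seq_len(n)))))
    tmp <- numeric(n)
    tmp[o] <- adj
    out[ok] <- tmp
  }
  out
}

#' Pairwise negative-binomial exact test between two design cells
#'
#' Computes, per gene, the conditional exact test on quantile-adjusted
#' pseudo-counts at the gene's shrunk dispersion, a prior-damped log2 fold
#' change from normalized group means, BH-corrected FDR, and the DE call
#' (|log2 FC| > `lfc_cutoff` and FDR < `fdr_cutoff`).
#'
#' @param counts Filtered count matrix.
#' @param design Design tibble.
#' @param contrast Length-2 character vector of cell labels
#'   (`"SD.BM"`, `"SD.NB"`, `"LD.BM"`, `"LD.NB"`); fold changes are
#'   `contrast[1]` over `contrast[2]`.
#' @param dispersion Optional result of [estimate_dispersion()] (computed
#'   if missing).
#' @param lfc_cutoff,fdr_cutoff DE call rule (defaults 0.5 and 0.05).
#' @param prior_count Prior added to group means for the fold change.
#' @return A `tx_de` object; `tidy()` returns the per-gene table.
#' @export
nb_pairwise_test <- function(counts, design, contrast,
                             dispersion = NULL, lfc_cutoff = 0.5,
                             fdr_cutoff = 0.05, prior_count = 0.5) {
  validate_design(design)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, design)
  groups <- dispersion$groups[colnames(counts)]
  if (!all(contrast %in% groups)) {
    stop("unknown group label in contrast: ",
         paste(setdiff(contrast, groups), collapse = ", "), call. = FALSE)
  }
  a_cols <- names(groups)[groups == contrast[1]]
  b_cols <- names(groups)[groups == contrast[2]]
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    stop("each contrast group needs at least 2 libraries", call. = FALSE)
  }
  pseudo <- dispersion$pseudo[rownames(counts), , drop = FALSE]
  s_a <- rowSums(pseudo[, a_cols, drop = FALSE])
  s_b <- rowSums(pseudo[, b_cols, drop = FALSE])
  phi <- dispersion$tagwise[rownames(counts)]
  p <- vapply(seq_len(nrow(pseudo)), function(i) {
    nb_exact_p(s_a[i], length(a_cols), s_b[i], length(b_cols), phi[i])
  }, numeric(1))
  log_fc <- log2((s_a / length(a_cols) + prior_count) /
                   (s_b / length(b_cols) + prior_count))
  log_cpm <- log2((s_a + s_b) / (length(c(a_cols, b_cols)) *
                                   dispersion$common_lib_size) * 1e6 + 1e-9)
  fdr <- bh_adjust(p)
  tab <- tibble::tibble(unigene_id = rownames(counts),
                        log_fc = log_fc, log_cpm = log_cpm,
                        fold_change = 2^log_fc,
                        p_value = p, fdr = fdr,
                        is_de = abs(log_fc) > lfc_cutoff & fdr < fdr_cutoff)
  structure(list(table = tab, contrast = contrast,
                 dispersion_common = dispersion$common,
                 lfc_cutoff = lfc_cutoff, fdr_cutoff = fdr_cutoff),
            class = "tx_de")
}

#' GLM likelihood-ratio test of the photoperiod x blood-meal interaction
#'
#' Fits, per gene, the negative-binomial log-linear model
#' `photoperiod + bloodmeal + photoperiod:bloodmeal` with effective
#' library-size offsets at the gene's shrunk dispersion, and tests the
#' interaction term by a 1-df likelihood-ratio test; p-values are
#' BH-corrected. Genes whose IRLS fit does not converge get NA p-values
#' and are reported.
#'
#' @param counts Filtered count matrix.
#' @param design Design tibble (full 2x2).
#' @param dispersion Optional [estimate_dispersion()] result.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @return A `tx_interaction` object with the per-gene table (interaction
#'   log2 FC, per-photoperiod fold changes in each blood-meal state,
#'   p_value, fdr) and `nonconverged` gene ids.
#' @export
interaction_test <- function(counts, design, dispersion = NULL,
                             max_iter = 100L) {
  validate_design(design)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, design)
  design <- design[match(colnames(counts), design$library_id), ]
  pp <- factor(design$photoperiod, levels = c("LD", "SD"))
  bm <- factor(design$bloodmeal, levels = c("NB", "BM"))
  off <- log(dispersion$lib_sizes)
  phi <- pmax(dispersion$tagwise[rownames(counts)], 1e-4)

  fit_one <- function(y, theta) {
    fam <- MASS::negative.binomial(theta = theta)
    full <- glm(y ~ pp * bm + offset(off), family = fam,
                control = list(maxit = max_iter))
    null <- glm(y ~ pp + bm + offset(off), family = fam,
                control = list(maxit = max_iter))
    if (!full$converged || !null$converged) return(c(NA_real_, NA_real_))
    lrt <- null$deviance - full$deviance
    c(pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
      coef(full)[["ppSD:bmBM"]] / log(2))
  }
  y <- round(counts)
  res <- t(vapply(seq_len(nrow(y)), function(i) {
    tryCatch(fit_one(y[i, ], 1 / phi[i]),
             error = function(e) c(NA_real_, NA_real_))
  }, numeric(2)))
  p <- res[, 1]

  # descriptive per-cell fold changes (photoperiod effect within each
  # blood-meal state), normalized means with a small prior
  cells <- dispersion$groups[colnames(counts)]
  pseudo <- dispersion$pseudo[rownames(counts), , drop = FALSE]
  cell_mean <- function(cell) {
    cols <- names(cells)[cells == cell]
    rowMeans(pseudo[, cols, drop = FALSE])
  }
  lfc_nb <- log2((cell_mean("SD.NB") + 0.5) / (cell_mean("LD.NB") + 0.5))
  lfc_bm <- log2((cell_mean("SD.BM") + 0.5) / (cell_mean("LD.BM") + 0.5))

  tab <- tibble::tibble(unigene_id = rownames(counts),
                        log_fc_interaction = res[, 2],
                        log_fc_photoperiod_nb = lfc_nb,
                        log_fc_photoperiod_bm = lfc_bm,
                        p_value = p, fdr = bh_adjust(p))
  structure(list(table = tab,
                 nonconverged = rownames(counts)[is.na(p)]),
            class = "tx_interaction")
}

#' Classical MDS of voom-style transformed counts
#'
#' Transforms counts to log2 CPM with a 0.5 prior on effective library
#' sizes, takes the `n_top` most variable genes, and embeds the libraries
#' in two dimensions by classical (Torgerson) multidimensional scaling of
#' their Euclidean distances.
#'
#' @param counts Count matrix (>= 3 libraries).
#' @param design Optional design tibble joined onto the coordinates.
#' @param n_top Number of most-variable genes used (default 500).
#' @param lib_sizes Effective library sizes (default: column sums times
#'   TMM factors).
#' @return A `tx_mds` tibble with `library_id`, `dim1`, `dim2` (and the
#'   design columns when supplied).
#' @export
mds_coordinates <- function(counts, design = NULL, n_top = 500L,
                            lib_sizes = NULL) {
  if (ncol(counts) < 3) stop("need at least 3 libraries", call. = FALSE)
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(counts) * tmm_factors(counts)
  }
  lc <- log2_cpm(counts, lib_sizes, prior = 0.5)
  v <- apply(lc, 1, var)
  top <- head(order(v, decreasing = TRUE), n_top)
  d <- dist(t(lc[top, , drop = FALSE]))
  xy <- cmdscale(d, k = 2)
  if (ncol(xy) < 2) {
    warning("distance matrix has rank < 2; second coordinate zeroed")
    xy <- cbind(xy, 0)
  }
  out <- tibble::tibble(library_id = colnames(counts),
                        dim1 = xy[, 1], dim2 = xy[, 2])
  if (!is.null(design)) {
    out <- dplyr::left_join(out, design, by = "library_id")
  }
  class(out) <- c("tx_mds", class(out))
  out
}
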