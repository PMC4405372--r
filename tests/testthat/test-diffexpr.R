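test_that("TMM factors have geometric mean 1 and absorb library size", {
  set.seed(91)
  design <- make_design(16)
  counts <- sim_counts(1000, design)$counts
  f <- tmm_factors(counts)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

  # two identical libraries -> factors all 1
  dup <- cbind(a = counts[, 1], b = counts[, 1])
  expect_equal(unname(tmm_factors(dup)), c(1, 1))

  # doubling a library's counts is absorbed by the library size
  dbl <- cbind(a = counts[, 1], b = 2 * counts[, 1])
  expect_equal(unname(tmm_factors(dbl)), c(1, 1))

  # all-zero library errors by name
  z <- counts; z[, 3] <- 0
  expect_error(tmm_factors(z), colnames(counts)[3])
})

test_that("TMM matches a brute-force weighted trimmed mean and edgeR", {
  set.seed(92)
  design <- make_design(8)
  counts <- sim_counts(2000, design)$counts
  # double a known 20% subset in library 2
  idx <- sample(2000, 400)
  counts[idx, 2] <- counts[idx, 2] * 2
  f <- tmm_factors(counts)

  # brute-force recomputation of every library's weighted trimmed mean
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(y) quantile(y, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  raw <- vapply(seq_len(ncol(counts)), function(j) {
    yo <- counts[, j]; yr <- counts[, ref]
    keep <- yo > 0 & yr > 0
    yo <- yo[keep]; yr <- yr[keep]
    m <- log2((yo / lib[j]) / (yr / lib[ref]))
    if (max(abs(m)) < 1e-6) return(1)
    a <- 0.5 * log2((yo / lib[j]) * (yr / lib[ref]))
    w <- (lib[j] - yo) / (lib[j] * yo) + (lib[ref] - yr) / (lib[ref] * yr)
    n <- length(m)
    sel <- rank(m) >= floor(0.3 * n) + 1 & rank(m) <= n - floor(0.3 * n) &
      rank(a) >= floor(0.05 * n) + 1 & rank(a) <= n - floor(0.05 * n)
    2^(sum(w[sel] * m[sel]) / sum(w[sel]))
  }, numeric(1))
  expect_equal(unname(f), raw / exp(mean(log(raw))), tolerance = 1e-10)

  # independent implementation: edgeR's TMM on the same matrix
  fe <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_lt(max(abs(f - fe)), 0.02)
})

test_that("the expression filter applies the adopted and literal readings", {
  lib <- rep(1e6, 16)
  counts <- rbind(
    zero = rep(0, 16),
    boundary = c(rep(8, 4), rep(1, 12)),   # log2 CPM 3 in exactly 4 libs
    low3 = c(rep(3, 3), rep(0, 13)))       # log2 CPM ~1.5 in only 3 libs
  colnames(counts) <- sprintf("lib%02d", 1:16)
  filt <- filter_low(counts, lib)
  expect_identical(rownames(filt$counts), "boundary")
  expect_equal(filt$n_discarded, 2)
  # the literal reading of the discard sentence removes nearly everything
  lit <- filter_low(counts, lib, literal = TRUE)
  expect_equal(lit$n_kept, 0)
})

test_that("dispersion estimation recovers the truth", {
  set.seed(93)
  design <- make_design(16)
  # Poisson data -> estimate near zero
  pois <- sim_counts(2000, design, dispersion = 0)$counts
  d0 <- estimate_dispersion(pois, design)
  expect_lt(d0$common, 0.05)
  # NB at 0.2 -> estimate in [0.15, 0.25]
  nb <- sim_counts(2000, design, dispersion = 0.2)$counts
  d2 <- estimate_dispersion(nb, design)
  expect_gt(d2$common, 0.15)
  expect_lt(d2$common, 0.25)
  # identical replicate columns -> estimate at the lower boundary
  flat <- matrix(rep(rpois(300, 50), 16), ncol = 16,
                 dimnames = list(NULL, design$library_id))
  dflat <- estimate_dispersion(flat, design, lib_sizes = rep(1e4, 16))
  expect_lt(dflat$common, 0.005)
})

test_that("the exact test is symmetric, null-calibrated and Poisson-consistent", {
  set.seed(94)
  design <- make_design(16)
  counts <- sim_counts(500, design, dispersion = 0.1)$counts
  disp <- estimate_dispersion(counts, design)
  de_ab <- nb_pairwise_test(counts, design, c("SD.NB", "LD.NB"),
                            dispersion = disp)
  de_ba <- nb_pairwise_test(counts, design, c("LD.NB", "SD.NB"),
                            dispersion = disp)
  expect_equal(tidy(de_ab)$log_fc, -tidy(de_ba)$log_fc)
  expect_equal(tidy(de_ab)$p_value, tidy(de_ba)$p_value, tolerance = 1e-12)

  # identical groups: no DE calls, fold changes ~0
  same <- counts
  same[, design$photoperiod == "SD"] <-
    same[, design$photoperiod == "LD"]
  d_same <- estimate_dispersion(same, design)
  de_same <- nb_pairwise_test(same, design, c("SD.NB", "LD.NB"),
                              dispersion = d_same)
  expect_equal(sum(tidy(de_same)$is_de), 0)

  # Poisson limit: the conditional test equals the exact binomial test
  for (case in list(c(8, 12), c(30, 14), c(3, 40))) {
    p_nb <- diapauseTx:::nb_exact_p(case[1], 4, case[2], 4, phi = 0)
    p_bin <- stats::binom.test(case[1], case[1] + case[2], 0.5)$p.value
    expect_equal(p_nb, p_bin, tolerance = 1e-9)
  }
})

test_that("unknown contrast labels and small groups are rejected", {
  set.seed(95)
  design <- make_design(16)
  counts <- sim_counts(50, design)$counts
  disp <- estimate_dispersion(counts, design)
  expect_error(nb_pairwise_test(counts, design, c("XX.NB", "LD.NB"),
                                dispersion = disp), "unknown group")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # against the independent reference implementation on random vectors
  # and on all permutations of a fixed set of <= 6 values
  set.seed(96)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  vals <- c(0.001, 0.02, 0.02, 0.3, 0.7, 1)
  for (i in 1:40) {
    p <- sample(vals)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # pointwise dominance and NA propagation
  p <- runif(30)
  expect_true(all(bh_adjust(p) >= p))
  pna <- c(0.01, NA, 0.5)
  expect_true(is.na(bh_adjust(pna)[2]))
})

test_that("MDS embeds exactly in the 3-library case and separates groups", {
  set.seed(97)
  design <- make_design(16)
  sim <- sim_counts(800, design, dispersion = 0.05, fold = 6,
                    de_frac = 0.3)
  counts <- sim$counts
  # two identical libraries have distance zero in the transformed space
  dup <- counts; dup[, 2] <- dup[, 1]
  lc <- log2_cpm(dup, colSums(dup), prior = 0.5)
  expect_equal(dist(t(lc[, 1:2]))[1], 0)

  # three libraries always embed exactly in 2-D
  three <- counts[, 1:3]
  lc3 <- log2_cpm(three, colSums(three) * tmm_factors(three), prior = 0.5)
  v <- apply(lc3, 1, var)
  top <- head(order(v, decreasing = TRUE), 500)
  d_in <- dist(t(lc3[top, ]))
  m3 <- mds_coordinates(three, n_top = 500)
  d_out <- dist(as.matrix(m3[, c("dim1", "dim2")]))
  expect_equal(as.vector(d_out), as.vector(d_in), tolerance = 1e-9)

  # strong group effects: replicates cluster by photoperiod
  m <- mds_coordinates(counts, design)
  xy <- as.matrix(m[, c("dim1", "dim2")])
  grp <- design$photoperiod
  within <- mean(dist(xy[grp == "SD", ])) + mean(dist(xy[grp == "LD", ]))
  between <- mean(as.matrix(dist(xy))[grp == "SD", grp == "LD"])
  expect_lt(within / 2, between)
})
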