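test_that("enrichment p-values match the hypergeometric tail at equal lengths", {
  set.seed(101)
  genes <- sprintf("g%03d", 1:200)
  de <- tibble::tibble(gene_id = genes,
                       is_de = c(rep(TRUE, 30), rep(FALSE, 170)))
  lens <- setNames(rep(1000, 200), genes)
  pw <- tibble::tibble(
    pathway_id = rep(c("enriched", "null"), each = 20),
    gene_id = c(genes[c(1:10, 101:110)], genes[c(25:30, 111:124)]))
  e <- length_bias_enrichment(de, lens, pw, n_resamples = 30000, seed = 5)
  for (pid in e$pathway_id) {
    row <- e[e$pathway_id == pid, ]
    hyp <- phyper(row$n_de_in_pathway - 1, 30, 170, row$n_pathway,
                  lower.tail = FALSE)
    mc_sd <- sqrt(hyp * (1 - hyp) / 30000)
    expect_lt(abs(row$p_over - hyp), 4 * mc_sd + 2e-4)
  }
})

test_that("the enrichment reporting rule is applied", {
  set.seed(102)
  genes <- sprintf("g%03d", 1:100)
  de <- tibble::tibble(gene_id = genes,
                       is_de = genes %in% genes[1:12])
  lens <- setNames(rep(500, 100), genes)
  # a pathway whose 4 DE members give p < 0.001 but fail the >= 5 rule
  pw <- tibble::tibble(pathway_id = "small",
                       gene_id = genes[c(1:4, 99)])
  e <- length_bias_enrichment(de, lens, pw, n_resamples = 20000, seed = 6)
  expect_lt(e$p_over, 0.001)
  expect_false(e$enriched)

  # zero DE members: p >= 0.5, not enriched
  pw0 <- tibble::tibble(pathway_id = "cold", gene_id = genes[50:70])
  e0 <- length_bias_enrichment(de, lens, pw0, n_resamples = 5000, seed = 7)
  expect_gte(e0$p_over, 0.5)
  expect_false(e0$enriched)

  # pathways without measured members are skipped with a warning
  pw_bad <- tibble::tibble(pathway_id = c("ok", "ghost"),
                           gene_id = c(genes[1], "not_measured"))
  expect_warning(length_bias_enrichment(de, lens, pw_bad,
                                        n_resamples = 1000, seed = 8),
                 "ghost")
})

test_that("the isotonic weighting function matches a PAVA oracle and is monotone", {
  set.seed(103)
  for (rep_i in 1:5) {
    n <- sample(8:20, 1)
    lens <- sort(runif(n, 100, 5000))
    flags <- runif(n) < (lens / max(lens)) * 0.6
    iso <- isoreg(lens, as.numeric(flags))
    expect_equal(iso$yf, pava_oracle(as.numeric(flags)), tolerance = 1e-12)
    expect_true(all(diff(iso$yf) >= -1e-12))
  }
})

test_that("enrichment p-values are super-uniform under a permutation null", {
  set.seed(104)
  genes <- sprintf("g%03d", 1:100)
  lens <- setNames(seq(200, 5000, length.out = 100), genes)
  # length-biased DE flags (long genes more often DE), fixed pathway
  base_flags <- runif(100) < 0.05 + 0.25 * (seq_len(100) / 100)
  pw <- tibble::tibble(pathway_id = "p", gene_id = genes[seq(5, 100, by = 5)])
  n_perm <- 400
  pvals <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    # permute flags among genes of similar length (within blocks),
    # respecting the length bias the weighting function models
    perm <- as.vector(vapply(split(seq_len(100),
                                   rep(1:10, each = 10)),
                             sample, integer(10)))
    de <- tibble::tibble(gene_id = genes, is_de = base_flags[perm])
    e <- length_bias_enrichment(de, lens, pw, n_resamples = 400,
                                seed = 104 + b)
    pvals[b] <- e$p_over
  }
  expect_lte(mean(pvals < 0.05), 0.07)
})

test_that("the exact proportion test reproduces fisher.test and is symmetric", {
  set.seed(105)
  for (i in 1:25) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    mine <- fisher_proportion_test(k1, n1, k2, n2)
    ref <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2,
                              byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
    # symmetry under simultaneous row and column swap
    expect_equal(mine, fisher_proportion_test(n2 - k2, n2, n1 - k1, n1),
                 tolerance = 1e-12)
  }
  expect_equal(fisher_proportion_test(10, 100, 10, 100), 1)
  expect_error(fisher_proportion_test(-1, 10, 2, 10), "non-negative")
  expect_error(fisher_proportion_test(11, 10, 2, 10), "non-negative")
})

test_that("Z-score rows are standardized and clustering order is deterministic", {
  expect_equal(unname(zscore_matrix(rbind(c(1, 2, 3), c(4, 5, 6)))$z[1, ]),
               c(-1, 0, 1))
  m <- rbind(a = c(5, 5, 5), b = c(1, 3, 9), c = c(9, 3, 1))
  z <- zscore_matrix(m)
  expect_equal(unname(z$z["a", ]), c(0, 0, 0))
  rm <- rowMeans(z$z)
  expect_true(all(abs(rm) < 1e-12))
  sds <- apply(z$z, 1, sd)
  expect_true(all(abs(sds - 1) < 1e-12 | sds == 0))
  z2 <- zscore_matrix(m)
  expect_identical(z$row_order, z2$row_order)
  expect_error(zscore_matrix(m[, 1, drop = FALSE]), "2 libraries")
})

test_that("diapause incidence follows its definition", {
  expect_equal(diapause_incidence(0, 10), 1)
  expect_equal(diapause_incidence(10, 0), 0)
  expect_equal(diapause_incidence(70, 30), 0.3)
  expect_equal(diapause_incidence(c(70, 50), c(30, 50)), c(0.3, 0.5))
  expect_error(diapause_incidence(0, 0), "undefined")
  expect_error(diapause_incidence(-1, 5), "non-negative")
})
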