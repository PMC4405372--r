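make_pairs <- function(seq1, seq2 = NULL) {
  n <- length(seq1)
  # mates are independent clean sequences unless given explicitly
  if (is.null(seq2)) seq2 <- random_reads(n, nchar(seq1))
  tibble::tibble(pair_id = sprintf("p%03d", seq_len(n)),
                 seq1 = seq1, qual1 = strrep("I", nchar(seq1)),
                 seq2 = seq2, qual2 = strrep("I", nchar(seq2)))
}

test_that("contaminant screening applies the identity/score rules per database", {
  set.seed(21)
  vec <- setNames(random_reads(1, 400), "vecA")
  adp <- setNames(random_reads(1, 33), "adpA")
  clean <- random_reads(4, 101)

  # mate 1 carries an exact 30 bp vector substring -> pair removed
  contaminated <- paste0(substr(clean[1], 1, 71), substr(vec, 101, 130))
  pairs <- make_pairs(c(contaminated, clean[2]))
  res <- screen_contaminants(pairs, vec, adp)
  expect_equal(nrow(res$retained), 1)
  expect_equal(res$log$pair_id, "p001")
  expect_equal(res$log$database, "vector")

  # adapter match with one mismatch over 30 bp: not removed (100% rule)
  adp30 <- substr(adp, 1, 30)
  substr(adp30, 15, 15) <- ifelse(substr(adp30, 15, 15) == "A", "C", "A")
  near_adp <- paste0(substr(clean[3], 1, 71), adp30)
  res2 <- screen_contaminants(make_pairs(near_adp), character(0), adp)
  expect_equal(nrow(res2$retained), 1)
  # the exact adapter IS removed
  exact <- paste0(substr(clean[3], 1, 71), substr(adp, 1, 30))
  res3 <- screen_contaminants(make_pairs(exact), character(0), adp)
  expect_equal(nrow(res3$retained), 0)

  # no databases: identity operation
  pairs4 <- make_pairs(clean)
  res4 <- screen_contaminants(pairs4, character(0), character(0))
  expect_identical(res4$retained, pairs4)

  # pair integrity: contamination on mate 2 removes the whole pair
  pairs5 <- make_pairs(clean[1], paste0(substr(vec, 51, 121),
                                        substr(clean[2], 1, 30)))
  res5 <- screen_contaminants(pairs5, vec, character(0))
  expect_equal(nrow(res5$retained), 0)
  expect_equal(res5$log$mate, 2)
})

test_that("quality trimming returns the longest high-quality run", {
  # whole read qualifies
  r <- tibble::tibble(id = "a", seq = strrep("A", 101),
                      qual = qual_string(rep(40, 101)))
  expect_identical(quality_trim(r), r)

  # no qualifying base
  r2 <- tibble::tibble(id = "b", seq = strrep("A", 101),
                       qual = qual_string(rep(2, 101)))
  expect_equal(nrow(quality_trim(r2)), 0)

  # constructed runs of 30 / 60 / 45 above threshold -> the 60 bp run
  q <- c(rep(40, 30), 10, rep(40, 60), 10, rep(40, 45))
  r3 <- tibble::tibble(id = "c", seq = strrep("G", length(q)),
                       qual = qual_string(q))
  out <- quality_trim(r3)
  expect_equal(nchar(out$seq), 60)
  expect_equal(out$qual, qual_string(rep(40, 60)))

  # mismatched lengths are a validation error
  r4 <- tibble::tibble(id = "d", seq = "ACGT", qual = "III")
  expect_error(quality_trim(r4), "length mismatch")
})

test_that("trimming equals the exhaustive-substring oracle", {
  set.seed(33)
  pol <- trim_policy(min_len = 10L, min_phred = 30L)
  for (i in 1:50) {
    q <- sample(c(2:40), 60, replace = TRUE)
    r <- tibble::tibble(id = "x", seq = random_reads(1, 60),
                        qual = qual_string(q))
    oracle <- trim_oracle(r$qual, pol$min_phred)
    out <- quality_trim(r, pol)
    if (oracle[2] > pol$min_len) {
      expect_equal(nchar(out$seq), oracle[2])
      expect_equal(out$seq, substr(r$seq, oracle[1], oracle[1] + oracle[2] - 1))
    } else {
      expect_equal(nrow(out), 0)
    }
  }
})

test_that("digital normalization keeps exactly C copies of a duplicated read", {
  set.seed(44)
  r <- random_reads(1, 101)
  reads <- tibble::tibble(id = as.character(1:100), seq = rep(r, 100))
  kept <- digital_normalize(reads, diginorm_policy(20, 20))
  expect_equal(nrow(kept), 20)

  # all-distinct reads sharing no k-mer are all kept
  distinct <- tibble::tibble(id = as.character(1:50),
                             seq = random_reads(50, 101))
  expect_equal(nrow(digital_normalize(distinct)), 50)

  # empty stream
  empty <- distinct[0, ]
  expect_equal(nrow(digital_normalize(empty)), 0)
})

test_that("diginorm matches an independent replay of the streaming counter", {
  set.seed(55)
  base <- random_reads(6, 50)
  reads <- sample(rep(base, times = c(30, 10, 5, 2, 1, 25)))
  pol <- diginorm_policy(k = 15L, coverage_cutoff = 5L)
  keep_pkg <- digital_normalize(tibble::tibble(id = as.character(
    seq_along(reads)), seq = reads), pol)
  keep_oracle <- diginorm_oracle(reads, pol$k, pol$coverage_cutoff)
  expect_identical(keep_pkg$id, as.character(which(keep_oracle)))
  # output is a subsequence no larger than the input
  expect_lte(nrow(keep_pkg), length(reads))

  # reads shorter than k are kept unconditionally
  short <- tibble::tibble(id = as.character(1:30),
                          seq = rep(substr(base[1], 1, 10), 30))
  expect_equal(nrow(digital_normalize(short, pol)), 30)

  # paired rule: a pair is kept when either mate is under the cutoff
  p <- tibble::tibble(pair_id = as.character(1:30),
                      seq1 = rep(base[1], 30), qual1 = strrep("I", 50),
                      seq2 = random_reads(30, 50), qual2 = strrep("I", 50))
  keptp <- digital_normalize(p, pol)
  expect_equal(nrow(keptp), 30)  # mate 2 always novel
})
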