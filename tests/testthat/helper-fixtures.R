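# Shared fixtures and independent oracles used across test files.

# Small, fast simulation configuration for unit tests.
tiny_config <- function(seed = 1L, mean_library_size = 400L, ...) {
  sim_config(seed = seed, n_genes = 12L, n_scaffolds = 2L,
             mean_library_size = mean_library_size, n_pathways = 4L,
             pathway_size_range = c(3L, 6L), ...)
}

# A balanced 2x2 design tibble for n libraries (multiple of 4).
make_design <- function(n = 16L) {
  d <- tidyr::expand_grid(photoperiod = c("SD", "LD"),
                          bloodmeal = c("BM", "NB"),
                          replicate = seq_len(n / 4L))
  tibble::tibble(library_id = sprintf("lib%02d", seq_len(n)), d)
}

# NB count matrix with optional planted fold change on the SD libraries.
sim_counts <- function(n_genes, design, dispersion = 0.1, fold = 1,
                       de_frac = 0, base_meanlog = log(100)) {
  mu <- rlnorm(n_genes, base_meanlog, 1)
  mumat <- outer(mu, rep(1, nrow(design)))
  de_idx <- seq_len(round(de_frac * n_genes))
  if (length(de_idx) > 0 && fold != 1) {
    sd_cols <- design$photoperiod == "SD"
    mumat[de_idx, sd_cols] <- mumat[de_idx, sd_cols] * fold
  }
  counts <- matrix(
    if (dispersion > 0) {
      rnbinom(length(mumat), mu = mumat, size = 1 / dispersion)
    } else {
      rpois(length(mumat), mumat)
    },
    nrow = n_genes,
    dimnames = list(sprintf("g%04d", seq_len(n_genes)), design$library_id))
  list(counts = counts, de_idx = de_idx)
}

# Exhaustive-substring oracle for quality trimming: the longest substring
# whose bases all have phred > min_phred (leftmost on ties).
trim_oracle <- function(qual, min_phred, offset = 33L) {
  q <- utf8ToInt(qual) - offset
  n <- length(q)
  best <- c(0L, 0L)  # start, len
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(q[s:e] > min_phred)) {
        if (e - s + 1L > best[2]) best <- c(s, e - s + 1L)
      } else break
    }
  }
  best
}

# Pool-adjacent-violators oracle for isotonic regression (ties averaged by
# block pooling), independent of stats::isoreg.
pava_oracle <- function(y) {
  n <- length(y)
  val <- as.numeric(y)
  wt <- rep(1, n)
  i <- 1
  repeat {
    viol <- which(diff(val) < -1e-15)
    if (length(viol) == 0) break
    j <- viol[1]
    new_val <- (val[j] * wt[j] + val[j + 1] * wt[j + 1]) / (wt[j] + wt[j + 1])
    new_wt <- wt[j] + wt[j + 1]
    val <- c(val[seq_len(j - 1)], new_val,
             val[setdiff(seq_along(val), seq_len(j + 1))])
    wt <- c(wt[seq_len(j - 1)], new_wt,
            wt[setdiff(seq_along(wt), seq_len(j + 1))])
  }
  rep(val, wt)
}

# Replay oracle for the streaming diginorm rule, exact counting in R.
diginorm_oracle <- function(reads, k, cutoff) {
  tab <- new.env(parent = emptyenv())
  canon <- function(s) {
    rc <- revcomp(s)
    ifelse(s <= rc, s, rc)
  }
  keep <- logical(length(reads))
  for (i in seq_along(reads)) {
    n <- nchar(reads[i])
    if (n < k) { keep[i] <- TRUE; next }
    kms <- canon(substring(reads[i], 1:(n - k + 1), k:n))
    cnt <- vapply(kms, function(km) {
      if (exists(km, envir = tab, inherits = FALSE)) {
        get(km, envir = tab)
      } else 0L
    }, integer(1))
    med <- floor((sort(cnt)[(length(cnt) + 1) %/% 2] +
                    sort(cnt)[length(cnt) %/% 2 + 1]) / 2)
    keep[i] <- med < cutoff
    if (keep[i]) {
      for (km in kms) {
        prev <- if (exists(km, envir = tab, inherits = FALSE)) {
          get(km, envir = tab)
        } else 0L
        assign(km, prev + 1L, envir = tab)
      }
    }
  }
  keep
}

random_reads <- function(n, len = 101) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], TRUE), collapse = ""),
    character(1))
}

# Point substitutions at a fixed per-base rate (test-side implementation).
mutate_seq_oracle <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# Phred-33 quality string from integer vector.
qual_string <- function(q) intToUtf8(q + 33L)
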