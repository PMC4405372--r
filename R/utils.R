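# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("invalid `", name, "`: must be a fraction in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop("invalid `", name, "`: must be an integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
    stop("invalid `", name, "`: must be positive", call. = FALSE)
  }
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Reverse-complement nucleotide sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA of given lengths (uses the current RNG stream).
random_dna <- function(lengths, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(lengths, function(n) {
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# Point-mutate a sequence at a per-base rate (substitutions only).
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(alt, b), 1),
                         character(1))
  }
  paste(chars, collapse = "")
}

# All k-mers of a set of sequences as a tibble (kmer, seq_index, pos).
kmer_table <- function(seqs, k) {
  n <- nchar(seqs)
  idx <- rep(seq_along(seqs), times = pmax(n - k + 1L, 0L))
  pos <- unlist(lapply(pmax(n - k + 1L, 0L), seq_len), use.names = FALSE)
  tibble::tibble(kmer = substring(seqs[idx], pos, pos + k - 1L),
                 seq_index = idx, pos = pos)
}
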