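# File formats used across the pipeline: FASTQ (phred-33, 4-line records),
# FASTA, GFF-like gene-model tables, design / pathway / count TSVs.

#' Read a 4-line FASTQ file into a tibble
#'
#' @param path Path to an uncompressed phred-33 FASTQ file.
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ ", path, ": ", length(lines),
         " lines is not a multiple of 4", call. = FALSE)
  }
  n <- length(lines) / 4
  if (n == 0) return(tibble::tibble(id = character(), seq = character(),
                                    qual = character()))
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seq <- lines[seq(2, by = 4, length.out = n)]
  sep <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad) > 0) {
    stop("malformed FASTQ record ", bad[1], " in ", path, call. = FALSE)
  }
  tibble::tibble(id = sub("^@", "", hdr), seq = seq, qual = qual)
}

#' Write a tibble of reads as a 4-line FASTQ file
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  out <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  readr::write_lines(out, path)
  invisible(path)
}

#' Read and mate-join a FASTQ pair
#'
#' @param path1,path2 Mate-1 and mate-2 FASTQ paths (records in the same
#'   order; `/1`, `/2` suffixes are stripped to form the pair id).
#' @return A tibble with `pair_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (nrow(r1) != nrow(r2)) {
    stop("FASTQ mate files differ in record count", call. = FALSE)
  }
  tibble::tibble(pair_id = sub("/[12]$", "", r1$id),
                 seq1 = r1$seq, qual1 = r1$qual,
                 seq2 = r2$seq, qual2 = r2$qual)
}

#' Write paired reads as two FASTQ files
#'
#' @param pairs Tibble as returned by [read_fastq_pairs()].
#' @param path1,path2 Output paths for mates 1 and 2.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_fastq(tibble::tibble(id = paste0(pairs$pair_id, "/1"),
                             seq = pairs$seq1, qual = pairs$qual1), path1)
  write_fastq(tibble::tibble(id = paste0(pairs$pair_id, "/2"),
                             seq = pairs$seq2, qual = pairs$qual2), path2)
  invisible(c(path1, path2))
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80)
  invisible(path)
}

# GFF-like gene-model table: scaffold, source, feature, start, end, score,
# strand, frame, attribute ("gene_id=<id>"); 1-based inclusive coordinates.
gff_cols <- c("scaffold", "source", "feature", "start", "end", "score",
              "strand", "frame", "attribute")

#' Read a GFF-like gene-model table
#'
#' @param path TSV path (9 GFF-like columns, `gene_id=` attribute).
#' @return Tibble with `gene_id`, `scaffold`, `start`, `end`, `strand`
#'   (1-based inclusive).
#' @export
read_gene_models <- function(path) {
  g <- readr::read_tsv(path, col_names = gff_cols, comment = "#",
                       col_types = "ccciicccc", progress = FALSE)
  tibble::tibble(gene_id = sub("^gene_id=", "", g$attribute),
                 scaffold = g$scaffold, start = g$start, end = g$end,
                 strand = g$strand)
}

#' Write gene models as a GFF-like table
#'
#' @param models Tibble with `gene_id`, `scaffold`, `start`, `end`, `strand`.
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  g <- tibble::tibble(scaffold = models$scaffold, source = "diapauseTx",
                      feature = "gene", start = models$start,
                      end = models$end, score = ".", strand = models$strand,
                      frame = ".", attribute = paste0("gene_id=", models$gene_id))
  readr::write_tsv(g, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read the 2x2 factorial design table
#'
#' @param path TSV with columns library_id, photoperiod, bloodmeal, replicate.
#' @return Validated design tibble.
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, col_types = "ccci", progress = FALSE)
  validate_design(d)
}

#' Validate a 2x2 photoperiod-by-blood-meal design
#'
#' Checks factor levels (SD/LD, BM/NB) and equal replication per cell.
#'
#' @param design Design tibble.
#' @return The design, invisibly validated.
#' @export
validate_design <- function(design) {
  need <- c("library_id", "photoperiod", "bloodmeal", "replicate")
  if (!all(need %in% names(design))) {
    stop("design table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(design$photoperiod %in% c("SD", "LD"))) {
    stop("photoperiod levels must be SD or LD", call. = FALSE)
  }
  if (!all(design$bloodmeal %in% c("BM", "NB"))) {
    stop("bloodmeal levels must be BM or NB", call. = FALSE)
  }
  if (anyDuplicated(design$library_id)) {
    stop("duplicate library ids in design", call. = FALSE)
  }
  cells <- table(design$photoperiod, design$bloodmeal)
  if (length(unique(as.vector(cells))) != 1) {
    stop("design is unbalanced across the 2x2 cells", call. = FALSE)
  }
  invisible(design)
}

#' Read a pathway-membership table
#'
#' @param path TSV with columns pathway_id, gene_id (optionally pathway_name).
#' @return Tibble of pathway memberships.
#' @export
read_pathways <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}
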