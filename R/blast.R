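# Wrappers around the NCBI BLAST+ binaries used for translated protein
# search (blastx) and genomic seed search (blastn). Hit tables are
# normalized to 0-based half-open query/target intervals with fractional
# identities; all downstream rules (chimera, percentile retention, UTR
# classification, HSP chaining) are implemented in this package.

empty_hits <- function() {
  tibble::tibble(query_id = character(), target_id = character(),
                 identity = double(), aligned_length = integer(),
                 q_start = integer(), q_end = integer(),
                 t_start = integer(), t_end = integer(),
                 strand = character(), frame = integer(),
                 e_value = double(), bit_score = double())
}

blast_path <- function(tool) {
  p <- Sys.which(tool)
  if (!nzchar(p)) {
    stop("BLAST+ binary `", tool, "` not found on PATH", call. = FALSE)
  }
  p
}

#' Run a BLAST+ search between in-memory sequence sets
#'
#' @param query Named character vector of nucleotide query sequences.
#' @param db Named character vector of database sequences.
#' @param program `"blastx"` (protein db) or `"blastn"` (nucleotide db).
#' @param e_max E-value cutoff passed to BLAST.
#' @return Hit tibble with 0-based half-open `q_start`/`q_end` and
#'   `t_start`/`t_end` intervals, fractional `identity`, `strand`
#'   (target strand for blastn), `frame` (query frame for blastx),
#'   `e_value` and `bit_score`; one row per HSP.
#' @export
run_blast <- function(query, db, program = c("blastx", "blastn"),
                      e_max = 1e-6) {
  program <- match.arg(program)
  if (length(query) == 0 || length(db) == 0) return(empty_hits())
  dir <- tempfile("blast")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  qf <- file.path(dir, "query.fasta")
  dbf <- file.path(dir, "db.fasta")
  write_fasta(query, qf)
  write_fasta(db, dbf)
  dbtype <- if (program == "blastx") "prot" else "nucl"
  status <- system2(blast_path("makeblastdb"),
                    c("-in", dbf, "-dbtype", dbtype),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("makeblastdb failed", call. = FALSE)
  fmt <- "6 qseqid sseqid pident length qstart qend sstart send evalue bitscore qframe"
  args <- c("-query", qf, "-db", dbf, "-evalue", format(e_max),
            "-outfmt", shQuote(fmt), "-max_target_seqs", "500",
            "-num_threads", "1",
            if (program == "blastx") c("-seg", "no") else c("-dust", "no"))
  out <- file.path(dir, "hits.tsv")
  status <- system2(blast_path(program), args, stdout = out, stderr = FALSE)
  if (status != 0) stop(program, " failed with status ", status, call. = FALSE)
  if (file.size(out) == 0) return(empty_hits())
  h <- readr::read_tsv(out, col_names = c("qseqid", "sseqid", "pident",
                                          "length", "qstart", "qend",
                                          "sstart", "send", "evalue",
                                          "bitscore", "qframe"),
                       col_types = "ccdiiiiiddi", progress = FALSE)
  minus_t <- h$sstart > h$send
  minus_q <- h$qstart > h$qend  # blastx reports reverse frames this way
  tibble::tibble(query_id = h$qseqid, target_id = h$sseqid,
                 identity = h$pident / 100, aligned_length = h$length,
                 q_start = as.integer(ifelse(minus_q, h$qend, h$qstart)) - 1L,
                 q_end = as.integer(ifelse(minus_q, h$qstart, h$qend)),
                 t_start = as.integer(ifelse(minus_t, h$send, h$sstart)) - 1L,
                 t_end = as.integer(ifelse(minus_t, h$sstart, h$send)),
                 strand = ifelse(minus_t | minus_q, "-", "+"),
                 frame = h$qframe, e_value = h$evalue, bit_score = h$bitscore)
}

# Best hit per query: lowest e-value, ties by bit score then target id.
best_hits <- function(hits) {
  hits %>%
    dplyr::arrange(.data$query_id, .data$e_value,
                   dplyr::desc(.data$bit_score), .data$target_id) %>%
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}
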