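# Final assembly construction, gene-model accounting and summary metrics.

#' Combine the two re-assembly paths into the final unigene set
#'
#' Concatenates the protein-path and genome-path retained contigs into one
#' unigene table (each unigene carries exactly one category) and reports
#' the gene-model accounting: distinct gene models per path, their union
#' and intersection, and the union as a fraction of the reference gene
#' models. Protein references are mapped to gene models by their shared
#' identifier.
#'
#' @param protein_retained `retained` tibble from [protein_reassemble()].
#' @param genome_retained `retained` tibble from [genome_reassemble()].
#' @param reference_gene_ids Character vector of all annotated gene models
#'   in the reference (for the union fraction); optional.
#' @return List with `unigenes` (tibble: unigene_id, seq, category,
#'   reference_id, annotation_identity) and `accounting` (see
#'   [gene_model_accounting()], plus the realized id sets).
#' @export
build_final_assembly <- function(protein_retained, genome_retained,
                                 reference_gene_ids = NULL) {
  unigenes <- dplyr::bind_rows(
    tibble::tibble(unigene_id = protein_retained$contig_id,
                   seq = protein_retained$seq,
                   category = "protein_annotated",
                   reference_id = protein_retained$reference_id,
                   annotation_identity = protein_retained$identity),
    tibble::tibble(unigene_id = genome_retained$contig_id,
                   seq = genome_retained$seq,
                   category = genome_retained$category,
                   reference_id = genome_retained$reference_id,
                   annotation_identity = genome_retained$identity))
  if (anyDuplicated(unigenes$unigene_id)) {
    stop("duplicate unigene ids in final assembly: ",
         paste(head(unique(unigenes$unigene_id[
           duplicated(unigenes$unigene_id)]), 3), collapse = ", "),
         call. = FALSE)
  }
  protein_models <- unique(protein_retained$reference_id)
  genome_models <- unique(genome_retained$reference_id[
    genome_retained$category %in% c("gene_model_annotated", "utr")])
  union_models <- union(protein_models, genome_models)
  acc <- gene_model_accounting(length(protein_models), length(genome_models),
                               length(union_models),
                               length(reference_gene_ids %||% character(0)))
  acc$protein_models <- protein_models
  acc$genome_models <- genome_models
  list(unigenes = unigenes, accounting = acc)
}

#' Gene-model accounting arithmetic
#'
#' Given the number of distinct gene models annotated by each re-assembly
#' path and by their union, computes the intersection
#' (`n_protein + n_genome - n_union`) and, when a reference count is
#' supplied, the union as a percentage of the annotated reference models.
#'
#' @param n_protein,n_genome Distinct gene models per path.
#' @param n_union Distinct gene models in the union of the two paths.
#' @param n_reference Annotated gene models in the reference (0 to skip
#'   the fraction).
#' @return List with `n_protein`, `n_genome`, `n_union`,
#'   `n_intersection`, `union_fraction_pct`.
#' @export
gene_model_accounting <- function(n_protein, n_genome, n_union,
                                  n_reference = 0) {
  if (n_union > n_protein + n_genome || n_union < max(n_protein, n_genome)) {
    stop("inconsistent gene-model counts", call. = FALSE)
  }
  list(n_protein = n_protein, n_genome = n_genome, n_union = n_union,
       n_intersection = n_protein + n_genome - n_union,
       union_fraction_pct = if (n_reference > 0) 100 * n_union / n_reference
       else NA_real_)
}

#' Assembly summary statistics
#'
#' N50 (the length L such that contigs of length >= L sum to at least half
#' the total assembly length), mean/median/maximum contig length and mean
#' GC over all bases.
#'
#' @param seqs Character vector of sequences (or tibble with a `seq`
#'   column).
#' @return One-row tibble: n_contigs, n50, mean_length, median_length,
#'   max_length, mean_gc.
#' @export
contig_stats <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (length(seqs) == 0) stop("empty sequence set", call. = FALSE)
  lens <- nchar(seqs)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1]]
  gc <- sum(vapply(strsplit(toupper(seqs), ""), function(ch)
    sum(ch %in% c("G", "C")), numeric(1))) / sum(lens)
  tibble::tibble(n_contigs = length(seqs), n50 = n50,
                 mean_length = mean(lens), median_length = median(lens),
                 max_length = max(lens), mean_gc = gc)
}
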