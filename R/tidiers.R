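# broom-style tidiers for fitted result objects.

#' @describeIn nb_pairwise_test Per-gene DE table as a tibble.
#' @param x A `tx_de` object.
#' @param ... Unused.
#' @export
tidy.tx_de <- function(x, ...) x$table

#' @describeIn nb_pairwise_test One-row model summary (contrast, genes
#'   tested, DE calls, common dispersion).
#' @export
glance.tx_de <- function(x, ...) {
  tibble::tibble(contrast = paste(x$contrast, collapse = " vs "),
                 n_genes = nrow(x$table),
                 n_de = sum(x$table$is_de, na.rm = TRUE),
                 n_up = sum(x$table$is_de & x$table$log_fc > 0, na.rm = TRUE),
                 n_down = sum(x$table$is_de & x$table$log_fc < 0,
                              na.rm = TRUE),
                 dispersion_common = x$dispersion_common)
}

#' @export
print.tx_de <- function(x, ...) {
  g <- glance.tx_de(x)
  cat("<tx_de>", g$contrast, "-", g$n_de, "DE of", g$n_genes, "genes (",
      g$n_up, "up /", g$n_down, "down )\n")
  invisible(x)
}

#' @describeIn interaction_test Per-gene interaction table as a tibble.
#' @param x A `tx_interaction` object.
#' @param ... Unused.
#' @export
tidy.tx_interaction <- function(x, ...) x$table

#' @describeIn interaction_test One-row summary of the interaction scan.
#' @export
glance.tx_interaction <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$table),
                 n_significant = sum(x$table$fdr < 0.05, na.rm = TRUE),
                 n_nonconverged = length(x$nonconverged))
}

#' @export
print.tx_interaction <- function(x, ...) {
  g <- glance.tx_interaction(x)
  cat("<tx_interaction>", g$n_significant, "of", g$n_genes,
      "genes with interaction FDR < 0.05\n")
  invisible(x)
}
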