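#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-gene results of a target-calling fit
#'
#' @param x a `ski_pelo_fit` from [call_ski_pelo_targets()].
#' @param ... unused.
#' @return Tibble with one row per gene: `gene_id`, `interaction_estimate`
#'   (log2 ratio of SHORT/LONG enrichment in the double mutant over wild
#'   type), `standard_error`, `p_value` (one-sided), `dispersion`, `called`.
#' @export
tidy.ski_pelo_fit <- function(x, ...) {
  x$results
}

#' One-row summary of a target-calling fit
#'
#' @param x a `ski_pelo_fit`.
#' @param ... unused.
#' @return Tibble: `n_genes_tested`, `n_called`, `alpha`, `n_genes`,
#'   `cutoff`, `median_dispersion`.
#' @export
glance.ski_pelo_fit <- function(x, ...) {
  tibble(
    n_genes_tested = nrow(x$results),
    n_called = sum(x$results$called),
    alpha = x$alpha,
    n_genes = x$n_genes,
    cutoff = x$cutoff,
    median_dispersion = median(x$results$dispersion, na.rm = TRUE)
  )
}
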