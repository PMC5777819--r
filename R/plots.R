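#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_hline geom_vline labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a metagene profile
#'
#' Mean normalized 5'-end density against offset from the stop codon's
#' first nucleotide; the dashed line marks the stall offset (-14, stop codon
#' in the A site).
#'
#' @param object a `metagene_profile`.
#' @param stall_offset offset to mark.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, stall_offset = -14, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset, y = .data$value)) +
    geom_line() +
    geom_vline(xintercept = stall_offset, linetype = "dashed",
               colour = "grey40") +
    labs(x = "offset from stop codon (nt, 5' ends)",
         y = "mean normalized density",
         title = sprintf("metagene profile (%d transcripts)",
                         object$n_transcripts[1])) +
    theme_minimal()
}

#' Plot codon termination frequencies
#'
#' 3'-end termination frequency at each offset around the codon; shaded
#' offsets 0-2 are the codon itself.
#'
#' @param object a `codon_termination_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.codon_termination_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset, y = .data$freq)) +
    ggplot2::annotate("rect", xmin = -0.5, xmax = 2.5, ymin = -Inf,
                      ymax = Inf, alpha = 0.15) +
    geom_col() +
    labs(x = "3'-end offset from codon first nt",
         y = "termination frequency",
         title = sprintf("read 3' ends around %s codons", object$codon[1])) +
    theme_minimal()
}

#' Plot an autocorrelation result
#'
#' @param object an `autocorr_result`.
#' @param lag_band band searched by [dominant_period()], marked dashed.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.autocorr_result <- function(object, lag_band = c(10L, 100L), ...) {
  period <- dominant_period(object, lag_band)
  ggplot(as_tibble(object), aes(x = .data$lag, y = .data$r)) +
    geom_line(na.rm = TRUE) +
    geom_vline(xintercept = period, linetype = "dashed", colour = "grey40") +
    labs(x = "lag (nt)", y = "Pearson r",
         title = sprintf("5'-end autocorrelation (dominant period %s nt)",
                         period)) +
    theme_minimal()
}

#' Plot a BSA window track
#'
#' Mean Hawaiian allele fraction per 100-variant window along the
#' chromosome; the dashed line is the linkage threshold, the dotted line the
#' unlinked expectation of 0.5.
#'
#' @param object a `bsa_window_track`.
#' @param threshold linkage threshold to mark.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.bsa_window_track <- function(object, threshold = 0.1, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$center_bp / 1e6, y = .data$mean_fraction)) +
    geom_line() +
    geom_hline(yintercept = 0.5, linetype = "dotted") +
    geom_hline(yintercept = threshold, linetype = "dashed",
               colour = "grey40") +
    labs(x = "position (Mb)", y = "mean Hawaiian allele fraction") +
    theme_minimal()
}

#' Volcano-style plot of target calls
#'
#' Interaction estimate against -log10 p per gene, called targets
#' highlighted, with the Bonferroni cutoff marked.
#'
#' @param fit a `ski_pelo_fit`.
#' @return A ggplot.
#' @export
plot_target_calls <- function(fit) {
  stopifnot(inherits(fit, "ski_pelo_fit"))
  d <- fit$results |> mutate(neglog_p = -log10(pmax(.data$p_value, 1e-300)))
  ggplot(d, aes(x = .data$interaction_estimate, y = .data$neglog_p,
                colour = .data$called)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_hline(yintercept = -log10(fit$cutoff), linetype = "dashed",
               colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    labs(x = "log2 interaction (SHORT enrichment in double mutant)",
         y = "-log10 p", colour = "called") +
    theme_minimal()
}
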