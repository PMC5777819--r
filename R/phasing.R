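#' Pearson autocorrelation of a 5'-end count track
#'
#' For each lag `x` the track is shifted against itself and the Pearson
#' correlation of the overlapping segments `a[1..N-x]` and `a[x+1..N]` is
#' computed (overlap truncation: no circular wrap, no zero padding). Lags
#' where either segment has zero variance are undefined (`NA`). Applied to
#' the short-footprint track upstream of a poly(A) site, a ribosome-width
#' periodicity of the phased stall peaks appears as a peak in `r` at the
#' inter-peak spacing.
#'
#' @param x numeric vector of per-position counts (e.g. from
#'   [track_window_values()] over the 300 nt upstream of the poly(A) site).
#' @param max_lag largest lag computed (lags 0..`max_lag`).
#' @return Tibble of class `autocorr_result`: `lag`, `r`, with attribute
#'   `window_length`.
#' @export
#' @examples
#' comb <- rep(c(5, rep(0, 27)), length.out = 300)
#' acf28 <- footprint_autocorrelation(comb)
#' dominant_period(acf28)
footprint_autocorrelation <- function(x, max_lag = 100L) {
  n <- length(x)
  if (n < max_lag + 2L) {
    abort(sprintf("window of %d positions is too short for max_lag %d.",
                  n, max_lag),
          class = "riboshort_phasing_error")
  }
  r <- purrr::map_dbl(0:max_lag, function(lag) {
    a <- x[seq_len(n - lag)]
    b <- x[seq.int(lag + 1L, n)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    cor(a, b)
  })
  out <- tibble(lag = 0:max_lag, r = r)
  class(out) <- c("autocorr_result", class(out))
  attr(out, "window_length") <- n
  out
}

#' Dominant autocorrelation period
#'
#' The lag with the maximum correlation coefficient within `lag_band`
#' (default 10-100 nt; the lower bound excludes trivial short-range
#' correlation). Ties break toward the smaller lag.
#'
#' @param result an `autocorr_result`.
#' @param lag_band inclusive `(min, max)` lag band searched.
#' @return The dominant lag (integer), or `NA` if no coefficient in the band
#'   is defined.
#' @export
dominant_period <- function(result, lag_band = c(10L, 100L)) {
  stopifnot(inherits(result, "autocorr_result"))
  band <- result[result$lag >= lag_band[1] & result$lag <= lag_band[2] &
                   !is.na(result$r), ]
  if (nrow(band) == 0L) {
    warn("no defined autocorrelation coefficients in the lag band")
    return(NA_integer_)
  }
  band$lag[which.max(band$r)]   # which.max takes the first (smallest) lag
}

#' Write autocorrelation coefficients as TSV
#'
#' Undefined coefficients are written as `NA`.
#'
#' @param result an `autocorr_result`.
#' @param path output path.
#' @export
write_autocorrelation_tsv <- function(result, path) {
  readr::write_tsv(as_tibble(result), path)
  invisible(path)
}
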