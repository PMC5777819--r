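#' Sliding-window Hawaiian allele frequency
#'
#' Averages the per-variant mapping-strain allele fraction
#' (`hawaiian_count / total_count`) over a moving window of `window_size`
#' variants (step `step`, default 1), which suppresses the sampling noise of
#' any individual variant. Zero-coverage variants are excluded from each
#' window's mean.
#'
#' @param variants variant tibble (`chrom`, `pos`, `hawaiian_count`,
#'   `total_count`), sorted by position within chromosome.
#' @param window_size number of variants per window.
#' @param step slide step in variants.
#' @return Tibble of class `bsa_window_track`: `chrom`, `center_index`
#'   (variant index of the window's central variant), `center_bp`,
#'   `start_bp`, `end_bp`, `mean_fraction`, `n_informative`.
#' @export
#' @examples
#' v <- tibble::tibble(chrom = "chrI", pos = seq_len(120) * 1000L,
#'                     hawaiian_count = 25L, total_count = 50L)
#' windowed_allele_frequency(v, window_size = 100)
windowed_allele_frequency <- function(variants, window_size = 100L,
                                      step = 1L) {
  n <- nrow(variants)
  if (n < window_size) {
    abort(sprintf("need at least window_size (%d) variants, got %d.",
                  window_size, n),
          class = "riboshort_bsa_error")
  }
  if (is.unsorted(variants$pos)) {
    abort("variants must be sorted by position.",
          class = "riboshort_bsa_error")
  }
  frac <- ifelse(variants$total_count > 0,
                 variants$hawaiian_count / variants$total_count, 0)
  informative <- as.integer(variants$total_count > 0)

  csum <- c(0, cumsum(frac * informative))
  cinf <- c(0, cumsum(informative))
  starts <- seq.int(1L, n - window_size + 1L, by = step)
  ends <- starts + window_size - 1L
  n_inf <- cinf[ends + 1L] - cinf[starts]
  mean_frac <- ifelse(n_inf > 0,
                      (csum[ends + 1L] - csum[starts]) / n_inf, NA_real_)
  center <- starts + window_size %/% 2L

  out <- tibble(
    chrom = variants$chrom[center],
    center_index = center,
    center_bp = variants$pos[center],
    start_bp = variants$pos[starts],
    end_bp = variants$pos[ends],
    mean_fraction = mean_frac,
    n_informative = as.integer(n_inf)
  )
  class(out) <- c("bsa_window_track", class(out))
  attr(out, "window_size") <- as.integer(window_size)
  out
}

#' Call linked regions from a window track
#'
#' Phenotype selection keeps only animals homozygous for the suppressor
#' background at the causal locus, depleting the mapping-strain allele
#' there; linkage therefore appears as a run of windows whose mean Hawaiian
#' fraction drops at or below `threshold`. Maximal runs of consecutive
#' qualifying windows are reported as bp intervals from the first to the
#' last window center.
#'
#' @param track a `bsa_window_track`.
#' @param threshold windows with mean fraction <= this value are linked.
#' @return Tibble of intervals: `chrom`, `start_bp`, `end_bp`, `n_windows`,
#'   `min_fraction`. Zero rows when nothing is linked.
#' @export
call_linked_regions <- function(track, threshold = 0.1) {
  stopifnot(inherits(track, "bsa_window_track"))
  low <- !is.na(track$mean_fraction) & track$mean_fraction <= threshold
  if (!any(low)) {
    return(tibble(chrom = character(), start_bp = integer(),
                  end_bp = integer(), n_windows = integer(),
                  min_fraction = numeric()))
  }
  runs <- rle(low)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  keep <- which(runs$values)
  purrr::map(keep, function(k) {
    idx <- run_start[k]:run_end[k]
    tibble(
      chrom = track$chrom[idx[1]],
      start_bp = track$center_bp[idx[1]],
      end_bp = track$center_bp[idx[length(idx)]],
      n_windows = length(idx),
      min_fraction = min(track$mean_fraction[idx])
    )
  }) |> bind_rows()
}

#' Write a window track as TSV, or linked intervals as BED
#'
#' @param track a `bsa_window_track`.
#' @param intervals interval tibble from [call_linked_regions()].
#' @param path output path.
#' @export
write_window_track_tsv <- function(track, path) {
  readr::write_tsv(as_tibble(track), path)
  invisible(path)
}

#' @rdname write_window_track_tsv
#' @export
write_linked_regions_bed <- function(intervals, path) {
  bed <- tibble(chrom = intervals$chrom,
                start = intervals$start_bp - 1L,   # BED is 0-based half-open
                end = intervals$end_bp,
                name = sprintf("linked_%d", seq_len(nrow(intervals))),
                score = intervals$n_windows,
                strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
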