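#' Equal-weight metagene profile around the stop codon
#'
#' For each qualifying transcript the per-offset 5'-end counts over the
#' window are divided by that transcript's mean per-base count over the same
#' window, and the normalized profiles are averaged with equal weight per
#' transcript - a transcript with uniform coverage contributes 1.0 at every
#' offset regardless of its depth or length, so deeply sequenced genes do
#' not dominate. Offsets are relative to the first nucleotide of the stop
#' codon. Transcripts contribute only if the window lies inside their
#' counting region and their total window signal reaches `min_reads`.
#'
#' @param tracks `FIVE_PRIME` coverage tibble (use raw counts,
#'   `library_total = 1e6`; the per-transcript normalization cancels any
#'   global scaling).
#' @param transcriptome transcript tibble.
#' @param window integer `(min, max)` offsets relative to `stop_start`.
#' @param min_reads minimum total window signal for a transcript to be
#'   included.
#' @return Tibble of class `metagene_profile`: `offset`, `value`,
#'   `n_transcripts` (constant column), with attribute `window`.
#' @export
metagene <- function(tracks, transcriptome, window = c(-120L, 12L),
                     min_reads = 10) {
  if (!identical(attr(tracks, "mode", exact = TRUE) %||% "FIVE_PRIME",
                 "FIVE_PRIME")) {
    abort("metagene profiles require FIVE_PRIME tracks.",
          class = "riboshort_profile_error")
  }
  offsets <- seq.int(window[1], window[2])

  # the window must sit inside the transcript's covered region so that a
  # uniform transcript really is flat across all offsets
  eligible <- transcriptome |>
    filter(.data$stop_start + window[1] >= .data$cds_start - 12L,
           .data$stop_start + window[2] <= nchar(.data$sequence) - 1L)

  per_tx <- tracks |>
    inner_join(eligible |> select("gene_id", "stop_start"),
               by = c(transcript_id = "gene_id")) |>
    mutate(offset = .data$pos - .data$stop_start) |>
    filter(.data$offset >= window[1], .data$offset <= window[2])

  totals <- per_tx |>
    group_by(.data$transcript_id) |>
    summarise(total = sum(.data$value), .groups = "drop") |>
    filter(.data$total >= min_reads)

  n_tx <- nrow(totals)
  if (n_tx == 0L) {
    out <- tibble(offset = offsets, value = NA_real_, n_transcripts = 0L)
    class(out) <- c("metagene_profile", class(out))
    attr(out, "window") <- window
    return(out)
  }

  norm <- per_tx |>
    inner_join(totals, by = "transcript_id") |>
    mutate(norm_value = .data$value / (.data$total / length(offsets)))

  profile <- norm |>
    group_by(.data$offset) |>
    summarise(value = sum(.data$norm_value) / n_tx, .groups = "drop")

  out <- tibble(offset = offsets) |>
    left_join(profile, by = "offset") |>
    mutate(value = coalesce(.data$value, 0), n_transcripts = n_tx)
  class(out) <- c("metagene_profile", class(out))
  attr(out, "window") <- window
  out
}

#' Stop-codon enrichment of a metagene profile
#'
#' The profile value at the stall offset (default -14: a read 5' end 14 nt
#' upstream of the stop places the stop codon in the ribosomal A site)
#' divided by the background level, defined as the median profile value over
#' offsets upstream of `background_max` (default -40, far enough that
#' the phased stall peaks at one and two ribosome widths upstream cannot
#' dominate the median).
#'
#' @param profile a `metagene_profile`.
#' @param stall_offset offset carrying the stall peak.
#' @param background_max offsets strictly below this value form the
#'   background band.
#' @return A single fold value (`NA` with a warning if the background is 0).
#' @export
metagene_stop_enrichment <- function(profile, stall_offset = -14L,
                                     background_max = -40L) {
  stopifnot(inherits(profile, "metagene_profile"))
  peak <- profile$value[profile$offset == stall_offset]
  bg <- median(profile$value[profile$offset < background_max])
  if (length(peak) != 1L || is.na(bg)) {
    abort("profile does not cover the stall offset and background band.",
          class = "riboshort_profile_error")
  }
  if (bg == 0) {
    warn("zero metagene background: enrichment undefined")
    return(NA_real_)
  }
  peak / bg
}

#' Per-codon 3'-end termination frequencies
#'
#' For every in-frame instance of `codon` (annotated ORF codons including
#' the stop codon), tallies where short-footprint 3' ends land at offsets
#' -9..+5 relative to the codon's first nucleotide, pooling tallies across
#' instances before normalizing. Frequencies divide by the total over
#' offsets -9..+2 (the codon plus its three upstream codons; the downstream
#' codon is excluded from the denominator because almost no short reads
#' terminate past a stop codon). Footprints are restricted to the SHORT
#' class with 5' ends inside the CDS counting window.
#'
#' @param footprints deduplicated footprint tibble.
#' @param transcriptome transcript tibble.
#' @param codon 3-mer (DNA alphabet, e.g. `"TGA"`).
#' @param offsets offsets tallied, relative to the codon's first nt.
#' @param denominator_offsets offsets summed for the denominator.
#' @return Tibble of class `codon_termination_profile`: `codon`, `offset`,
#'   `count`, `freq`, with attributes `n_instances` and `defined` (`FALSE`
#'   when the denominator was zero, in which case `freq` is `NA`).
#' @export
metacodon_termination <- function(footprints, transcriptome, codon,
                                  offsets = -9:5,
                                  denominator_offsets = -9:2) {
  stopifnot(nchar(codon) == 3L)
  fp <- footprints[assign_size_class(footprints$length) == "SHORT", ]
  windows <- cds_window(transcriptome)
  fp <- fp |>
    inner_join(windows, by = c(transcript_id = "gene_id")) |>
    filter(!.data$empty,
           .data$five_prime >= .data$window_start,
           .data$five_prime <= .data$window_end) |>
    mutate(three_prime = .data$five_prime + .data$length - 1L)

  ends <- fp |> count(.data$transcript_id, .data$three_prime, name = "n")

  instances <- purrr::pmap(
    list(transcriptome$gene_id, transcriptome$sequence,
         transcriptome$cds_start, transcriptome$stop_start),
    function(gene_id, sequence, cds_start, stop_start) {
      starts <- seq.int(cds_start, stop_start, by = 3L)
      codons <- substring(sequence, starts + 1L, starts + 3L)
      keep <- codons == codon
      if (!any(keep)) return(NULL)
      tibble(transcript_id = gene_id, codon_start = starts[keep])
    }
  ) |> purrr::compact() |> bind_rows()

  n_instances <- if (nrow(instances)) nrow(instances) else 0L
  tallies <- tibble(offset = offsets, count = 0)
  if (n_instances > 0L) {
    hits <- instances |>
      tidyr::expand_grid(offset = offsets) |>
      mutate(three_prime = .data$codon_start + .data$offset) |>
      inner_join(ends, by = c("transcript_id", "three_prime")) |>
      group_by(.data$offset) |>
      summarise(count = sum(.data$n), .groups = "drop")
    tallies <- tallies |>
      rows_update(hits, by = "offset")
  }
  denom <- sum(tallies$count[tallies$offset %in% denominator_offsets])
  defined <- denom > 0
  if (!defined) warn("zero denominator: termination frequencies undefined")
  out <- tallies |>
    mutate(codon = codon,
           freq = if (defined) .data$count / denom else NA_real_) |>
    select("codon", "offset", "count", "freq")
  class(out) <- c("codon_termination_profile", class(out))
  attr(out, "n_instances") <- n_instances
  attr(out, "defined") <- defined
  attr(out, "denominator_offsets") <- denominator_offsets
  out
}

#' Write a metagene or metacodon profile as TSV
#'
#' @param profile profile tibble.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}
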