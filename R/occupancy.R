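#' CDS counting window
#'
#' Footprint counting is restricted to reads whose 5' ends map between 12 nt
#' upstream of the start codon and 14 nt upstream of the stop codon: a 5' end
#' at `cds_start - 12` puts the start codon in the ribosomal P site and one
#' at `stop_start - 14` puts the stop codon in the A site, so the window
#' spans exactly the elongating/terminating positions of the ORF. Both
#' bounds are inclusive.
#'
#' @param transcriptome transcript tibble (needs `gene_id`, `cds_start`,
#'   `stop_start`).
#' @return Tibble `gene_id`, `window_start`, `window_end` (0-based,
#'   inclusive) and `empty` (`TRUE` for CDSs too small to have a window;
#'   flagged with a warning). Windows are clipped at position 0 with a
#'   warning.
#' @export
#' @examples
#' tx <- tibble::tibble(gene_id = "t1", cds_start = 100L, stop_start = 400L)
#' cds_window(tx)
cds_window <- function(transcriptome) {
  out <- tibble(
    gene_id = transcriptome$gene_id,
    window_start = transcriptome$cds_start - 12L,
    window_end = transcriptome$stop_start - 14L
  )
  if (any(out$window_start < 0L)) {
    warn("CDS window clipped at transcript position 0 for some transcripts")
    out$window_start <- pmax(out$window_start, 0L)
  }
  out$empty <- out$window_end < out$window_start
  if (any(out$empty)) {
    warn(sprintf("%d transcripts have an empty CDS window (tiny CDS)",
                 sum(out$empty)))
  }
  out
}

#' Count footprints per gene within a coordinate window
#'
#' Counts deduplicated, size-classed footprints whose 5' end lies inside the
#' gene's counting window (inclusive). `region = "cds"` uses the
#' \[start - 12, stop - 14\] window of [cds_window()]; `region = "stop"`
#' restricts to the stop-proximal window \[stop - stop_margin, stop\], which
#' isolates the stop-codon stall peak from the uniform background (used for
#' the smg-dependence statistic). Footprints on transcripts absent from the
#' annotation are skipped and tallied in the `n_unknown` attribute.
#'
#' @param footprints footprint tibble (deduplicated).
#' @param transcriptome transcript tibble.
#' @param size_class one of `"SHORT"`, `"INTERMEDIATE"`, `"LONG"`, or `NULL`
#'   to count all lengths.
#' @param region `"cds"` or `"stop"`.
#' @param stop_margin width (nt) of the stop-proximal window.
#' @return Tibble `gene_id`, `size_class`, `count` with one row per
#'   annotated gene (zero counts included).
#' @export
count_gene_occupancy <- function(footprints, transcriptome,
                                 size_class = "SHORT",
                                 region = c("cds", "stop"),
                                 stop_margin = 20L) {
  region <- match.arg(region)
  if (!is.null(size_class)) {
    footprints <- footprints[assign_size_class(footprints$length) ==
                               size_class, ]
  }
  n_unknown <- sum(!footprints$transcript_id %in% transcriptome$gene_id)

  windows <- if (region == "cds") {
    cds_window(transcriptome)
  } else {
    tibble(gene_id = transcriptome$gene_id,
           window_start = pmax(transcriptome$stop_start - stop_margin, 0L),
           window_end = transcriptome$stop_start,
           empty = FALSE)
  }
  counted <- footprints |>
    inner_join(windows, by = c(transcript_id = "gene_id")) |>
    filter(!.data$empty,
           .data$five_prime >= .data$window_start,
           .data$five_prime <= .data$window_end) |>
    count(gene_id = .data$transcript_id, name = "count")

  out <- tibble(gene_id = transcriptome$gene_id) |>
    left_join(counted, by = "gene_id") |>
    mutate(size_class = size_class %||% "ALL",
           count = as.integer(coalesce(.data$count, 0L))) |>
    select("gene_id", "size_class", "count")
  attr(out, "n_unknown") <- n_unknown
  out
}

#' Per-position coverage tracks
#'
#' `FIVE_PRIME` mode adds one count at each read's 5' position;
#' `FULL_SPAN` adds one at every position the read covers. Values are scaled
#' to reads per million by `1e6 / library_total`; pass `library_total = 1e6`
#' to keep raw counts. Only positions with non-zero signal are returned
#' (tracks are sparse); use [track_window_values()] for a dense window.
#'
#' @param footprints footprint tibble.
#' @param mode `"FIVE_PRIME"` or `"FULL_SPAN"`.
#' @param library_total uniquely-mapped read total used for scaling
#'   (must be > 0).
#' @return Tibble `transcript_id`, `pos` (0-based), `value` with attributes
#'   `mode` and `library_total`.
#' @export
#' @examples
#' fp <- tibble::tibble(transcript_id = "t1", five_prime = c(3L, 3L, 9L),
#'                      length = 16L)
#' coverage_track(fp, mode = "FIVE_PRIME", library_total = 1e6)
coverage_track <- function(footprints, mode = c("FIVE_PRIME", "FULL_SPAN"),
                           library_total) {
  mode <- match.arg(mode)
  if (length(library_total) != 1L || library_total <= 0) {
    abort("`library_total` must be a single positive number.",
          class = "riboshort_track_error")
  }
  scale <- 1e6 / library_total
  if (mode == "FIVE_PRIME") {
    out <- footprints |>
      count(.data$transcript_id, pos = .data$five_prime, name = "n") |>
      mutate(value = .data$n * scale) |>
      select("transcript_id", "pos", "value")
  } else {
    spans <- footprints |>
      group_by(.data$transcript_id) |>
      reframe(pos = sequence(.data$length, from = .data$five_prime)) |>
      count(.data$transcript_id, .data$pos, name = "n") |>
      mutate(value = .data$n * scale)
    out <- spans |> select("transcript_id", "pos", "value")
  }
  out <- arrange(out, .data$transcript_id, .data$pos)
  attr(out, "mode") <- mode
  attr(out, "library_total") <- library_total
  out
}

#' Dense window of a coverage track
#'
#' @param track tibble from [coverage_track()].
#' @param transcript_id transcript to extract.
#' @param start,end 0-based inclusive window bounds.
#' @return Numeric vector of length `end - start + 1` with zeros where the
#'   track has no signal.
#' @export
track_window_values <- function(track, transcript_id, start, end) {
  sub <- track[track$transcript_id == transcript_id &
                 track$pos >= start & track$pos <= end, ]
  vals <- numeric(end - start + 1L)
  vals[sub$pos - start + 1L] <- sub$value
  vals
}

#' Ratio of mean per-base coverage between two regions
#'
#' Means are per base (total signal over region length), so the ratio is
#' invariant to region length. An undefined ratio (zero denominator) is
#' returned as `NA` with a warning.
#'
#' @param track tibble from [coverage_track()] (one transcript).
#' @param region_a,region_b 0-based inclusive `(start, end)` intervals.
#' @param transcript_id transcript to use; defaults to the only one present.
#' @return A single numeric ratio (possibly `NA`).
#' @export
region_ratio <- function(track, region_a, region_b, transcript_id = NULL) {
  if (is.null(transcript_id)) {
    ids <- unique(track$transcript_id)
    if (length(ids) != 1L) {
      abort("track covers several transcripts; give `transcript_id`.",
            class = "riboshort_track_error")
    }
    transcript_id <- ids
  }
  stopifnot(region_a[2] >= region_a[1], region_b[2] >= region_b[1])
  mean_a <- mean(track_window_values(track, transcript_id,
                                     region_a[1], region_a[2]))
  mean_b <- mean(track_window_values(track, transcript_id,
                                     region_b[1], region_b[2]))
  if (mean_b == 0) {
    warn("denominator region has zero coverage: ratio undefined")
    return(NA_real_)
  }
  mean_a / mean_b
}

#' Write a coverage track as bedGraph
#'
#' @param track tibble from [coverage_track()].
#' @param path output path.
#' @export
write_track_bedgraph <- function(track, path) {
  bg <- tibble(chrom = track$transcript_id, start = track$pos,
               end = track$pos + 1L, value = track$value)
  readr::write_tsv(bg, path, col_names = FALSE)
  invisible(path)
}

#' Write / read a count matrix as annotated TSV
#'
#' Wide table (gene rows, one column per library) preceded by `#` metadata
#' lines recording each library's genotype, smg background, size class,
#' replicate and uniquely-mapped total.
#'
#' @param counts long count tibble as produced by [simulate_count_matrix()].
#' @param path file path.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- counts |>
    mutate(library = paste(.data$genotype, .data$smg, .data$size_class,
                           .data$replicate, sep = "|"))
  meta <- counts |>
    distinct(.data$library, .data$genotype, .data$smg, .data$size_class,
             .data$replicate, .data$library_total)
  header <- sprintf(
    "#library\t%s\tgenotype=%s;smg=%s;size_class=%s;replicate=%d;library_total=%d",
    meta$library, meta$genotype, meta$smg, meta$size_class, meta$replicate,
    as.integer(meta$library_total)
  )
  wide <- counts |>
    select("gene_id", "library", "count") |>
    tidyr::pivot_wider(names_from = "library", values_from = "count",
                       values_fill = 0L)
  writeLines(header, path)
  readr::write_tsv(wide, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  lines <- readr::read_lines(path)
  meta_lines <- lines[startsWith(lines, "#library")]
  parts <- stringr::str_split_fixed(meta_lines, "\t", 3)
  kv <- purrr::map(parts[, 3], function(x) {
    pieces <- stringr::str_split_fixed(strsplit(x, ";")[[1]], "=", 2)
    setNames(pieces[, 2], pieces[, 1])
  })
  meta <- tibble(
    library = parts[, 2],
    genotype = purrr::map_chr(kv, "genotype"),
    smg = purrr::map_chr(kv, "smg"),
    size_class = purrr::map_chr(kv, "size_class"),
    replicate = as.integer(purrr::map_chr(kv, "replicate")),
    library_total = as.numeric(purrr::map_chr(kv, "library_total"))
  )
  wide <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                          col_types = readr::cols())
  wide |>
    tidyr::pivot_longer(-"gene_id", names_to = "library",
                        values_to = "count") |>
    inner_join(meta, by = "library") |>
    select("gene_id", "genotype", "smg", "size_class", "replicate",
           "count", "library_total")
}
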