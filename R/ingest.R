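SIZE_CLASS_BOUNDS <- list(
  SHORT = c(15L, 18L),
  INTERMEDIATE = c(19L, 22L),
  LONG = c(28L, 30L)
)

#' Assign footprint size classes
#'
#' 15-18 nt footprints are the truncated/rescue-awaiting class (`SHORT`),
#' 28-30 nt the elongating class (`LONG`), 19-22 nt `INTERMEDIATE`; anything
#' else is `DISCARD`. Every length maps to exactly one label.
#'
#' @param length integer vector of footprint lengths (nt).
#' @return Character vector of labels.
#' @export
#' @examples
#' assign_size_class(c(16, 29, 24))
assign_size_class <- function(length) {
  stopifnot(all(length >= 1))
  dplyr::case_when(
    length >= 15 & length <= 18 ~ "SHORT",
    length >= 19 & length <= 22 ~ "INTERMEDIATE",
    length >= 28 & length <= 30 ~ "LONG",
    TRUE ~ "DISCARD"
  )
}

#' Collapse PCR duplicates by UMI
#'
#' Reads identical in `(transcript_id, five_prime, length, umi)` are PCR
#' copies of one captured molecule and are collapsed to a single record. The
#' result is order-independent and idempotent. Records whose UMI is missing
#' or shorter than `umi_length` are rejected; their number is reported as a
#' message and stored in the `n_rejected` attribute.
#'
#' @param footprints tibble with columns `transcript_id`, `five_prime`,
#'   `length`, `umi`.
#' @param umi_length required UMI length.
#' @return Deduplicated footprint tibble (one row per distinct key), sorted
#'   by transcript, position, length and UMI, with attributes `n_input` and
#'   `n_rejected`.
#' @export
#' @examples
#' fp <- tibble::tibble(transcript_id = "t1", five_prime = c(5L, 5L),
#'                      length = 16L, umi = c("ACGTAC", "ACGTAC"))
#' nrow(collapse_duplicates(fp))
collapse_duplicates <- function(footprints, umi_length = 6L) {
  ok <- !is.na(footprints$umi) & nchar(footprints$umi) == umi_length
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    rlang::inform(sprintf("rejected %d records with missing/short UMIs",
                          n_rejected))
  }
  out <- footprints[ok, ] |>
    distinct(.data$transcript_id, .data$five_prime, .data$length, .data$umi,
             .keep_all = TRUE) |>
    arrange(.data$transcript_id, .data$five_prime, .data$length, .data$umi)
  attr(out, "n_input") <- nrow(footprints)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Read / write footprints as BED6
#'
#' One read per line: `chrom` is the transcript id, `start`/`end` are
#' 0-based half-open, `name` is `read_id:UMI`, `score` is the footprint
#' length, `strand` is `+`. Internally the 3' end is reported inclusive
#' (`five_prime + length - 1`); the half-open convention exists only on
#' disk and the conversion lives here. Readers are gzip-transparent.
#'
#' @param footprints footprint tibble.
#' @param path BED file path (may end in `.gz`).
#' @return `read_footprints_bed()` returns the footprint tibble;
#'   `write_footprints_bed()` returns `path` invisibly.
#' @export
write_footprints_bed <- function(footprints, path) {
  read_id <- footprints$read_id %||% sprintf("r%08d", seq_len(nrow(footprints)))
  bed <- tibble(
    chrom = footprints$transcript_id,
    start = footprints$five_prime,
    end = footprints$five_prime + footprints$length,
    name = paste0(read_id, ":", footprints$umi),
    score = footprints$length,
    strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_footprints_bed
#' @export
read_footprints_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic"
  )
  name_parts <- stringr::str_split_fixed(bed$name, ":", 2)
  tibble(
    transcript_id = bed$chrom,
    five_prime = bed$start,
    length = bed$end - bed$start,
    strand = bed$strand,
    umi = name_parts[, 2],
    read_id = name_parts[, 1]
  )
}
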