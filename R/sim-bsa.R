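#' Simulate a bulk-segregant mapping pool
#'
#' Lays down marker variants along a chromosome with inter-variant spacing
#' uniform on `snp_spacing_range`, then draws pooled allele counts. The
#' phenotype selection removes the mapping-strain ("Hawaiian") allele at the
#' suppressor locus, so the expected Hawaiian allele fraction at distance `d`
#' from `suppressor_position` is `0.5 * (1 - exp(-d / distance_scale))` - 0
#' at the locus, rising to 0.5 for unlinked markers. Observed counts are
#' `Binomial(total, fraction)` with per-site totals `Poisson(pool_depth)`.
#'
#' @param config a [bsa_config()].
#' @param seed seed; defaults to `config$seed`.
#' @return Tibble of variants: `chrom`, `pos` (1-based bp),
#'   `hawaiian_count`, `total_count`, `expected_fraction`. If
#'   `pool_depth` is 0 all counts are zero and the result carries attribute
#'   `zero_depth = TRUE` (with a warning).
#' @export
#' @examples
#' pool <- simulate_bsa_pool(bsa_config(chrom_length = 2e6,
#'                                      suppressor_position = 1e6))
#' head(pool)
simulate_bsa_pool <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "bsa_config"))
  withr::local_seed(seed)

  lo <- config$snp_spacing_range[1]
  hi <- config$snp_spacing_range[2]
  n_max <- ceiling(config$chrom_length / lo) + 1L
  spacing <- floor(runif(n_max, lo, hi + 1))
  pos <- cumsum(spacing)
  pos <- pos[pos <= config$chrom_length]

  d <- abs(pos - config$suppressor_position)
  frac <- 0.5 * (1 - exp(-d / config$distance_scale))

  if (config$pool_depth == 0L) {
    warn("`pool_depth` is 0: emitting all-zero allele counts.")
    out <- tibble(chrom = "chrI", pos = as.integer(pos),
                  hawaiian_count = 0L, total_count = 0L,
                  expected_fraction = frac)
    attr(out, "zero_depth") <- TRUE
    return(out)
  }
  total <- rpois(length(pos), config$pool_depth)
  haw <- rbinom(length(pos), total, frac)
  tibble(chrom = "chrI", pos = as.integer(pos),
         hawaiian_count = as.integer(haw), total_count = as.integer(total),
         expected_fraction = frac)
}

#' Read / write pooled variant allele-count tables
#'
#' The TSV carries `chrom`, `pos`, `hawaiian_count`, `total_count`; the VCF
#' is a minimal VCFv4.2 with the pooled allele depths in the per-sample `AD`
#' field (reference = background strain, alternate = Hawaiian).
#'
#' @param variants variant tibble as from [simulate_bsa_pool()].
#' @param path file path.
#' @return Readers return the variant tibble; writers return `path`
#'   invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  readr::write_tsv(
    variants[, c("chrom", "pos", "hawaiian_count", "total_count")], path
  )
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    hawaiian_count = readr::col_integer(),
    total_count = readr::col_integer()
  ))
}

#' @rdname write_variants_tsv
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref=N2, alt=Hawaiian)\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tpool"
  )
  body <- sprintf(
    "%s\t%d\t.\tA\tT\t.\tPASS\t.\tAD\t%d,%d",
    variants$chrom, variants$pos,
    variants$total_count - variants$hawaiian_count, variants$hawaiian_count
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_vcf <- function(path) {
  rlang::check_installed("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref <- as.integer(purrr::map_chr(parts, 1))
  alt <- as.integer(purrr::map_chr(parts, 2))
  tibble(
    chrom = as.character(v@fix[, "CHROM"]),
    pos = as.integer(v@fix[, "POS"]),
    hawaiian_count = alt,
    total_count = ref + alt
  )
}
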