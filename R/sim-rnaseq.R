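#' Simulate RNA-seq fragments
#'
#' Per-gene fragment counts follow
#' `Poisson(depth * expression * mrna_multiplier * noise)`, fragment lengths
#' are uniform on 25-40 nt, and fragment start positions are uniform along
#' the transcript - except for the premature-stop-codon (PTC) gene in the
#' surveillance-deficient double mutant with intact NMD, where per-base
#' coverage upstream of the PTC is `bimodal_ratio` times the downstream
#' coverage (the decay fragment 5' of the truncation persists while the
#' downstream half is degraded). In an `smg-1` background the step disappears
#' and coverage is uniform again.
#'
#' @inheritParams simulate_footprints
#' @param depth expected fragments in the library.
#' @return Tibble of fragments: `transcript_id`, `start` (0-based), `length`.
#' @export
#' @examples
#' tx <- generate_transcriptome(sim_config(n_genes = 10))
#' fr <- simulate_rnaseq(tx, "skih-2 pelo-1", config = sim_config(n_genes = 10),
#'                       depth = 1e4)
#' dplyr::count(fr, transcript_id)
simulate_rnaseq <- function(transcriptome, genotype, smg = "smg+",
                            config = sim_config(), depth = config$depth,
                            seed = config$seed) {
  .check_genotype(genotype, smg)
  withr::local_seed(seed)

  n <- nrow(transcriptome)
  mult <- .gene_mrna_multiplier(transcriptome, genotype, config)
  noise <- .replicate_noise(n, config$rna_replicate_dispersion)
  n_frag <- rpois(n, depth * transcriptome$expression_level * mult * noise)

  bimodal <- genotype == "skih-2 pelo-1" && smg == "smg+"

  pieces <- purrr::map(seq_len(n), function(i) {
    m <- n_frag[i]
    if (m == 0L) return(NULL)
    tx_len <- nchar(transcriptome$sequence[i])
    len <- sample(25:40, m, replace = TRUE)
    max_start <- tx_len - len            # start uniform on [0, tx_len - len]
    ptc <- NULL
    if (bimodal && transcriptome$gene_class[i] == "ptc") {
      stalls <- transcriptome$stall_sites[[i]]
      ptc_pos <- stalls$position[stalls$class == "STOP_CODON" &
                                   stalls$position < transcriptome$stop_start[i]]
      if (length(ptc_pos) == 1L) ptc <- ptc_pos
    }
    if (is.null(ptc)) {
      start <- floor(runif(m) * (max_start + 1))
    } else {
      # piecewise-constant start density: weight R upstream of the PTC
      r <- config$bimodal_ratio
      n_up <- pmin(ptc, max_start + 1)
      n_down <- pmax(max_start + 1 - ptc, 0)
      p_up <- r * n_up / (r * n_up + n_down)
      up <- runif(m) < p_up
      start <- ifelse(up,
                      floor(runif(m) * n_up),
                      ptc + floor(runif(m) * pmax(n_down, 1)))
    }
    tibble(transcript_id = transcriptome$gene_id[i],
           start = as.integer(start), length = as.integer(len))
  })
  out <- bind_rows(purrr::compact(pieces))
  if (nrow(out) == 0L) {
    out <- tibble(transcript_id = character(), start = integer(),
                  length = integer())
  }
  out
}

#' Tally RNA-seq fragments per gene
#'
#' @param fragments tibble from [simulate_rnaseq()].
#' @return Tibble `gene_id`, `count`, `library_total` (the same total, the
#'   number of fragments in the library, on every row).
#' @export
count_fragments <- function(fragments) {
  fragments |>
    count(gene_id = .data$transcript_id, name = "count") |>
    mutate(library_total = sum(.data$count))
}
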