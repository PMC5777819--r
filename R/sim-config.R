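#' Genotype and stall-site vocabularies
#'
#' The simulator and the target caller recognise four ribosome-rescue/decay
#' genotypes (the wild type, single mutants of the SKI-complex helicase and
#' the pelota rescue factor, and the double mutant), each in an NMD-proficient
#' (`"smg+"`) or NMD-deficient (`"smg-1"`) background. Stall sites fall into
#' three classes: ribosomes that reach the physical mRNA 3' end
#' (`THREE_PRIME_END`, the nonstop-reporter situation), ribosomes stalled on a
#' truncated stop codon (`STOP_CODON`, smg-dependent), and ribosomes stalled
#' at an internal endonucleolytic cut such as a tRNA-endonuclease site
#' (`INTERNAL_ENDO`, smg-independent).
#'
#' @format Character vectors of allowed labels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
GENOTYPES <- c("WT", "skih-2", "pelo-1", "skih-2 pelo-1")

#' @rdname vocabularies
#' @export
SMG_BACKGROUNDS <- c("smg+", "smg-1")

#' @rdname vocabularies
#' @export
STALL_CLASSES <- c("THREE_PRIME_END", "STOP_CODON", "INTERNAL_ENDO")

.default_stall_boost <- function() {
  one <- c(THREE_PRIME_END = 1, STOP_CODON = 1, INTERNAL_ENDO = 1)
  list(
    "WT"            = one,
    "skih-2"        = one,
    "pelo-1"        = c(THREE_PRIME_END = 2.5, STOP_CODON = 2.5, INTERNAL_ENDO = 2.5),
    "skih-2 pelo-1" = c(THREE_PRIME_END = 5.0, STOP_CODON = 5.0, INTERNAL_ENDO = 5.0)
  )
}

.default_mrna_multiplier <- function() {
  # reporter-transcript mRNA de-repression per genotype; background genes
  # are unchanged (multiplier 1)
  c("WT" = 1, "skih-2" = 7.12, "pelo-1" = 3.81, "skih-2 pelo-1" = 19.4)
}

#' Simulator configuration
#'
#' Bundles every tunable of the synthetic transcriptome / footprint / RNA-seq
#' generator. Defaults encode the study conditions the rest of the package is
#' benchmarked against: mRNA de-repression of the nonstop reporter of
#' 7.12x (ski helicase mutant), 3.81x (pelota mutant) and 19.4x (double
#' mutant); short-footprint stall intensities of 2.5x (pelota) and 5x (double
#' mutant) at stop codons with a further 16x multiplier on planted target
#' genes; phased upstream stall peaks spaced one ribosome width (28 nt) apart
#' with geometrically decaying weight; and a 12x upstream/downstream RNA
#' coverage step across a premature stop codon in the surveillance-deficient
#' background.
#'
#' @param n_genes total number of transcripts to simulate.
#' @param n_targets number of planted SKI/PELO target genes (stop-codon stall
#'   with the extra `target_boost` multiplier).
#' @param include_reporter,include_ptc,include_endo include the single
#'   nonstop-reporter transcript (no stop codon, 3'-end stall), the premature
#'   -stop-codon allele, and the internal tRNA-endonuclease-site gene.
#' @param background_stop_stall if `TRUE` (default) every ordinary coding
#'   gene carries a stop-codon stall at its annotated stop, so genome-wide
#'   metagene enrichment follows the genotype's `stall_boost`; set `FALSE`
#'   for a clean null background (e.g. caller error-rate experiments).
#' @param length_distribution mean and sd (nt) of simulated CDS length,
#'   rounded to codons and floored at `cds_min`.
#' @param cds_min minimum CDS length in nt.
#' @param depth expected unique molecules per library.
#' @param short_fraction_background probability that a captured footprint is
#'   short (15-18 nt) absent any stall.
#' @param stall_boost named list (per genotype) of named vectors (per stall
#'   class) of multiplicative short-footprint intensity at stall sites, on the
#'   scale of the per-position background short-footprint density (boost 1 =
#'   no peak above background).
#' @param target_boost multiplier applied to the stop-codon stall excess
#'   (`boost - 1`) of planted target genes, so targets are ordinary genes in
#'   any background where rescue/decay is functional.
#' @param mrna_multiplier named vector of per-genotype mRNA abundance scaling
#'   for the reporter transcript.
#' @param peak_spacing_delta spacing (nt) between successive phased upstream
#'   stall peaks (one ribosome width).
#' @param peak_decay_rho geometric weight of the k-th upstream peak
#'   (weight `rho^k`), `0 < rho < 1`.
#' @param peak_k_max largest upstream peak index simulated (k = 0..k_max).
#' @param smg_residual fraction of stop-codon stall intensity retained in an
#'   `smg-1` mutant background (internal-endonuclease stalls are unaffected).
#' @param bimodal_ratio upstream/downstream per-base RNA-seq coverage ratio
#'   across a premature stop codon in the surveillance-deficient background.
#' @param umi_length length of the random unique molecular identifier.
#' @param pcr_duplication_p geometric parameter of the per-molecule PCR
#'   duplicate count (extra copies ~ Geometric(1 - p)); the default keeps
#'   duplicates to a few percent of reads.
#' @param replicate_dispersion gamma dispersion of multiplicative biological
#'   noise applied per gene and library in footprint simulations; 0.01
#'   corresponds to a 10% CV between replicate libraries (size selection and
#'   ligation add appreciable library-to-library variability).
#' @param rna_replicate_dispersion same, for RNA-seq libraries; mRNA
#'   abundance is far more reproducible between biological replicates (the
#'   reporter's replicate fold SDs are a few percent), default 6e-4
#'   (2.4% CV).
#' @param reporter_expression expression share of the reporter transcript.
#' @param seed integer seed; identical `(config, seed)` give byte-identical
#'   simulator output.
#'
#' @return A list with class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 20, depth = 1e4)
#' cfg$stall_boost[["pelo-1"]]["STOP_CODON"]
sim_config <- function(n_genes = 500,
                       n_targets = 0,
                       include_reporter = TRUE,
                       include_ptc = TRUE,
                       include_endo = TRUE,
                       background_stop_stall = TRUE,
                       length_distribution = c(mean = 135, sd = 15),
                       cds_min = 105,
                       depth = 1e6,
                       short_fraction_background = 0.1,
                       stall_boost = .default_stall_boost(),
                       target_boost = 16,
                       mrna_multiplier = .default_mrna_multiplier(),
                       peak_spacing_delta = 28,
                       peak_decay_rho = 0.4,
                       peak_k_max = 5,
                       smg_residual = 0.1,
                       bimodal_ratio = 12,
                       umi_length = 6,
                       pcr_duplication_p = 0.03,
                       replicate_dispersion = 0.01,
                       rna_replicate_dispersion = 6e-4,
                       reporter_expression = 0.002,
                       seed = 1L) {
  cfg <- structure(
    list(
      n_genes = as.integer(n_genes),
      n_targets = as.integer(n_targets),
      include_reporter = isTRUE(include_reporter),
      include_ptc = isTRUE(include_ptc),
      include_endo = isTRUE(include_endo),
      background_stop_stall = isTRUE(background_stop_stall),
      length_distribution = length_distribution,
      cds_min = as.integer(cds_min),
      depth = depth,
      short_fraction_background = short_fraction_background,
      stall_boost = stall_boost,
      target_boost = target_boost,
      mrna_multiplier = mrna_multiplier,
      peak_spacing_delta = as.integer(peak_spacing_delta),
      peak_decay_rho = peak_decay_rho,
      peak_k_max = as.integer(peak_k_max),
      smg_residual = smg_residual,
      bimodal_ratio = bimodal_ratio,
      umi_length = as.integer(umi_length),
      pcr_duplication_p = pcr_duplication_p,
      replicate_dispersion = replicate_dispersion,
      rna_replicate_dispersion = rna_replicate_dispersion,
      reporter_expression = reporter_expression,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config a `sim_config` object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_special <- config$n_targets + config$include_reporter +
    config$include_ptc + config$include_endo
  if (config$n_genes < 1L) {
    abort("`n_genes` must be at least 1.", class = "riboshort_config_error")
  }
  if (config$n_genes < n_special) {
    abort(
      sprintf(
        "`n_genes` (%d) is smaller than the number of special genes (%d).",
        config$n_genes, n_special
      ),
      class = "riboshort_config_error"
    )
  }
  boosts <- unlist(config$stall_boost)
  if (any(boosts <= 0) || any(config$mrna_multiplier <= 0) ||
      config$target_boost <= 0) {
    abort("all stall boosts and mRNA multipliers must be > 0.",
          class = "riboshort_config_error")
  }
  if (!all(GENOTYPES %in% names(config$stall_boost)) ||
      !all(GENOTYPES %in% names(config$mrna_multiplier))) {
    abort("stall_boost and mrna_multiplier must cover all genotypes.",
          class = "riboshort_config_error")
  }
  if (config$peak_decay_rho <= 0 || config$peak_decay_rho >= 1) {
    abort("`peak_decay_rho` must be in (0, 1).",
          class = "riboshort_config_error")
  }
  if (config$smg_residual < 0 || config$smg_residual > 1) {
    abort("`smg_residual` must be in [0, 1].",
          class = "riboshort_config_error")
  }
  if (config$short_fraction_background <= 0 ||
      config$short_fraction_background >= 1) {
    abort("`short_fraction_background` must be in (0, 1).",
          class = "riboshort_config_error")
  }
  invisible(config)
}

#' Bulk-segregant pool configuration
#'
#' Parameters of the simulated mapping cross: a suppressor mutation isolated
#' in one genetic background is crossed to a polymorphic wild isolate, F2
#' animals are phenotype-selected and pooled, and the pool is sequenced. At
#' the selected locus the mapping-strain allele is depleted to zero; the
#' expected mapping-strain ("Hawaiian") allele fraction recovers towards 0.5
#' with distance d as `0.5 * (1 - exp(-d / distance_scale))`.
#'
#' @param chrom_length chromosome length in bp.
#' @param snp_spacing_range inter-variant spacing range in bp; spacing is
#'   uniform on this interval (one marker every 700-1300 bp by default).
#' @param suppressor_position bp position of the selected suppressor locus.
#' @param pool_depth sequencing reads per variant site.
#' @param distance_scale characteristic recombination distance (bp)
#'   controlling how fast the allele fraction rises back to 0.5.
#' @param seed integer seed.
#'
#' @return A list with class `"bsa_config"`.
#' @export
#' @examples
#' bsa_config(chrom_length = 2e6, suppressor_position = 1e6)
bsa_config <- function(chrom_length = 15e6,
                       snp_spacing_range = c(700, 1300),
                       suppressor_position = 7.5e6,
                       pool_depth = 50,
                       distance_scale = 2e6,
                       seed = 1L) {
  if (suppressor_position <= 0 || suppressor_position >= chrom_length) {
    abort("`suppressor_position` must lie inside the chromosome.",
          class = "riboshort_config_error")
  }
  if (any(snp_spacing_range <= 0) ||
      snp_spacing_range[2] < snp_spacing_range[1]) {
    abort("`snp_spacing_range` must be positive and ordered.",
          class = "riboshort_config_error")
  }
  structure(
    list(
      chrom_length = chrom_length,
      snp_spacing_range = snp_spacing_range,
      suppressor_position = suppressor_position,
      pool_depth = as.integer(pool_depth),
      distance_scale = distance_scale,
      seed = as.integer(seed)
    ),
    class = "bsa_config"
  )
}

.check_genotype <- function(genotype, smg) {
  if (!is.character(genotype) || length(genotype) != 1L ||
      !genotype %in% GENOTYPES) {
    abort(
      sprintf("unknown genotype label %s; expected one of: %s",
              deparse(genotype), paste(GENOTYPES, collapse = ", ")),
      class = "riboshort_genotype_error"
    )
  }
  if (!smg %in% SMG_BACKGROUNDS) {
    abort(
      sprintf("unknown smg background %s; expected \"smg+\" or \"smg-1\"",
              deparse(smg)),
      class = "riboshort_genotype_error"
    )
  }
  invisible(TRUE)
}
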