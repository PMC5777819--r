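# ---- internal: generative model of footprint capture ------------------------
#
# Each captured unique molecule on a gene is one of:
#   LONG      elongating footprint, length 28-30, 5' uniform on the CDS window
#   BG_SHORT  background short footprint, length 15-18, 5' uniform on the
#             CDS window
#   STALL     stall-derived short footprint whose 3' end sits at a
#             cleavage/truncation point t - k*delta (phased peaks k = 0..k_max
#             with geometric weight rho^k), length 15-18
#
# Stall intensity is calibrated against the per-position background density:
# with lengths uniform on {15..18} exactly 1/4 of a peak's 5' mass falls on
# any one supported position, so giving peak k a total weight of
# 4 * (boost - 1) * rho^k * (background short weight per window position)
# makes the expected 5' count at the canonical stall offset equal to
# boost * background. The metagene enrichment statistic therefore recovers
# `boost` in expectation, and a boost of 1 (wild type) adds nothing.

.cds_window_bounds <- function(cds_start, stop_start) {
  c(start = cds_start - 12L, end = stop_start - 14L)
}

# possible 3'-end truncation points for one stall site, with probabilities:
# stop codons are truncated after the 2nd base (UGA) or the 2nd/3rd base
# (UAA/UAG); a full stop codon with an attached downstream base never occurs
.truncation_points <- function(position, class, sequence) {
  if (class == "STOP_CODON") {
    codon <- substr(sequence, position + 1L, position + 3L)
    if (codon == "TGA") {
      list(t = position + 1L, p = 1)
    } else {
      list(t = c(position + 1L, position + 2L), p = c(0.5, 0.5))
    }
  } else {
    list(t = position, p = 1)
  }
}

# per-gene component table: category weights as shares of the gene's
# molecules, plus what is needed to sample (or integrate) 5' positions
.footprint_components <- function(transcriptome, genotype, smg, config) {
  q0 <- config$short_fraction_background
  rho <- config$peak_decay_rho
  delta <- config$peak_spacing_delta
  boosts <- config$stall_boost[[genotype]]

  purrr::pmap(
    list(transcriptome$sequence, transcriptome$cds_start,
         transcriptome$stop_start, transcriptome$stall_sites,
         transcriptome$is_planted_target),
    function(sequence, cds_start, stop_start, stalls, is_target) {
      w <- .cds_window_bounds(cds_start, stop_start)
      width <- w[["end"]] - w[["start"]] + 1L
      lambda <- q0 / width   # background short weight per window position

      stall_rows <- purrr::pmap(
        list(stalls$position, stalls$class),
        function(position, class) {
          boost <- boosts[[class]]
          excess <- boost - 1
          if (class == "STOP_CODON" && is_target) {
            # the target multiplier scales the stall intensity in excess of
            # background, so targets are indistinguishable from background
            # genes wherever rescue/decay is functional (boost 1)
            excess <- excess * config$target_boost
          }
          if (class == "STOP_CODON" && smg == "smg-1") {
            excess <- excess * config$smg_residual
          }
          if (excess <= 0) return(NULL)
          tp <- .truncation_points(position, class, sequence)
          ks <- 0:config$peak_k_max
          ks <- ks[min(tp$t) - delta * ks - 17L >= 0L]
          if (length(ks) == 0) return(NULL)
          tibble(
            kind = "STALL",
            weight = 4 * excess * lambda * rho^ks,
            k = ks,
            t = list(tp$t),
            t_prob = list(tp$p)
          )
        }
      )
      comp <- bind_rows(
        tibble(kind = "BG_SHORT", weight = q0, k = NA_integer_,
               t = list(NULL), t_prob = list(NULL)),
        purrr::compact(stall_rows)
      )
      w_long <- 1 - sum(comp$weight)
      if (w_long < 0.02) {
        abort(paste0("stall intensity leaves <2% elongating footprints for a",
                     " gene; lower boosts or background short fraction"),
              class = "riboshort_config_error")
      }
      bind_rows(
        tibble(kind = "LONG", weight = w_long, k = NA_integer_,
               t = list(NULL), t_prob = list(NULL)),
        comp
      )
    }
  )
}

.gene_mrna_multiplier <- function(transcriptome, genotype, config) {
  ifelse(transcriptome$gene_class == "reporter",
         config$mrna_multiplier[[genotype]], 1)
}

.replicate_noise <- function(n, dispersion) {
  if (dispersion <= 0) return(rep(1, n))
  rgamma(n, shape = 1 / dispersion, rate = 1 / dispersion)
}

.umi_alphabet <- c("A", "C", "G", "T")

.random_umis <- function(n, umi_length) {
  if (n == 0) return(character())
  # decode uniform integers through a precomputed k-mer table
  kmers <- do.call(
    paste0,
    rev(purrr::map(seq_len(umi_length) - 1L, function(i) {
      rep(rep(.umi_alphabet, each = 4^i), length.out = 4^umi_length)
    }))
  )
  kmers[sample.int(length(kmers), n, replace = TRUE)]
}

# sample 5' positions and lengths for `m` molecules of one component
.sample_component <- function(comp_row, m, window) {
  if (comp_row$kind == "LONG") {
    len <- sample(28:30, m, replace = TRUE)
    fp <- window[["start"]] +
      sample.int(window[["end"]] - window[["start"]] + 1L, m,
                 replace = TRUE) - 1L
  } else if (comp_row$kind == "BG_SHORT") {
    len <- sample(15:18, m, replace = TRUE)
    fp <- window[["start"]] +
      sample.int(window[["end"]] - window[["start"]] + 1L, m,
                 replace = TRUE) - 1L
  } else {
    len <- sample(15:18, m, replace = TRUE)
    ts <- comp_row$t[[1]]
    t <- if (length(ts) == 1L) rep(ts, m) else {
      ts[sample.int(length(ts), m, replace = TRUE, prob = comp_row$t_prob[[1]])]
    }
    fp <- t - comp_row$k * attr(window, "delta") - len + 1L
  }
  list(five_prime = as.integer(fp), length = as.integer(len))
}

#' Simulate ribosome footprints for one library
#'
#' Draws unique molecules per gene from
#' `Poisson(depth * expression * mrna_multiplier * noise)` and assigns each
#' molecule to a footprint category (elongating 28-30 nt, background short
#' 15-18 nt, or stall-derived short with its 3' end at a truncation point and
#' phased upstream peaks one ribosome width apart). Stop-codon stall
#' intensity scales with the genotype's `stall_boost` (times `target_boost`
#' on planted targets) and is reduced to `smg_residual` of its excess in an
#' `smg-1` background; internal-endonuclease stalls are smg-independent.
#' Every molecule carries a random UMI and a geometric PCR duplicate count;
#' the returned records are reads (duplicates expanded).
#'
#' @param transcriptome tibble from [generate_transcriptome()].
#' @param genotype one of `GENOTYPES`.
#' @param smg `"smg+"` or `"smg-1"`.
#' @param config a [sim_config()].
#' @param depth expected unique molecules in the library.
#' @param seed seed for this library.
#' @return Tibble of reads: `transcript_id`, `five_prime` (0-based),
#'   `length`, `strand`, `umi`, `read_id`.
#' @export
#' @examples
#' tx <- generate_transcriptome(sim_config(n_genes = 10, depth = 2000))
#' fp <- simulate_footprints(tx, "pelo-1", config = sim_config(n_genes = 10),
#'                           depth = 2000)
#' table(assign_size_class(fp$length))
simulate_footprints <- function(transcriptome, genotype, smg = "smg+",
                                config = sim_config(),
                                depth = config$depth, seed = config$seed) {
  .check_genotype(genotype, smg)
  comps <- .footprint_components(transcriptome, genotype, smg, config)
  withr::local_seed(seed)

  n <- nrow(transcriptome)
  mult <- .gene_mrna_multiplier(transcriptome, genotype, config)
  # the short and long size classes are separate physical libraries (gel
  # slices with their own ligation/amplification), so their biological/
  # library noise draws are independent
  noise_short <- .replicate_noise(n, config$replicate_dispersion)
  noise_long <- .replicate_noise(n, config$replicate_dispersion)
  mu <- depth * transcriptome$expression_level * mult

  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    comp <- comps[[i]]
    g <- ifelse(comp$kind == "LONG", noise_long[i], noise_short[i])
    m_comp <- rpois(nrow(comp), mu[i] * comp$weight * g)
    if (sum(m_comp) == 0L) next
    window <- .cds_window_bounds(transcriptome$cds_start[i],
                                 transcriptome$stop_start[i])
    attr(window, "delta") <- config$peak_spacing_delta
    drawn <- purrr::map(which(m_comp > 0L), function(j) {
      .sample_component(comp[j, ], m_comp[j], window)
    })
    pieces[[i]] <- tibble(
      transcript_id = transcriptome$gene_id[i],
      five_prime = unlist(purrr::map(drawn, "five_prime")),
      length = unlist(purrr::map(drawn, "length"))
    )
  }
  mol <- bind_rows(pieces)
  if (nrow(mol) == 0L) {
    return(tibble(transcript_id = character(), five_prime = integer(),
                  length = integer(), strand = character(),
                  umi = character(), read_id = character()))
  }
  mol$umi <- .random_umis(nrow(mol), config$umi_length)
  copies <- 1L + rgeom(nrow(mol), 1 - config$pcr_duplication_p)
  reads <- mol[rep.int(seq_len(nrow(mol)), copies), ]
  reads$strand <- "+"
  reads$read_id <- sprintf("r%08d", seq_len(nrow(reads)))
  as_tibble(reads)
}

# window-restricted fraction of a stall component's 5' mass
.stall_window_fraction <- function(comp_row, window) {
  ts <- comp_row$t[[1]]
  ps <- comp_row$t_prob[[1]]
  f <- 0
  for (j in seq_along(ts)) {
    fp <- ts[j] - comp_row$k * attr(window, "delta") - (15:18) + 1L
    f <- f + ps[j] * mean(fp >= window[["start"]] & fp <= window[["end"]])
  }
  f
}

#' Simulate CDS-window footprint counts directly
#'
#' Count-level counterpart of [simulate_footprints()]: instead of emitting
#' read records it draws, per gene, Poisson counts of short and long
#' footprints whose 5' ends fall in the CDS counting window, using exactly
#' the per-category intensities of the molecule-level model (the marginal of
#' a Poisson-total multinomial is Poisson). Use it for large
#' count-matrix experiments where individual reads are never needed.
#'
#' @inheritParams simulate_footprints
#' @return Tibble with `gene_id`, `size_class` (`"SHORT"`/`"LONG"`), `count`,
#'   and `library_total` (total unique molecules of that size class in the
#'   library, in or out of the window).
#' @export
simulate_footprint_counts <- function(transcriptome, genotype, smg = "smg+",
                                      config = sim_config(),
                                      depth = config$depth,
                                      seed = config$seed) {
  .check_genotype(genotype, smg)
  comps <- .footprint_components(transcriptome, genotype, smg, config)
  withr::local_seed(seed)

  n <- nrow(transcriptome)
  mult <- .gene_mrna_multiplier(transcriptome, genotype, config)
  noise_short <- .replicate_noise(n, config$replicate_dispersion)
  noise_long <- .replicate_noise(n, config$replicate_dispersion)
  mu <- depth * transcriptome$expression_level * mult

  per_gene <- purrr::map(seq_len(n), function(i) {
    comp <- comps[[i]]
    window <- .cds_window_bounds(transcriptome$cds_start[i],
                                 transcriptome$stop_start[i])
    attr(window, "delta") <- config$peak_spacing_delta
    w_short <- sum(comp$weight[comp$kind != "LONG"])
    w_short_in <- sum(purrr::map_dbl(seq_len(nrow(comp)), function(j) {
      if (comp$kind[j] == "LONG") return(0)
      if (comp$kind[j] == "BG_SHORT") return(comp$weight[j])
      comp$weight[j] * .stall_window_fraction(comp[j, ], window)
    }))
    w_long <- comp$weight[comp$kind == "LONG"]
    short_in <- rpois(1L, mu[i] * noise_short[i] * w_short_in)
    short_out <- rpois(1L, mu[i] * noise_short[i] * (w_short - w_short_in))
    long_in <- rpois(1L, mu[i] * noise_long[i] * w_long)
    c(short_in = short_in, short_out = short_out, long_in = long_in)
  })
  m <- do.call(rbind, per_gene)
  bind_rows(
    tibble(gene_id = transcriptome$gene_id, size_class = "SHORT",
           count = as.integer(m[, "short_in"]),
           library_total = sum(m[, "short_in"]) + sum(m[, "short_out"])),
    tibble(gene_id = transcriptome$gene_id, size_class = "LONG",
           count = as.integer(m[, "long_in"]),
           library_total = sum(m[, "long_in"]))
  )
}

#' Simulate a full count matrix across genotypes and replicates
#'
#' Convenience wrapper running [simulate_footprint_counts()] for each
#' genotype x replicate library and stacking the results in the long format
#' the target caller consumes. Replicate seeds are derived from `seed`.
#'
#' @inheritParams simulate_footprint_counts
#' @param genotypes genotypes to simulate libraries for.
#' @param n_replicates replicates per genotype.
#' @return Long tibble: `gene_id`, `genotype`, `smg`, `size_class`,
#'   `replicate`, `count`, `library_total`.
#' @export
simulate_count_matrix <- function(transcriptome,
                                  genotypes = c("WT", "skih-2 pelo-1"),
                                  smg = "smg+", n_replicates = 2,
                                  config = sim_config(),
                                  depth = config$depth,
                                  seed = config$seed) {
  grid <- tidyr::expand_grid(genotype = genotypes,
                             replicate = seq_len(n_replicates))
  purrr::pmap(grid, function(genotype, replicate) {
    lib_seed <- (seed + 1009L * match(genotype, GENOTYPES) +
                   7919L * replicate) %% .Machine$integer.max
    simulate_footprint_counts(transcriptome, genotype, smg, config,
                              depth = depth, seed = lib_seed) |>
      mutate(genotype = genotype, smg = smg, replicate = replicate)
  }) |>
    bind_rows() |>
    select("gene_id", "genotype", "smg", "size_class", "replicate",
           "count", "library_total")
}
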