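test_that("generated transcriptomes contain the configured gene classes", {
  cfg <- sim_config(n_genes = 10, n_targets = 0, seed = 3)
  tx <- generate_transcriptome(cfg)
  expect_equal(nrow(tx), 10)
  expect_equal(sum(tx$gene_class == "reporter"), 1)

  # exactly one transcript (the reporter) lacks an annotated stop codon
  stop_codon <- substr(tx$sequence, tx$stop_start + 1, tx$stop_start + 3)
  expect_equal(sum(!stop_codon %in% c("TAA", "TAG", "TGA")), 1)
  expect_false(stop_codon[tx$gene_class == "reporter"] %in%
                 c("TAA", "TAG", "TGA"))

  # reporter carries a 3'-end stall at polya_site - 1 and no stop-codon stall
  rep_stalls <- tx$stall_sites[[which(tx$gene_class == "reporter")]]
  expect_equal(rep_stalls$class, "THREE_PRIME_END")
  expect_equal(rep_stalls$position,
               tx$polya_site[tx$gene_class == "reporter"] - 1L)

  expect_error(generate_transcriptome(sim_config(n_genes = 2, n_targets = 5)),
               class = "riboshort_config_error")
})

test_that("coordinate invariants hold for every generated transcript", {
  tx <- generate_transcriptome(sim_config(n_genes = 40, n_targets = 5,
                                          seed = 11))
  expect_true(all(tx$cds_start >= 0))
  expect_true(all(tx$cds_start < tx$stop_start))
  expect_true(all(tx$stop_start < tx$polya_site))
  expect_true(all(tx$polya_site <= nchar(tx$sequence)))
  expect_true(all((tx$stop_start - tx$cds_start) %% 3 == 0))
  expect_equal(sum(tx$expression_level), 1)
})

test_that("background CDSs contain no in-frame premature stop codon", {
  cfg <- sim_config(n_genes = 300, include_reporter = FALSE,
                    include_ptc = FALSE, include_endo = FALSE, seed = 5)
  tx <- generate_transcriptome(cfg)
  # brute-force scan of every in-frame codon strictly inside each CDS
  n_premature <- sum(vapply(seq_len(nrow(tx)), function(i) {
    starts <- seq(tx$cds_start[i], tx$stop_start[i] - 3L, by = 3L)
    codons <- substring(tx$sequence[i], starts + 1L, starts + 3L)
    sum(codons %in% c("TAA", "TAG", "TGA"))
  }, numeric(1)))
  expect_equal(n_premature, 0)
})

test_that("identical seeds and configs give byte-identical outputs", {
  cfg <- tiny_config()
  tx1 <- generate_transcriptome(cfg)
  tx2 <- generate_transcriptome(cfg)
  expect_identical(tx1, tx2)

  f1 <- withr::local_tempfile(fileext = ".fa")
  g1 <- withr::local_tempfile(fileext = ".gff3")
  f2 <- withr::local_tempfile(fileext = ".fa")
  g2 <- withr::local_tempfile(fileext = ".gff3")
  write_transcriptome(tx1, f1, g1)
  write_transcriptome(tx2, f2, g2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  fp1 <- simulate_footprints(tx1, "pelo-1", config = cfg, seed = 99)
  fp2 <- simulate_footprints(tx1, "pelo-1", config = cfg, seed = 99)
  expect_identical(fp1, fp2)
})

test_that("transcriptome FASTA + GFF3 round trip preserves the model", {
  skip_if_not_installed("rtracklayer")
  tx <- tiny_tx()
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_transcriptome(tx, fa, gff)
  back <- read_transcriptome(fa, gff)
  back <- back[match(tx$gene_id, back$gene_id), ]
  expect_equal(back$sequence, tx$sequence)
  expect_equal(back$cds_start, tx$cds_start)
  expect_equal(back$stop_start, tx$stop_start)
  expect_equal(back$polya_site, tx$polya_site)
  expect_equal(back$is_planted_target, tx$is_planted_target)
  expect_equal(back$expression_level, tx$expression_level, tolerance = 1e-6)
  expect_equal(purrr::map(back$stall_sites, as.data.frame),
               purrr::map(tx$stall_sites, as.data.frame))
})

test_that("footprint simulation honours depth, genotype and labels", {
  cfg <- tiny_config()
  tx <- tiny_tx(cfg)
  expect_equal(nrow(simulate_footprints(tx, "WT", config = cfg, depth = 0)), 0)
  expect_error(simulate_footprints(tx, "ski-7", config = cfg),
               class = "riboshort_genotype_error")
  expect_error(simulate_footprints(tx, "WT", smg = "smg2", config = cfg),
               class = "riboshort_genotype_error")
})

test_that("unique molecule counts follow the Poisson expectation", {
  cfg <- sim_config(n_genes = 6, include_reporter = FALSE,
                    include_ptc = FALSE, include_endo = FALSE,
                    replicate_dispersion = 0, pcr_duplication_p = 0,
                    depth = 4e4, seed = 21)
  tx <- generate_transcriptome(cfg)
  fp <- simulate_footprints(tx, "WT", config = cfg)
  dd <- collapse_duplicates(fp)
  per_gene <- table(factor(dd$transcript_id, levels = tx$gene_id))
  mu <- cfg$depth * tx$expression_level
  expect_true(all(abs(as.numeric(per_gene) - mu) <= 4 * sqrt(mu) + 1))
})

test_that("stall-derived 3' ends respect stop-codon truncation rules", {
  # huge stall boost so the stop peak dwarfs background; UGA: never a 3' end
  # past the second base of the stop
  boosts <- list(
    "WT" = c(THREE_PRIME_END = 1, STOP_CODON = 1, INTERNAL_ENDO = 1),
    "skih-2" = c(THREE_PRIME_END = 1, STOP_CODON = 1, INTERNAL_ENDO = 1),
    "pelo-1" = c(THREE_PRIME_END = 1, STOP_CODON = 100, INTERNAL_ENDO = 1),
    "skih-2 pelo-1" = c(THREE_PRIME_END = 1, STOP_CODON = 100,
                        INTERNAL_ENDO = 1)
  )
  cfg <- sim_config(n_genes = 1, include_reporter = FALSE,
                    include_ptc = FALSE, include_endo = FALSE,
                    stall_boost = boosts, replicate_dispersion = 0,
                    pcr_duplication_p = 0)
  for (codon in c("TGA", "TAA")) {
    tx <- make_transcript(stop_codon = codon)
    fp <- simulate_footprints(tx, "pelo-1", config = cfg, depth = 3e4,
                              seed = 17)
    fp <- fp[assign_size_class(fp$length) == "SHORT", ]
    three_prime <- fp$five_prime + fp$length - 1L
    s <- tx$stop_start
    tally <- tabulate(factor(three_prime, levels = 0:(tx$polya_site - 1L)),
                      nbins = tx$polya_site)
    at <- function(p) tally[p + 1L]
    if (codon == "TGA") {
      # peak after the 2nd stop base; position s+2 carries background only
      expect_gt(at(s + 1L), 50 * max(at(s + 2L), 1))
    } else {
      # UAA: truncation after 2nd or 3rd base, roughly evenly
      expect_gt(at(s + 1L), 100)
      expect_gt(at(s + 2L), 100)
      expect_lt(abs(at(s + 1L) - at(s + 2L)) /
                  (at(s + 1L) + at(s + 2L)), 0.2)
    }
    # a full stop codon with an attached downstream base never occurs:
    # nothing can reach past s+3 (background length limit) and the
    # stall machinery never emits a 3' end at s+3 or beyond
    expect_equal(sum(three_prime > s + 3L), 0)
  }
})

test_that("smg_residual = 1 makes smg backgrounds indistinguishable", {
  cfg <- sim_config(n_genes = 15, n_targets = 3, depth = 2e4,
                    smg_residual = 1, seed = 13)
  tx <- generate_transcriptome(cfg)
  a <- simulate_footprints(tx, "skih-2 pelo-1", "smg+", cfg, seed = 55)
  b <- simulate_footprints(tx, "skih-2 pelo-1", "smg-1", cfg, seed = 55)
  expect_identical(a, b)
})

test_that("read records conserve molecule counts through duplication", {
  cfg <- sim_config(n_genes = 10, n_targets = 0, depth = 1e4,
                    pcr_duplication_p = 0.2, seed = 31)
  tx <- generate_transcriptome(cfg)
  fp <- simulate_footprints(tx, "WT", config = cfg)
  keys <- paste(fp$transcript_id, fp$five_prime, fp$length, fp$umi)
  dd <- collapse_duplicates(fp)
  expect_equal(nrow(dd), length(unique(keys)))
  expect_gte(nrow(fp), nrow(dd))
})

test_that("count-level and molecule-level simulators agree in distribution", {
  cfg <- sim_config(n_genes = 30, depth = 1e5, replicate_dispersion = 0,
                    pcr_duplication_p = 0, seed = 8)
  tx <- generate_transcriptome(cfg)
  reps <- purrr::map(1:3, function(r) {
    mol <- simulate_footprints(tx, "pelo-1", config = cfg, seed = 100 + r)
    count_gene_occupancy(collapse_duplicates(mol), tx, "SHORT")$count
  })
  mol_mean <- purrr::reduce(reps, `+`) / 3
  cl <- purrr::map(1:3, function(r) {
    simulate_footprint_counts(tx, "pelo-1", config = cfg, seed = 200 + r) |>
      dplyr::filter(.data$size_class == "SHORT") |>
      dplyr::pull(.data$count)
  })
  cl_mean <- purrr::reduce(cl, `+`) / 3
  # same expectation gene by gene, within Monte-Carlo error
  expect_true(all(abs(mol_mean - cl_mean) <=
                    5 * sqrt(pmax(mol_mean, 1) / 3) + 3))
})

test_that("short-footprint stop enrichment is monotone in the stall boost", {
  res <- purrr::map_dbl(c(1, 2.5, 5), function(b) {
    boosts <- list(
      "WT" = c(THREE_PRIME_END = 1, STOP_CODON = 1, INTERNAL_ENDO = 1),
      "skih-2" = c(THREE_PRIME_END = 1, STOP_CODON = 1, INTERNAL_ENDO = 1),
      "pelo-1" = c(THREE_PRIME_END = b, STOP_CODON = b, INTERNAL_ENDO = b),
      "skih-2 pelo-1" = c(THREE_PRIME_END = 5, STOP_CODON = 5,
                          INTERNAL_ENDO = 5)
    )
    cfg <- sim_config(n_genes = 60, depth = 3e5, stall_boost = boosts,
                      seed = 19)
    tx <- generate_transcriptome(cfg)
    fp <- collapse_duplicates(simulate_footprints(tx, "pelo-1", config = cfg,
                                                  seed = 23))
    sh <- fp[assign_size_class(fp$length) == "SHORT", ]
    prof <- metagene(coverage_track(sh, "FIVE_PRIME", 1e6),
                     tx[tx$gene_class == "background", ])
    metagene_stop_enrichment(prof)
  })
  expect_true(all(diff(res) > 0))
  expect_lt(abs(res[1] - 1), 0.2)   # boost 1 adds nothing above background
})

test_that("RNA-seq coverage is uniform except across a PTC with NMD intact", {
  cfg <- sim_config(n_genes = 20, seed = 2)
  tx <- generate_transcriptome(cfg)
  ptc <- tx[tx$gene_class == "ptc", ]
  ptc_pos <- ptc$stall_sites[[1]]$position[1]
  regions <- list(a = c(ptc$cds_start, ptc_pos - 41L),
                  b = c(ptc_pos + 40L, ptc$polya_site - 41L))
  ratio_for <- function(genotype, smg, gene) {
    depth <- 4e4 / tx$expression_level[tx$gene_id == gene]
    fr <- simulate_rnaseq(tx, genotype, smg, cfg, depth = depth, seed = 71)
    fr <- fr[fr$transcript_id == gene, ]
    trk <- coverage_track(dplyr::rename(fr, five_prime = "start"),
                          "FULL_SPAN", 1e6)
    region_ratio(trk, regions$a, regions$b, transcript_id = gene)
  }
  expect_equal(ratio_for("skih-2 pelo-1", "smg+", ptc$gene_id),
               cfg$bimodal_ratio, tolerance = 0.1)
  # bimodality is smg-dependent and absent from ordinary genes
  expect_equal(ratio_for("skih-2 pelo-1", "smg-1", ptc$gene_id), 1,
               tolerance = 0.1)
  bg <- tx$gene_id[tx$gene_class == "background"][1]
  bg_row <- tx[tx$gene_id == bg, ]
  fr <- simulate_rnaseq(tx, "WT", config = cfg,
                        depth = 4e4 / bg_row$expression_level, seed = 72)
  trk <- coverage_track(
    dplyr::rename(fr[fr$transcript_id == bg, ], five_prime = "start"),
    "FULL_SPAN", 1e6)
  mid <- (bg_row$cds_start + bg_row$stop_start) %/% 2
  expect_equal(
    region_ratio(trk, c(bg_row$cds_start, mid), c(mid + 1L, bg_row$stop_start),
                 transcript_id = bg),
    1, tolerance = 0.1)
})

test_that("simulated BSA pools match the recombination model", {
  bc <- bsa_config(chrom_length = 3e6, suppressor_position = 1.5e6,
                   distance_scale = 5e5, pool_depth = 60, seed = 6)
  pool <- simulate_bsa_pool(bc)
  # exhaustive spacing check
  expect_true(all(diff(pool$pos) >= 700 & diff(pool$pos) <= 1300))
  d <- abs(pool$pos - bc$suppressor_position)
  expect_equal(pool$expected_fraction, 0.5 * (1 - exp(-d / 5e5)))
  # model limits: ~0 at the locus, 0.5 far away
  expect_lt(min(pool$expected_fraction), 0.001)
  expect_equal(max(pool$expected_fraction), 0.5, tolerance = 0.06)
  expect_warning(zero <- simulate_bsa_pool(bsa_config(
    chrom_length = 2e5, suppressor_position = 1e5, pool_depth = 0)),
    "pool_depth")
  expect_true(all(zero$total_count == 0))
  expect_true(attr(zero, "zero_depth"))
})
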