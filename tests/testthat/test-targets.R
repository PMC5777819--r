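test_that("fold changes follow normalized replicate ratios", {
  counts <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g", genotype = "WT", replicate = 1:2,
                   count = c(100L, 100L), library_total = 1e6),
    tibble::tibble(gene_id = "g", genotype = "skih-2", replicate = 1:2,
                   count = c(700L, 720L), library_total = 1e6)
  )
  fc <- estimate_fold_change(counts, "skih-2", "WT")
  expect_equal(fc$folds[[1]], c(7.0, 7.2))
  expect_equal(fc$mean_fold, 7.1)
  expect_equal(fc$sd_fold, 0.1414, tolerance = 1e-3)

  same <- estimate_fold_change(
    dplyr::mutate(counts, count = 50L), "skih-2", "WT")
  expect_equal(same$mean_fold, 1.0)
  expect_equal(same$sd_fold, 0)

  expect_error(estimate_fold_change(counts[0, ], "skih-2", "WT"),
               class = "riboshort_counts_error")
})

test_that("planted reporter mRNA multipliers are recovered from RNA-seq", {
  cfg <- sim_config(n_genes = 100, depth = 2e5, seed = 47)
  tx <- generate_transcriptome(cfg)
  counts <- purrr::map(c("WT", "pelo-1"), function(gt) {
    purrr::map(1:2, function(r) {
      fr <- simulate_rnaseq(tx, gt, config = cfg,
                            seed = 100 + 7 * match(gt, GENOTYPES) + r)
      count_fragments(fr) |> dplyr::mutate(genotype = gt, replicate = r)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  fc <- estimate_fold_change(counts, "pelo-1", "WT",
                             genes = tx$gene_id[tx$gene_class == "reporter"])
  expect_equal(fc$mean_fold, cfg$mrna_multiplier[["pelo-1"]],
               tolerance = 0.1)
})

test_that("the Bonferroni threshold is the exact family-wise identity", {
  expect_equal(bonferroni_threshold(0.05, 18302), 2.7319e-6,
               tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 20000), 2.5e-6)
  withr::local_seed(1)
  for (i in 1:20) {
    a <- runif(1, 0.001, 0.2)
    n <- sample.int(5e4, 1)
    expect_equal(bonferroni_threshold(a, n) * n, a)
  }
})

test_that("pure mRNA-level changes produce no interaction call", {
  # SHORT and LONG both rise 5x in the double mutant: the ratio of ratios
  # cancels and the gene must not be called
  counts <- hand_counts(list(
    g1 = c(2000, 2100, 10000, 10500,   # LONG: WT, WT, DM, DM
           400, 380, 2000, 1900)       # SHORT: WT, WT, DM, DM
  ))
  fit <- call_ski_pelo_targets(counts, n_genes = 1000)
  res <- tidy(fit)
  expect_lt(abs(res$interaction_estimate), 0.3)
  expect_false(res$called)
})

test_that("the caller validates its input design", {
  counts <- hand_counts(list(g1 = rep(100L, 8)))
  expect_error(call_ski_pelo_targets(dplyr::select(counts, -"replicate")),
               "replicate", class = "riboshort_counts_error")
  expect_error(call_ski_pelo_targets(counts[counts$replicate == 1, ]),
               class = "riboshort_counts_error")
})

test_that("all-zero genes get p = 1 and calls imply positive enrichment", {
  counts <- dplyr::bind_rows(
    hand_counts(list(g0 = rep(0L, 8))),
    hand_counts(list(g1 = c(1000, 1010, 990, 1000,   # LONG
                            200, 190, 1400, 1450)))  # SHORT up in DM
  )
  fit <- call_ski_pelo_targets(counts, n_genes = 2)
  res <- tidy(fit)
  expect_equal(res$p_value[res$gene_id == "g0"], 1)
  expect_false(res$called[res$gene_id == "g0"])
  called <- res[res$called, ]
  expect_true(all(called$p_value < fit$cutoff))
  expect_true(all(called$interaction_estimate > 0))
})

test_that("p-values fall monotonically with the planted interaction", {
  ps <- purrr::map_dbl(c(1, 2, 4, 8), function(effect) {
    counts <- hand_counts(list(g = c(
      5000, 5050, 4950, 5000,
      1000, 1010, round(1000 * effect), round(1010 * effect)
    )))
    tidy(call_ski_pelo_targets(counts, n_genes = 100))$p_value
  })
  expect_true(all(diff(ps) < 0))
})

test_that("the caller is invariant to global library rescaling", {
  counts <- hand_counts(list(g = c(3000, 3050, 2900, 3010,
                                   600, 620, 2400, 2380)))
  fit1 <- tidy(call_ski_pelo_targets(counts, n_genes = 10))
  scaled <- dplyr::mutate(counts, count = count * 3L,
                          library_total = library_total * 3)
  fit3 <- tidy(call_ski_pelo_targets(scaled, n_genes = 10))
  expect_equal(fit1$interaction_estimate, fit3$interaction_estimate,
               tolerance = 0.02)
  expect_equal(log10(fit1$p_value), log10(fit3$p_value), tolerance = 0.2)
})

test_that("tidy and glance summarise a fit, and calls survive the TSV", {
  cfg <- sim_config(n_genes = 200, n_targets = 25, include_reporter = FALSE,
                    include_ptc = FALSE, include_endo = FALSE,
                    background_stop_stall = FALSE, depth = 3e6, seed = 53)
  tx <- generate_transcriptome(cfg)
  cm <- simulate_count_matrix(tx, config = cfg, seed = 53)
  fit <- call_ski_pelo_targets(cm)
  res <- tidy(fit)
  expect_s3_class(res, "tbl_df")
  expect_equal(nrow(res), 200)
  g <- glance(fit)
  expect_equal(g$n_called, sum(res$called))
  expect_equal(g$cutoff, 0.05 / 200)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_target_calls(fit, path)
  expect_match(readLines(path, n = 1), "cutoff")
  back <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(back), 200)
  expect_false(is.unsorted(back$p_value))
})

test_that("the NB interaction caller agrees with an independent DESeq2 fit", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(n_genes = 300, n_targets = 40, include_reporter = FALSE,
                    include_ptc = FALSE, include_endo = FALSE,
                    background_stop_stall = FALSE, depth = 5e6, seed = 59)
  tx <- generate_transcriptome(cfg)
  cm <- simulate_count_matrix(tx, config = cfg, seed = 59)
  fit <- tidy(call_ski_pelo_targets(cm))

  wide <- cm |>
    dplyr::mutate(lib = paste(genotype, size_class, replicate, sep = ".")) |>
    dplyr::select("gene_id", "lib", "count") |>
    tidyr::pivot_wider(names_from = "lib", values_from = "count")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$gene_id
  coldata <- data.frame(
    genotype = factor(sub("\\..*", "", colnames(mat)),
                      levels = c("WT", "skih-2 pelo-1")),
    size_class = factor(sub(".*\\.(\\w+)\\.\\d+$", "\\1", colnames(mat)),
                        levels = c("LONG", "SHORT"))
  )
  dds <- DESeq2::DESeqDataSetFromMatrix(mat, coldata,
                                        ~ genotype * size_class)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  interaction_name <- utils::tail(DESeq2::resultsNames(dds), 1)
  res <- DESeq2::results(dds, name = interaction_name)
  merged <- dplyr::inner_join(
    fit, tibble::tibble(gene_id = rownames(res), deseq_p = res$pvalue,
                        deseq_lfc = res$log2FoldChange), by = "gene_id")
  # same enrichment contrast, independently fitted machinery
  expect_gt(cor(merged$interaction_estimate, merged$deseq_lfc,
                use = "complete.obs"), 0.95)
  planted <- tx$gene_id[tx$is_planted_target]
  top_ours <- merged$gene_id[rank(merged$p_value) <= 40]
  top_deseq <- merged$gene_id[rank(merged$deseq_p) <= 40]
  expect_gt(length(intersect(top_ours, planted)), 35)
  expect_gt(length(intersect(top_ours, top_deseq)), 30)
})

test_that("smg dependence fractions normalize per million and flag targets", {
  plus <- tibble::tibble(gene_id = c("a", "b", "c"),
                         count = c(95L, 50L, 0L), library_total = 1e6)
  minus <- tibble::tibble(gene_id = c("a", "b", "c"),
                          count = c(5L, 50L, 0L), library_total = 1e6)
  expect_warning(fr <- smg_dependence_fraction(plus, minus), "zero")
  expect_equal(fr$fraction[fr$gene_id == "a"], 0.05)
  expect_true(fr$smg_dependent[fr$gene_id == "a"])
  expect_equal(fr$fraction[fr$gene_id == "b"], 0.5)
  expect_false(fr$smg_dependent[fr$gene_id == "b"])
  expect_true(is.na(fr$fraction[fr$gene_id == "c"]))

  # unequal totals: normalization matters
  fr2 <- suppressWarnings(
    smg_dependence_fraction(plus, minus, library_totals = c(1e6, 2e6)))
  expect_equal(fr2$fraction[fr2$gene_id == "b"], 1 / 3)
})
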