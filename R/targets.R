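#' Bonferroni p-value cutoff
#'
#' Family-wise cutoff `alpha / n_genes` used to declare SKI/PELO targets
#' (with the ~18,302 annotated genes this reproduces the 2.7319e-6 cutoff
#' used genome-wide).
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_genes number of genes tested (>= 1).
#' @return The per-gene p-value cutoff.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 18302)
bonferroni_threshold <- function(alpha, n_genes) {
  stopifnot(alpha > 0, alpha < 1, n_genes >= 1)
  alpha / n_genes
}

#' Per-gene fold changes between two conditions
#'
#' For each replicate `i`, the fold is the ratio of library-size-normalized
#' counts `(count_a / total_a) / (count_b / total_b)`; zero counts receive a
#' pseudocount of 0.5 (Haldane correction). The mean and SD across
#' replicates are reported, as in "fold +/- SD from n biological
#' replicates".
#'
#' @param counts long tibble with `gene_id`, a condition column, `replicate`,
#'   `count` and `library_total`.
#' @param condition_a,condition_b condition labels (numerator, denominator).
#' @param genes genes to report (default all).
#' @param condition_col name of the condition column (default `"genotype"`).
#' @return Tibble: `gene_id`, `condition_a`, `condition_b`, `n_replicates`,
#'   `folds` (list column of per-replicate folds), `mean_fold`, `sd_fold`.
#' @export
estimate_fold_change <- function(counts, condition_a, condition_b,
                                 genes = NULL,
                                 condition_col = "genotype") {
  cc <- counts[[condition_col]]
  if (is.null(cc)) {
    abort(sprintf("counts have no `%s` column.", condition_col),
          class = "riboshort_counts_error")
  }
  counts <- counts[cc %in% c(condition_a, condition_b), ]
  if (!is.null(genes)) counts <- counts[counts$gene_id %in% genes, ]
  if (nrow(counts) == 0L || length(unique(counts$replicate)) < 1L) {
    abort("no replicated counts for the requested conditions.",
          class = "riboshort_counts_error")
  }

  normed <- counts |>
    mutate(condition = .data[[condition_col]],
           norm = (pmax(.data$count, 0) +
                     ifelse(.data$count == 0, 0.5, 0)) / .data$library_total)
  paired <- normed |>
    select("gene_id", "condition", "replicate", "norm") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "norm")
  if (!all(c(condition_a, condition_b) %in% names(paired))) {
    abort("both conditions must be present in the counts.",
          class = "riboshort_counts_error")
  }
  paired |>
    mutate(fold = .data[[condition_a]] / .data[[condition_b]]) |>
    group_by(.data$gene_id) |>
    summarise(
      n_replicates = dplyr::n(),
      folds = list(.data$fold),
      mean_fold = mean(.data$fold),
      sd_fold = if (dplyr::n() >= 2) stats::sd(.data$fold) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(condition_a = condition_a, condition_b = condition_b) |>
    select("gene_id", "condition_a", "condition_b", "n_replicates",
           "folds", "mean_fold", "sd_fold")
}

# method-of-moments NB dispersion across within-condition replicates,
# pooled over the four design cells: on the per-library rate scale
# q = count/total, Var(q) = E[q]/total + alpha E[q]^2, so the Poisson part
# subtracted is m * mean(1/total) at the correct scale
.mom_dispersion <- function(y, totals, cell) {
  alphas <- purrr::map_dbl(split(seq_along(y), cell), function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    q <- y[idx] / totals[idx]
    m <- mean(q)
    if (m <= 0) return(NA_real_)
    (var(q) - m * mean(1 / totals[idx])) / m^2
  })
  est <- mean(alphas[is.finite(alphas)])
  if (!is.finite(est)) NA_real_ else est
}

# squeeze noisy per-gene estimates (a handful of residual df each) toward
# the cross-gene median, then apply the floor; with d0 = 0 the raw per-gene
# values are used
.moderate_dispersion <- function(raw, resid_df, prior_df, floor) {
  prior <- stats::median(raw[is.finite(raw) & raw > 0])
  if (!is.finite(prior)) prior <- floor
  raw[!is.finite(raw)] <- prior
  pmax((prior_df * prior + resid_df * raw) / (prior_df + resid_df), floor)
}

#' Call SKI/PELO target genes
#'
#' Identifies genes enriched for short (15-18 nt) footprints in the
#' ski-helicase/pelota double mutant relative to short footprints in wild
#' type and long (28-30 nt) footprints in either genotype - the signature of
#' a transcript feeding ribosome-rescue-dependent decay. Per gene, a
#' log-linear negative-binomial model with log-library-total offsets and
#' terms `intercept + genotype + size_class + genotype:size_class` is fitted
#' over the 8 libraries (2 genotypes x 2 size classes x >= 2 replicates);
#' the gene's NB dispersion is estimated by method of moments across
#' within-condition replicates, moderated toward the cross-gene median
#' (each per-gene estimate carries only a few residual degrees of freedom,
#' so information is shared across genes as dispersion-trend methods do),
#' and floored at 0.01. The one-sided Wald p-value for a positive
#' interaction is compared against the Bonferroni cutoff
#' `alpha / n_genes`. Single-mutant libraries are ignored by design.
#'
#' @param counts long count tibble (`gene_id`, `genotype`, `size_class`,
#'   `replicate`, `count`, `library_total`) covering genotypes `"WT"` and
#'   `"skih-2 pelo-1"` and size classes `"SHORT"` and `"LONG"`, counts
#'   restricted to the CDS window (see [count_gene_occupancy()]).
#' @param alpha family-wise error rate.
#' @param n_genes number for the Bonferroni correction; defaults to the
#'   number of genes in `counts`.
#' @param dispersion_floor lower bound on the per-gene NB dispersion.
#' @param dispersion_prior_df prior degrees of freedom of the moderation
#'   (weight of the cross-gene median relative to the per-gene residual
#'   df); 0 disables moderation.
#' @return An object of class `ski_pelo_fit`; see [tidy.ski_pelo_fit()] for
#'   the per-gene table (`gene_id`, `interaction_estimate` in log2,
#'   `standard_error`, `p_value`, `dispersion`, `called`).
#' @export
call_ski_pelo_targets <- function(counts, alpha = 0.05, n_genes = NULL,
                                  dispersion_floor = 0.01,
                                  dispersion_prior_df = 40) {
  needed <- c("gene_id", "genotype", "size_class", "replicate", "count",
              "library_total")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols) > 0) {
    abort(sprintf("counts are missing required columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "riboshort_counts_error")
  }
  counts <- counts[counts$genotype %in% c("WT", "skih-2 pelo-1") &
                     counts$size_class %in% c("SHORT", "LONG"), ]
  design <- counts |>
    distinct(.data$genotype, .data$size_class, .data$replicate)
  cells <- design |> count(.data$genotype, .data$size_class)
  if (nrow(cells) != 4L || any(cells$n < 2L)) {
    abort(paste0("counts must cover {WT, skih-2 pelo-1} x {SHORT, LONG} ",
                 "with >= 2 replicates each."),
          class = "riboshort_counts_error")
  }

  counts <- counts |>
    arrange(.data$gene_id, .data$genotype, .data$size_class, .data$replicate)
  n_lib <- nrow(design)
  first <- counts[seq_len(n_lib) + 0L, ]   # shared design across genes
  genotype <- factor(first$genotype, levels = c("WT", "skih-2 pelo-1"))
  size_class <- factor(first$size_class, levels = c("LONG", "SHORT"))
  X <- stats::model.matrix(~ genotype * size_class)
  offset <- log(first$library_total)
  cell <- interaction(genotype, size_class)

  genes <- unique(counts$gene_id)
  if (nrow(counts) != n_lib * length(genes)) {
    abort("counts must contain one row per gene per library.",
          class = "riboshort_counts_error")
  }
  if (is.null(n_genes)) n_genes <- length(genes)
  cutoff <- bonferroni_threshold(alpha, n_genes)

  y_mat <- matrix(counts$count, nrow = n_lib)
  colnames(y_mat) <- genes

  # per-gene method-of-moments dispersions, moderated across genes
  raw_disp <- vapply(seq_along(genes), function(i) {
    .mom_dispersion(y_mat[, i], first$library_total, cell)
  }, numeric(1))
  resid_df <- sum(cells$n - 1L)
  disp_all <- .moderate_dispersion(raw_disp, resid_df, dispersion_prior_df,
                                   dispersion_floor)

  fit_one <- function(y, disp) {
    if (all(y == 0)) {
      return(c(est = 0, se = NA_real_, p = 1, disp = disp))
    }
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        x = X, y = y, offset = offset,
        family = MASS::negative.binomial(theta = 1 / disp, link = "log"),
        control = stats::glm.control(maxit = 50)
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || anyNA(fit$coefficients)) {
      return(c(est = NA_real_, se = NA_real_, p = 1, disp = disp))
    }
    p_idx <- ncol(X)
    covmat <- tryCatch(
      chol2inv(fit$qr$qr[seq_len(p_idx), seq_len(p_idx), drop = FALSE]),
      error = function(e) NULL
    )
    if (is.null(covmat) || !is.finite(covmat[p_idx, p_idx]) ||
        covmat[p_idx, p_idx] <= 0) {
      return(c(est = NA_real_, se = NA_real_, p = 1, disp = disp))
    }
    est <- unname(fit$coefficients[p_idx])
    se <- sqrt(covmat[p_idx, p_idx])
    p <- pnorm(est / se, lower.tail = FALSE)
    c(est = est, se = se, p = p, disp = disp)
  }

  stats_mat <- vapply(seq_along(genes),
                      function(i) fit_one(y_mat[, i], disp_all[i]),
                      c(est = 0, se = 0, p = 0, disp = 0))
  results <- tibble(
    gene_id = genes,
    interaction_estimate = stats_mat["est", ] / log(2),
    standard_error = stats_mat["se", ] / log(2),
    p_value = stats_mat["p", ],
    dispersion = stats_mat["disp", ],
    called = stats_mat["p", ] < cutoff &
      !is.na(stats_mat["est", ]) & stats_mat["est", ] > 0
  )
  structure(
    list(results = results, alpha = alpha, n_genes = n_genes,
         cutoff = cutoff),
    class = "ski_pelo_fit"
  )
}

#' @export
print.ski_pelo_fit <- function(x, ...) {
  cat(sprintf(
    "SKI/PELO target call: %d of %d genes called at p < %.4g (alpha %.3g / %d)\n",
    sum(x$results$called), nrow(x$results), x$cutoff, x$alpha, x$n_genes
  ))
  print(head(arrange(x$results, .data$p_value)), ...)
  invisible(x)
}

#' Write target calls as TSV (sorted by p-value)
#'
#' @param fit a `ski_pelo_fit`.
#' @param path output path; the cutoff is recorded in a `#` header line.
#' @export
write_target_calls <- function(fit, path) {
  stopifnot(inherits(fit, "ski_pelo_fit"))
  writeLines(sprintf("#alpha=%g;n_genes=%d;cutoff=%g",
                     fit$alpha, fit$n_genes, fit$cutoff), path)
  readr::write_tsv(arrange(fit$results, .data$p_value), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Per-gene smg-dependence of short footprints
#'
#' Given matched short-footprint counts from an NMD-proficient (`smg+`) and
#' an NMD-deficient (`smg-1`) library (same rescue-deficient background),
#' computes per gene the fraction of per-million-normalized short reads that
#' come from the `smg-1` mutant:
#' `fraction = cpm_minus / (cpm_plus + cpm_minus)`. Genes whose short
#' footprints require the NMD pathway lose them in the mutant, so a fraction
#' below 0.05 (>95% of reads from the `smg+` strain) flags a strongly
#' smg-dependent gene; smg-independent stall classes (internal
#' endonucleolytic sites) sit near 0.5.
#'
#' @param counts_smg_plus,counts_smg_minus tibbles with `gene_id`, `count`.
#' @param library_totals numeric vector `c(plus, minus)` of uniquely-mapped
#'   totals; defaults to each table's `library_total` column.
#' @param flag_below fractions at or below this are flagged.
#' @return Tibble: `gene_id`, `cpm_smg_plus`, `cpm_smg_minus`, `fraction`
#'   (`NA` when both normalized counts are 0), `smg_dependent`.
#' @export
smg_dependence_fraction <- function(counts_smg_plus, counts_smg_minus,
                                    library_totals = NULL,
                                    flag_below = 0.05) {
  if (is.null(library_totals)) {
    library_totals <- c(counts_smg_plus$library_total[1],
                        counts_smg_minus$library_total[1])
  }
  stopifnot(length(library_totals) == 2L, all(library_totals > 0))
  joined <- full_join(
    counts_smg_plus |> select("gene_id", plus = "count"),
    counts_smg_minus |> select("gene_id", minus = "count"),
    by = "gene_id"
  ) |>
    mutate(
      cpm_smg_plus = coalesce(.data$plus, 0L) / library_totals[1] * 1e6,
      cpm_smg_minus = coalesce(.data$minus, 0L) / library_totals[2] * 1e6,
      fraction = ifelse(
        .data$cpm_smg_plus + .data$cpm_smg_minus > 0,
        .data$cpm_smg_minus / (.data$cpm_smg_plus + .data$cpm_smg_minus),
        NA_real_
      ),
      smg_dependent = !is.na(.data$fraction) & .data$fraction <= flag_below
    )
  if (any(is.na(joined$fraction))) {
    warn(sprintf("%d genes have zero normalized counts in both libraries",
                 sum(is.na(joined$fraction))))
  }
  joined |>
    select("gene_id", "cpm_smg_plus", "cpm_smg_minus", "fraction",
           "smg_dependent")
}
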