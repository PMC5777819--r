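#' Pipeline configuration
#'
#' Assembles and validates the structured configuration consumed by
#' [run_stage()]. All randomness of a run flows from the single top-level
#' `seed`; per-library seeds are derived from it deterministically.
#'
#' @param out_dir directory stage outputs are written to.
#' @param seed top-level integer seed.
#' @param sim named list of [sim_config()] arguments.
#' @param bsa named list of [bsa_config()] arguments.
#' @param libraries list of library descriptors, each a named list with
#'   `genotype`, `smg` and `replicate`.
#' @param alpha family-wise error rate for target calling.
#' @param metagene_window,min_reads metagene parameters.
#' @param metacodon_codons codons profiled by the metacodon stage.
#' @param phase_window,phase_max_lag autocorrelation parameters.
#' @param linkage_threshold,bsa_window_size BSA mapping parameters.
#' @return A validated list with class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "riboshort_run",
                            seed = 1L,
                            sim = list(),
                            bsa = list(),
                            libraries = list(
                              list(genotype = "WT", smg = "smg+",
                                   replicate = 1),
                              list(genotype = "WT", smg = "smg+",
                                   replicate = 2),
                              list(genotype = "skih-2 pelo-1", smg = "smg+",
                                   replicate = 1),
                              list(genotype = "skih-2 pelo-1", smg = "smg+",
                                   replicate = 2)
                            ),
                            alpha = 0.05,
                            metagene_window = c(-120L, 12L),
                            min_reads = 10,
                            metacodon_codons = c("TGA", "TAA", "TAG"),
                            phase_window = 300L,
                            phase_max_lag = 100L,
                            linkage_threshold = 0.1,
                            bsa_window_size = 100L) {
  cfg <- structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim, bsa = bsa,
         libraries = libraries, alpha = alpha,
         metagene_window = as.integer(metagene_window),
         min_reads = min_reads, metacodon_codons = metacodon_codons,
         phase_window = as.integer(phase_window),
         phase_max_lag = as.integer(phase_max_lag),
         linkage_threshold = linkage_threshold,
         bsa_window_size = as.integer(bsa_window_size)),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
}

#' @rdname pipeline_config
#' @param config object to validate.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (i in seq_along(config$libraries)) {
    lib <- config$libraries[[i]]
    for (field in c("genotype", "smg", "replicate")) {
      if (is.null(lib[[field]])) {
        abort(sprintf("library %d is missing required field `%s`.", i, field),
              class = "riboshort_config_error")
      }
    }
    .check_genotype(lib$genotype, lib$smg)
  }
  if (config$alpha <= 0 || config$alpha >= 1) {
    abort("field `alpha` must be in (0, 1).",
          class = "riboshort_config_error")
  }
  # constructing the sub-configs validates their fields
  do.call(sim_config, config$sim)
  do.call(bsa_config, config$bsa)
  invisible(config)
}

#' @rdname pipeline_config
#' @param path YAML file holding the configuration.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$libraries <- purrr::map(raw$libraries, as.list)
  do.call(pipeline_config, raw)
}

.lib_tag <- function(lib) {
  sprintf("%s_%s_rep%d", gsub("[^a-zA-Z0-9]+", "", lib$genotype),
          gsub("[^a-zA-Z0-9+]+", "", sub("\\+$", "plus", lib$smg)),
          as.integer(lib$replicate))
}

.lib_seed <- function(config, lib) {
  (config$seed + 1009L * match(lib$genotype, GENOTYPES) +
     101L * match(lib$smg, SMG_BACKGROUNDS) +
     7919L * as.integer(lib$replicate)) %% .Machine$integer.max
}

#' Run a pipeline stage
#'
#' Orchestrates the analysis as file-based stages in `config$out_dir`:
#' `simulate` writes the transcriptome (FASTA + GFF3) and one footprint BED
#' per configured library; `dedup` collapses PCR duplicates; `count` builds
#' the CDS-window count matrix; `metagene`, `metacodon` and `phase` compute
#' the profile statistics; `call-targets` runs the NB interaction test;
#' `smg-fraction` computes per-gene smg dependence (requires smg+ and smg-1
#' libraries of the same genotype); `bsa-map` simulates and maps a
#' bulk-segregant pool; `all` runs every stage in order. A
#' `run_manifest.json` records the configuration hash, seed and package
#' version.
#'
#' @param stage one of `"simulate"`, `"dedup"`, `"count"`, `"metagene"`,
#'   `"metacodon"`, `"phase"`, `"call-targets"`, `"smg-fraction"`,
#'   `"bsa-map"`, `"all"`.
#' @param config a [pipeline_config()].
#' @return Invisibly, the paths written by the stage.
#' @export
run_stage <- function(stage = c("simulate", "dedup", "count", "metagene",
                                "metacodon", "phase", "call-targets",
                                "smg-fraction", "bsa-map", "all"),
                      config) {
  stage <- match.arg(stage)
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, paste0(...))

  if (stage == "all") {
    stages <- c("simulate", "dedup", "count", "metagene", "metacodon",
                "phase", "call-targets", "bsa-map")
    smgs <- unique(purrr::map_chr(config$libraries, "smg"))
    if (length(smgs) > 1L) stages <- c(stages, "smg-fraction")
    paths <- unlist(purrr::map(stages, run_stage, config = config))
    return(invisible(paths))
  }

  scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  tx <- NULL
  load_tx <- function() {
    if (file.exists(out("transcriptome.gff3"))) {
      read_transcriptome(out("transcriptome.fa"), out("transcriptome.gff3"))
    } else {
      generate_transcriptome(scfg)
    }
  }
  dedup_lib <- function(lib) {
    path <- out("footprints_", .lib_tag(lib), "_dedup.bed")
    if (!file.exists(path)) {
      abort(sprintf("missing input %s; run the dedup stage first.", path),
            class = "riboshort_input_error")
    }
    read_footprints_bed(path)
  }
  message(sprintf("[riboshort] running stage %s -> %s", stage,
                  config$out_dir))

  paths <- switch(
    stage,
    "simulate" = {
      tx <- generate_transcriptome(scfg)
      write_transcriptome(tx, out("transcriptome.fa"),
                          out("transcriptome.gff3"))
      bed <- purrr::map_chr(config$libraries, function(lib) {
        fp <- simulate_footprints(tx, lib$genotype, lib$smg, scfg,
                                  seed = .lib_seed(config, lib))
        p <- out("footprints_", .lib_tag(lib), ".bed")
        write_footprints_bed(fp, p)
        p
      })
      c(out("transcriptome.fa"), out("transcriptome.gff3"), bed)
    },
    "dedup" = {
      purrr::map_chr(config$libraries, function(lib) {
        fp <- read_footprints_bed(out("footprints_", .lib_tag(lib), ".bed"))
        p <- out("footprints_", .lib_tag(lib), "_dedup.bed")
        write_footprints_bed(collapse_duplicates(fp), p)
        p
      })
    },
    "count" = {
      tx <- load_tx()
      counts <- purrr::map(config$libraries, function(lib) {
        fp <- dedup_lib(lib)
        purrr::map(c("SHORT", "LONG"), function(sc) {
          cls <- assign_size_class(fp$length)
          count_gene_occupancy(fp, tx, size_class = sc) |>
            mutate(genotype = lib$genotype, smg = lib$smg,
                   replicate = as.integer(lib$replicate),
                   library_total = sum(cls == sc))
        }) |> bind_rows()
      }) |> bind_rows()
      write_count_matrix(counts, out("counts.tsv"))
      out("counts.tsv")
    },
    "metagene" = {
      tx <- load_tx()
      purrr::map_chr(config$libraries, function(lib) {
        fp <- dedup_lib(lib)
        fp <- fp[assign_size_class(fp$length) == "SHORT", ]
        track <- coverage_track(fp, "FIVE_PRIME", library_total = 1e6)
        prof <- metagene(track, tx, window = config$metagene_window,
                         min_reads = config$min_reads)
        p <- out("metagene_", .lib_tag(lib), ".tsv")
        write_profile_tsv(prof, p)
        p
      })
    },
    "metacodon" = {
      tx <- load_tx()
      purrr::map_chr(config$libraries, function(lib) {
        fp <- dedup_lib(lib)
        prof <- purrr::map(config$metacodon_codons, function(codon) {
          as_tibble(metacodon_termination(fp, tx, codon))
        }) |> bind_rows()
        p <- out("metacodon_", .lib_tag(lib), ".tsv")
        readr::write_tsv(prof, p)
        p
      })
    },
    "phase" = {
      tx <- load_tx()
      rep_tx <- tx[tx$gene_class == "reporter", ]
      if (nrow(rep_tx) == 0L) {
        abort("no reporter transcript in the annotation.",
              class = "riboshort_input_error")
      }
      purrr::map_chr(config$libraries, function(lib) {
        fp <- dedup_lib(lib)
        fp <- fp[assign_size_class(fp$length) == "SHORT", ]
        track <- coverage_track(fp, "FIVE_PRIME", library_total = 1e6)
        vals <- track_window_values(track, rep_tx$gene_id[1],
                                    rep_tx$polya_site[1] - config$phase_window,
                                    rep_tx$polya_site[1] - 1L)
        ac <- footprint_autocorrelation(vals, config$phase_max_lag)
        p <- out("autocorrelation_", .lib_tag(lib), ".tsv")
        write_autocorrelation_tsv(ac, p)
        p
      })
    },
    "call-targets" = {
      if (!file.exists(out("counts.tsv"))) {
        abort(sprintf("missing input %s; run the count stage first.",
                      out("counts.tsv")),
              class = "riboshort_input_error")
      }
      counts <- read_count_matrix(out("counts.tsv"))
      fit <- call_ski_pelo_targets(counts, alpha = config$alpha)
      write_target_calls(fit, out("targets.tsv"))
      out("targets.tsv")
    },
    "smg-fraction" = {
      tx <- load_tx()
      libs <- config$libraries
      smg_of <- purrr::map_chr(libs, "smg")
      plus <- libs[smg_of == "smg+"][1]
      minus <- libs[smg_of == "smg-1"][1]
      if (length(plus) == 0L || length(minus) == 0L ||
          is.null(plus[[1]]) || is.null(minus[[1]])) {
        abort("smg-fraction needs one smg+ and one smg-1 library.",
              class = "riboshort_config_error")
      }
      counts <- purrr::map(c(plus, minus), function(lib) {
        fp <- dedup_lib(lib)
        cls <- assign_size_class(fp$length)
        count_gene_occupancy(fp, tx, size_class = "SHORT",
                             region = "stop") |>
          mutate(library_total = sum(cls == "SHORT"))
      })
      frac <- smg_dependence_fraction(counts[[1]], counts[[2]])
      readr::write_tsv(frac, out("smg_fraction.tsv"))
      out("smg_fraction.tsv")
    },
    "bsa-map" = {
      bcfg <- do.call(bsa_config, c(config$bsa, list(seed = config$seed)))
      pool <- simulate_bsa_pool(bcfg)
      write_variants_tsv(pool, out("bsa_variants.tsv"))
      trk <- windowed_allele_frequency(pool, config$bsa_window_size)
      write_window_track_tsv(trk, out("bsa_windows.tsv"))
      write_linked_regions_bed(call_linked_regions(
        trk, config$linkage_threshold), out("bsa_linked.bed"))
      c(out("bsa_variants.tsv"), out("bsa_windows.tsv"),
        out("bsa_linked.bed"))
    }
  )

  manifest <- list(
    stage = stage,
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("riboshort")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
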