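# shared fixtures, built in code at test time

tiny_config <- function(...) {
  sim_config(n_genes = 12, n_targets = 2, depth = 5e3, seed = 7, ...)
}

tiny_tx <- function(cfg = tiny_config()) generate_transcriptome(cfg)

# one hand-built transcript with a chosen stop codon; 0-based coordinates
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  setdiff(as.vector(outer(outer(b, b, paste0), b, paste0)),
          c("TAA", "TAG", "TGA"))
}

make_transcript <- function(gene_id = "tx1", n_codons = 60, utr5 = 30,
                            utr3 = 50, stop_codon = "TGA",
                            stall = TRUE, seed = 1) {
  withr::local_seed(seed)
  body <- paste0(
    "ATG",
    paste(sample(sense_codons(), n_codons - 1, replace = TRUE),
          collapse = "")
  )
  seq <- paste0(paste(sample(c("A","C","G","T"), utr5, TRUE), collapse = ""),
                body, stop_codon,
                paste(sample(c("A","C","G","T"), utr3, TRUE), collapse = ""))
  cds_start <- utr5
  stop_start <- utr5 + 3L * n_codons
  stalls <- if (stall) {
    tibble::tibble(position = as.integer(stop_start), class = "STOP_CODON")
  } else {
    tibble::tibble(position = integer(), class = character())
  }
  tibble::tibble(
    gene_id = gene_id, sequence = seq, cds_start = as.integer(cds_start),
    stop_start = as.integer(stop_start), polya_site = nchar(seq),
    gene_class = "background", is_planted_target = FALSE,
    expression_level = 1, stall_sites = list(stalls)
  )
}

# random footprint table for oracle tests
random_footprints <- function(n, transcript_ids, max_pos = 400, seed = 1) {
  withr::local_seed(seed)
  tibble::tibble(
    transcript_id = sample(transcript_ids, n, replace = TRUE),
    five_prime = sample.int(max_pos, n, replace = TRUE) - 1L,
    length = sample(c(15:22, 28:30, 24), n, replace = TRUE),
    strand = "+",
    umi = replicate(n, paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                             collapse = ""))
  )
}

# a complete 8-library count table for one or more genes, built by hand;
# counts are ordered LONG (WT r1, WT r2, DM r1, DM r2) then SHORT likewise
hand_counts <- function(gene_counts, totals = rep(1e6, 8)) {
  design <- tidyr::expand_grid(
    size_class = c("LONG", "SHORT"),
    genotype = c("WT", "skih-2 pelo-1"),
    replicate = 1:2
  )
  purrr::imap(gene_counts, function(cts, gene) {
    design |>
      dplyr::mutate(gene_id = gene, count = as.integer(cts),
                    library_total = totals, smg = "smg+")
  }) |> dplyr::bind_rows()
}
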