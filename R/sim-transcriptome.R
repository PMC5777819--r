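STOP_CODONS <- c("TAA", "TAG", "TGA")

.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

SENSE_CODONS <- setdiff(.all_codons(), STOP_CODONS)

.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# CDS body of n_codons codons: ATG + sense codons, so no in-frame premature
# stop can occur by construction
.random_cds_body <- function(n_codons) {
  paste0("ATG", paste(sample(SENSE_CODONS, n_codons - 1L, replace = TRUE),
                      collapse = ""))
}

.stall_tbl <- function(position = integer(), class = character()) {
  tibble(position = as.integer(position), class = class)
}

#' Generate a synthetic transcriptome
#'
#' Builds single-isoform, plus-strand transcript models in transcript
#' coordinates (0-based): a 5' UTR, an ATG-initiated CDS free of in-frame
#' premature stop codons, a stop codon, and a 3' UTR ending at the poly(A)
#' site. Depending on the configuration the set contains one nonstop reporter
#' (its reading frame runs into the poly(A) site and carries a 3'-end stall),
#' one premature-stop-codon (PTC) allele with a stop-codon stall at an
#' internal in-frame stop, one gene with an internal endonucleolytic cut site
#' (smg-independent stall), `n_targets` planted SKI/PELO target genes
#' (boosted stop-codon stalls), and ordinary background genes.
#'
#' @param config a [sim_config()].
#' @param seed seed; defaults to `config$seed`.
#' @return A tibble with one row per transcript: `gene_id`, `sequence`,
#'   `cds_start`, `stop_start`, `polya_site` (0-based; the stop codon occupies
#'   `stop_start..stop_start+2`), `gene_class`, `is_planted_target`,
#'   `expression_level` (shares summing to 1), and a `stall_sites`
#'   list-column of `(position, class)` tibbles.
#' @export
#' @examples
#' tx <- generate_transcriptome(sim_config(n_genes = 12, n_targets = 2))
#' table(tx$gene_class)
generate_transcriptome <- function(config, seed = config$seed) {
  validate_sim_config(config)
  withr::local_seed(seed)

  n_special <- config$n_targets + config$include_reporter +
    config$include_ptc + config$include_endo
  n_background <- config$n_genes - n_special

  classes <- c(
    if (config$include_reporter) "reporter",
    if (config$include_ptc) "ptc",
    if (config$include_endo) "endo",
    rep("target", config$n_targets),
    rep("background", n_background)
  )
  n <- length(classes)

  # CDS length in nt (multiple of 3, floored), fixed for the special genes
  # so their geometry supports the analyses built on them
  cds_len <- pmax(
    round(rnorm(n, config$length_distribution[["mean"]],
                config$length_distribution[["sd"]]) / 3) * 3L,
    config$cds_min
  )
  cds_len[classes == "reporter"] <- 900L
  cds_len[classes == "ptc"] <- 600L
  cds_len[classes == "endo"] <- 450L

  utr5 <- sample(20:40, n, replace = TRUE)
  utr3 <- sample(40:80, n, replace = TRUE)

  rows <- purrr::pmap(
    list(cls = classes, L = as.integer(cds_len), u5 = utr5, u3 = utr3,
         idx = seq_len(n)),
    function(cls, L, u5, u3, idx) {
      cds_start <- u5
      stop_start <- cds_start + L
      if (cls == "reporter") {
        # reading frame runs to the poly(A) site: no stop codon at all
        body <- .random_cds_body(L / 3L)
        sequence <- paste0(.random_nt(u5), body)
        polya <- nchar(sequence)
        stop_start <- polya - 3L   # last (sense) codon; keeps invariants
        stalls <- .stall_tbl(polya - 1L, "THREE_PRIME_END")
      } else {
        body <- .random_cds_body(L / 3L)
        stop_codon <- sample(STOP_CODONS, 1L)
        if (cls == "ptc") {
          # premature in-frame stop at codon 100 of the annotated ORF
          ptc_codon <- 100L
          substr(body, 3L * ptc_codon + 1L, 3L * ptc_codon + 3L) <-
            sample(STOP_CODONS, 1L)
        }
        sequence <- paste0(.random_nt(u5), body, stop_codon, .random_nt(u3))
        polya <- nchar(sequence)
        stalls <- .stall_tbl()
        if (cls == "ptc") {
          stalls <- bind_rows(stalls,
                              .stall_tbl(cds_start + 300L, "STOP_CODON"))
        }
        if (cls == "endo") {
          stalls <- bind_rows(
            stalls,
            .stall_tbl(cds_start + as.integer(L / 2), "INTERNAL_ENDO")
          )
        }
        if (cls == "target" || config$background_stop_stall) {
          stalls <- bind_rows(stalls, .stall_tbl(stop_start, "STOP_CODON"))
        }
      }
      tibble(
        gene_id = sprintf("%s_%04d", cls, idx),
        sequence = sequence,
        cds_start = as.integer(cds_start),
        stop_start = as.integer(stop_start),
        polya_site = as.integer(polya),
        gene_class = cls,
        is_planted_target = cls == "target",
        stall_sites = list(stalls)
      )
    }
  )
  tx <- bind_rows(rows)

  expr <- exp(rnorm(n, 0, 1))
  expr[tx$gene_class == "reporter"] <- 0
  expr <- expr / sum(expr) *
    (1 - config$reporter_expression * any(tx$gene_class == "reporter"))
  expr[tx$gene_class == "reporter"] <- config$reporter_expression
  tx$expression_level <- expr

  tx[, c("gene_id", "sequence", "cds_start", "stop_start", "polya_site",
         "gene_class", "is_planted_target", "expression_level",
         "stall_sites")]
}

#' Write / read a transcriptome as FASTA + GFF3
#'
#' Sequences go to FASTA; gene/mRNA/CDS features go to GFF3 (1-based,
#' inclusive, per the standard) with the simulator's extra annotations
#' (poly(A) site, stall sites, expression share, gene class) carried as
#' attributes of the mRNA feature so a round trip preserves the model.
#'
#' @param transcriptome tibble from [generate_transcriptome()].
#' @param fasta,gff3 output (or input) file paths.
#' @return `write_transcriptome()` returns the paths invisibly;
#'   `read_transcriptome()` returns the transcriptome tibble.
#' @export
write_transcriptome <- function(transcriptome, fasta, gff3) {
  seqs <- Biostrings::DNAStringSet(
    setNames(transcriptome$sequence, transcriptome$gene_id)
  )
  Biostrings::writeXStringSet(seqs, fasta)

  stall_attr <- purrr::map_chr(transcriptome$stall_sites, function(s) {
    if (nrow(s) == 0) return(".")
    paste(sprintf("%d:%s", s$position, s$class), collapse = "|")
  })
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(transcriptome))) {
    r <- transcriptome[i, ]
    len <- nchar(r$sequence)
    lines <- c(
      lines,
      sprintf("%s\triboshort\tgene\t1\t%d\t.\t+\t.\tID=gene:%s",
              r$gene_id, len, r$gene_id),
      sprintf(paste0(
        "%s\triboshort\tmRNA\t1\t%d\t.\t+\t.\tID=mrna:%s;Parent=gene:%s;",
        "polya_site=%d;stall_sites=%s;expression_level=%.8g;gene_class=%s;",
        "is_planted_target=%s"
      ), r$gene_id, len, r$gene_id, r$gene_id, r$polya_site, stall_attr[i],
         r$expression_level, r$gene_class, tolower(r$is_planted_target)),
      sprintf("%s\triboshort\tCDS\t%d\t%d\t.\t+\t0\tID=cds:%s;Parent=mrna:%s",
              r$gene_id, r$cds_start + 1L, r$stop_start + 3L, r$gene_id,
              r$gene_id)
    )
  }
  writeLines(lines, gff3)
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' @rdname write_transcriptome
#' @export
read_transcriptome <- function(fasta, gff3) {
  rlang::check_installed(c("rtracklayer", "GenomicRanges"))
  seqs <- Biostrings::readDNAStringSet(fasta)
  gff <- rtracklayer::import(gff3)
  mrna <- gff[gff$type == "mRNA"]
  cds <- gff[gff$type == "CDS"]
  seqid <- as.character(GenomicRanges::seqnames(mrna))
  cds_by <- setNames(
    as.integer(GenomicRanges::start(cds)) - 1L,
    as.character(GenomicRanges::seqnames(cds))
  )
  cds_end_by <- setNames(
    as.integer(GenomicRanges::end(cds)),
    as.character(GenomicRanges::seqnames(cds))
  )
  stalls <- purrr::map(as.character(mrna$stall_sites), function(x) {
    if (is.na(x) || x == ".") return(.stall_tbl())
    parts <- strsplit(strsplit(x, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    .stall_tbl(as.integer(purrr::map_chr(parts, 1)),
               purrr::map_chr(parts, 2))
  })
  tibble(
    gene_id = seqid,
    sequence = unname(as.character(seqs[seqid])),
    cds_start = unname(cds_by[seqid]),
    stop_start = unname(cds_end_by[seqid]) - 3L,
    polya_site = as.integer(mrna$polya_site),
    gene_class = as.character(mrna$gene_class),
    is_planted_target = as.character(mrna$is_planted_target) == "true",
    expression_level = as.numeric(mrna$expression_level),
    stall_sites = stalls
  )
}
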