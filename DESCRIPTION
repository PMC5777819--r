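Package: riboshort
Title: Short Ribosome Footprint Analysis for Translational Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects decay intermediates of translational surveillance
    (nonstop and no-go mRNA decay) from ribosome profiling data. Ribosomes
    awaiting rescue protect short (15-18 nt) mRNA fragments whose 3' ends mark
    cleavage or truncation points; the package partitions footprints into size
    classes after UMI deduplication, builds coordinate-restricted count
    matrices and coverage tracks, computes equal-weight metagene and per-codon
    3'-end termination profiles, measures footprint phasing by Pearson
    autocorrelation, and calls SKI/PELO-dependent target genes with a
    negative-binomial Wald interaction test at a Bonferroni cutoff. A
    mechanistic simulator of the recursive nonstop-decay model generates
    footprint, RNA-seq and bulk-segregant-pool data with the statistical
    structure the analysis assumes, and a sliding-window allele-frequency
    module maps suppressor loci from pooled variant counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    GenomicRanges,
    rtracklayer,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
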