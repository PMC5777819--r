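---
title: "Detecting translational-surveillance decay intermediates from short ribosome footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting translational-surveillance decay intermediates from short ribosome footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboshort)
library(dplyr)
```

## The biology and the measurement

When a ribosome runs out of mRNA — because the transcript has no stop codon,
because an endonuclease cut the message under its feet, or because the stop
codon itself has been truncated — it stalls with an empty or partial A site.
Such ribosomes are removed by the pelota/HBS-1 rescue machinery while the
SKI complex feeds the exposed mRNA 3' end into the 3'→5' exosome. A ribosome
in this state protects only ~15–18 nt of mRNA from nuclease digestion,
roughly half the ~28–30 nt footprint of an elongating ribosome, and its
footprint's **3' end marks the cleavage or truncation point**. Sequencing
the short footprint class in rescue/decay mutants therefore turns decay
intermediates into a positional signal:

* on a **nonstop transcript**, short footprints pile up at the poly(A)
  junction, with further peaks spaced one ribosome width (~28 nt) upstream —
  the recursive signature of trailing ribosomes running into the new 3' end
  created by cleavage at the leading ribosome's 5' edge;
* at **stop codons** in pelota-deficient animals, short footprints
  accumulate with 5' ends 14 nt upstream of the stop (stop codon in the A
  site) and 3' ends after the stop codon's second base (UGA) or second/third
  base (UAA/UAG) — a truncated stop codon that release factor eRF1 cannot
  use;
* at **internal endonuclease sites** (such as the tRNA-endonuclease cut
  sites of the `xbp-1`-type unfolded-protein-response mRNA), the same short
  class appears independently of the nonsense-mediated-decay (NMD/smg)
  pathway.

The package implements the full quantitative pipeline over such data — UMI
deduplication, size classing, coordinate-restricted counting, equal-weight
metagene and per-codon termination profiles, autocorrelation phasing, a
negative-binomial interaction test that calls SKI/PELO target genes, and
sliding-window bulk-segregant mapping — together with a mechanistic
simulator that generates footprint, RNA-seq and mapping-pool data with the
statistical structure those analyses assume.

## Coordinate conventions

All analyses run in transcript space, 0-based. The counting window for a
transcript is `[cds_start − 12, stop_start − 14]`, both ends inclusive: a
read whose 5' end is 12 nt upstream of the start codon holds the start codon
in the P site, and one 14 nt upstream of the stop holds the stop codon in
the A site, so the window spans exactly the positions of translating
ribosomes. The inclusive reading of both bounds is a deliberate choice (the
phrase "between" leaves the boundary open); both boundary behaviours are
exercised in the tests, and the inclusive version is the default
everywhere. The 3' end of a read is reported inclusively
(`five_prime + length − 1`); BED files on disk use the half-open convention
and the conversion lives in one reader/writer pair.

## The generative model

`generate_transcriptome()` builds single-isoform, plus-strand transcripts:
a 5' UTR, an ATG-initiated CDS assembled from sense codons only (so no
in-frame premature stop can occur by construction), a stop codon and a 3'
UTR. Special transcripts are planted on request: a nonstop reporter whose
reading frame runs into the poly(A) site (3'-end stall, high expression
share 0.002, mRNA de-repressed 7.12× / 3.81× / 19.4× in the ski-helicase,
pelota and double mutants), a premature-stop-codon (PTC) allele with an
internal in-frame stop at codon 100, an internal-endonuclease gene, and any
number of SKI/PELO target genes.

`simulate_footprints()` draws, per gene and library,
`Poisson(depth × expression × mRNA multiplier × noise)` unique molecules
and assigns each to one of three categories:

* **elongating** (length 28–30, 5' uniform over the counting window);
* **background short** (length 15–18, 5' uniform over the window, share
  `short_fraction_background`, default 0.1);
* **stall-derived short** (length 15–18, 3' end at a truncation point
  `t − k·Δ` for phased peaks `k = 0..5`, spacing Δ = 28 nt, geometric
  weight `ρ^k` with ρ = 0.4).

Stall intensity is calibrated against the background: peak `k` receives a
total expected weight of `4 (boost − 1) ρ^k` times the per-position
background short density. Because stall lengths are uniform on {15,…,18},
exactly one quarter of a peak's 5' mass lands on any single supported
position for every stop-codon type, so the expected 5'-end count at the
canonical −14 offset is `boost ×` background and the metagene enrichment
statistic recovers `boost` in expectation — a wild-type boost of 1 adds
nothing. Genotype defaults are 2.5 (pelota mutant) and 5.0 (double mutant)
for all stall classes; planted targets multiply the stop-codon *excess*
`(boost − 1)` by `target_boost = 16`, which makes them indistinguishable
from background genes wherever rescue is functional and gives
`1 + 16×(5−1) = 65`-fold stop enrichment in the double mutant — comfortably
beyond the ≥13-fold scale reported for endogenous targets, which is the
bound the recovery experiment checks. In an `smg-1` background the
stop-codon stall excess is scaled by `smg_residual` (default 0.1, a free
parameter: the data constrain only that "a minority" of the signal
remains), while internal-endonuclease stalls are untouched; with
`smg_residual = 1` the two smg backgrounds are byte-identical under a
shared seed.

Truncation points honour the codon chemistry: UGA stops always truncate
after the second base; UAA/UAG truncate after the second or third base with
equal probability; a full stop codon with an attached downstream nucleotide
is never emitted.

Every molecule carries a random 6-nt UMI and a geometric PCR duplicate
count (default parameter 0.03, keeping duplicates to a few percent of
reads, matching the duplication level the UMI protocol is designed to
absorb).

### Replicate noise

Two gamma-noise scales are deliberately distinct. Footprint libraries get
`replicate_dispersion = 0.01` (10% CV), drawn **independently for the short
and long size classes** — they are physically separate gel slices with
their own ligation and amplification, and this independence is what makes
the caller's dispersion floor meaningful (a noise term shared between the
classes would cancel in the interaction contrast). RNA-seq libraries get
`rna_replicate_dispersion = 6e-4` (2.4% CV): mRNA abundance between
biological replicates is far more reproducible, as the reporter's
replicate fold SDs (a few percent of the fold) indicate.

### Simulation scale

Defaults are a scaled-down transcriptome: CDS lengths are normal with mean
135 nt, sd 15 nt, floored at 105 nt. Compact transcripts keep molecule-level
simulations fast and concentrate the stop-codon stall signal relative to
the uniform background so that the planted-target recovery experiments
reach the power the calibration prescribes with two replicates. The
per-position calibration above is length-invariant, so metagene and
metacodon statistics are unaffected by this choice; only per-gene count
contrasts scale with it, and the methods themselves take any annotation.

`simulate_footprint_counts()` is an exact count-level marginalisation of
the molecule-level model (the marginal of a Poisson-total multinomial is
Poisson): it draws window counts per gene and size class directly and is
used for large count-matrix experiments. A distributional-agreement test
pins the two paths to the same expectations.

### What the simulator does not model

Sequence errors, alignment ambiguity, spliced genome coordinates,
multi-isoform genes, codon-specific dwell times, ribosome queueing beyond
the geometric peak train, and 5'-end heterogeneity of real RNase digestion.
Passing recovery tests therefore demonstrates that the pipeline measures
what the model plants — not that real libraries are this clean; on real
data the size-selection boundaries, unique-mapping filters and isoform
rules upstream of this package do substantial work.

## The analysis statistics

**Metagene.** Each transcript's per-offset 5'-end counts over the window
(default offsets −120..+12 around the stop) are divided by that
transcript's mean per-base count over the same window, then averaged with
equal weight per transcript, so depth and length drop out; transcripts
enter only if the window fits inside their covered region and their window
total reaches `min_reads` (default 10; the source analyses state no
threshold, so it is configurable). Enrichment is the profile value at
offset −14 over the median profile value at offsets below −40. The wide
window matters: the phased stall peaks sit near −42 and −70, and a narrow
background band lets them drag the median up by ~10%; with 80 background
offsets the median is robust to the ~15 contaminated positions.

**Metacodon termination.** For every in-frame instance of a codon
(including annotated stop codons), short-read 3' ends are tallied at
offsets −9..+5 from the codon's first base, pooled across instances
*before* normalization (robust to zero-coverage instances; a per-instance
averaging mode would weight sparse instances equally), and divided by the
tally over offsets −9..+2 — the codon plus its three upstream codons,
excluding the downstream codon because almost nothing terminates past a
stop. The frequencies over the 12 denominator offsets sum to exactly 1.

**Phasing.** The 5'-end count vector over the 300 nt upstream of the
poly(A) site is correlated with itself at lags 0..100 (overlap truncation,
no circular wrap or padding — the minimal reading of "shift and
correlate"); lags where either segment is constant are undefined. The
dominant period is the lag of the maximum coefficient within lags 10–100
(the lower bound excludes trivial short-range correlation; peak-picking is
this package's explicit operationalisation of reading a periodicity off
the curve), ties broken toward the smaller lag.

**Target calling.** Only wild-type and double-mutant libraries enter (the
single mutants are ignored by design); per gene a log-linear NB model with
log-library-total offsets and terms
`intercept + genotype + size_class + genotype:size_class` is fitted to the
8 libraries, and the one-sided Wald p-value for a positive interaction —
short-footprint enrichment beyond any mRNA-level change — is compared to
the Bonferroni cutoff `alpha / n_genes` (0.05 / 18,302 annotated genes
reproduces the 2.7319e-6 genome-wide cutoff). Dispersion is estimated per
gene by method of moments across within-condition replicates on the
count/total rate scale, then moderated toward the cross-gene median with
prior df 40 before applying the 0.01 floor. The moderation is essential,
not cosmetic: a per-gene estimate from two replicates carries ~4 residual
df, and its chi-square noise alone caps per-gene power at the Bonferroni
cutoff around 96% no matter how deep the libraries are, while also making
tail p-values conservative; sharing information across genes (as every
dispersion-trend method in this field does) restores both the calibration
(null type-I ≈ 0.045–0.052 at nominal 0.05 in the packaged experiments)
and power ≈ 1 for strong planted effects. Fold changes for reporting are
plain normalized replicate ratios with a Haldane pseudocount of 0.5 on
zero counts, summarised as mean ± SD across replicates.

**smg dependence.** For a gene, the fraction of per-million-normalized
short reads coming from the `smg-1` library,
`cpm₋ / (cpm₊ + cpm₋)`; values at or below 0.05 (>95% of reads from the
NMD-proficient strain) flag strongly smg-dependent genes. For stop-codon
targets this statistic is computed on **stop-proximal** counts (5' ends in
`[stop − 20, stop]`, the `region = "stop"` option of
`count_gene_occupancy()`): the quantity of interest is the stop-codon
stall peak, and whole-CDS totals would dilute it with uniform background
short footprints that are smg-independent by construction. Internal-
endonuclease genes sit near 0.5 under either counting, as expected for an
NMD-independent stall class.

**BSA mapping.** Pooled allele fractions are averaged over a moving window
of 100 variants (step 1; the window is what suppresses single-variant
sampling noise at realistic pool depths), and linked regions are maximal
runs of windows at or below a Hawaiian-fraction threshold of 0.1 — the
phenotype selection keeps suppressor-strain homozygotes, so linkage shows
as depletion of the mapping strain's alleles. The threshold is this
package's default; no numeric value is inherited. The simulated pool uses
marker spacing uniform on 700–1300 bp and an exponential recovery of the
expected Hawaiian fraction to 0.5 with characteristic distance
`distance_scale` (default 2 Mb, a plausible within-chromosome recombination
scale for a selfing cross pool).

## Numerical and degenerate-input choices

Zero-coverage variants are excluded from window means; a window with no
informative variant is `NA`. A zero metagene background, a zero
region-ratio denominator, and an all-zero metacodon denominator are
reported as `NA` with a warning rather than silently propagated. All-zero
genes get `p = 1` and are never called. Library totals must be positive;
coverage tracks refuse `library_total ≤ 0`. The counting window is clipped
at transcript position 0 with a warning, and a CDS too small to contain a
window is flagged empty. Every simulator consumes a single integer seed
and is byte-deterministic given (config, seed).

## Experiment sizes used by the packaged checks

The recovery experiments shipped in the test suite and the acceptance
script use: 200 genes × 5e5 fragments × 2 replicates for the reporter RNA
folds; 5,000 genes (723 targets) at 1e8 expected molecules per library for
caller power, and 2,000 null genes at 4e6 for calibration; 500 genes at 1e6
molecules for the metagene recoveries; a 60-gene transcriptome at 4e6
molecules for reporter phasing (the reporter is a highly expressed myosin;
its 300-nt window holds several thousand short reads); 5e4 RNA fragments
for the PTC bimodality. These sizes were chosen once, at design time, as
the smallest that leave the Monte-Carlo error of each statistic well inside
its stated recovery tolerance.

## Known limitations

The caller assumes a complete 2×2×replicates design and a shared library
layout across genes; unbalanced designs are rejected rather than patched.
The NB Wald test with 8 observations leans on the moderated dispersion —
with `dispersion_prior_df = 0` it reverts to the noisy per-gene estimator
and loses both calibration and power. Planted-target recovery experiments
use a clean null background (`background_stop_stall = FALSE`) so that
specificity is measurable; with the genome-wide stop-codon stall switched
on, every gene is a weak true positive in the double mutant and "false
positive" stops being a meaningful category. The smg-dependence band for
targets presumes the stop-proximal counting window; whole-CDS counting
answers a different (gene-level) question.
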