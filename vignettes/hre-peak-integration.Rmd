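---
title: "Summit-centred HRE analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summit-centred HRE analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrescope)
```

## The analysis in one paragraph

Hypoxia-inducible factor (HIF) binds DNA at the hypoxia response element
(HRE), whose core consensus is the 5-mer RCGTG (R = A or G). Because a 5-mer
this short occurs roughly once per 256 bp of random sequence on either
strand, the presence of the motif alone says little; the informative signal
in ChIP-seq data is its *concentration near peak summits* and its *decay
with peak significance rank*. hrescope packages that logic: it scans
summit-centred windows for RCGTG on both strands, profiles match offsets
around summits, classifies summits into six genomic-context categories
against the nearest transcription start site (TSS), associates peaks with
genes through a two-nearest-genes rule restricted to a ±1 kb TSS window,
intersects the associated genes with differential-expression (DE) gene sets
under an exact hypergeometric test, and quantifies ChIP enrichment from
qPCR cycle-threshold (Ct) tables with an efficiency-corrected (Pfaffl-type)
ratio. A seeded generator produces synthetic genomes, gene models, peaks,
expression tables and Ct tables with planted ground truth, so every stage
is testable end to end without any external download.

## Motif scanning

`scan_rcgtg()` reports every position whose forward 5-mer is ACGTG or GCGTG
(a "+" hit) or is CACGT/CACGC, i.e. reads as RCGTG on the reverse
complement (a "−" hit). Two consequences are intentional:

* the palindromic extension CACGTG produces **two hits at overlapping
  positions**, one per strand — it genuinely binds bidirectionally;
* `N` never matches, so masked or ambiguous sequence cannot create hits.

Exactly 4 of the 1024 possible 5-mers match on either strand, giving the
analytic background rate of 1 match per 256 bp on uniform sequence; the
test suite checks a 10 Mb simulation against this expectation.

`peak_has_hre()` reads "the 100 bp surrounding the summit" as the half-open
window `[summit − half_width, summit + half_width)` with the **whole 5-mer
required inside** (match start ≤ summit + half_width − 5). This is the
conservative reading; the alternative — only the match start inside — is
exposed as `full_motif = FALSE`, and the two differ for at most 4 border
positions per peak. Windows are clipped at chromosome ends rather than
erroring, because summits can legitimately sit near contig boundaries.

PWM/log-odds scanning is deliberately out of scope: score-thresholded
scanning of a 5 bp degenerate consensus discards experimentally confirmed
fish HREs while adding parameters; the plain consensus is the method.

## Region classification

Each summit is classified against the gene whose TSS is nearest (unsigned
distance; ties broken by lexicographic gene id for determinism), using a
per-gene, strand-aware template with half-open boundaries:

| label | extent (defaults) |
|---|---|
| TSS | ±1 kb around the TSS |
| Promoter | 5′ of the TSS region out to 5 kb upstream |
| Inside | gene body minus the TSS region |
| Proximal | 5 kb flanking the promoter/body envelope |
| Distal | 90 kb flanking the proximal regions |
| Desert | beyond (≥ 100 kb upstream of the TSS, ≥ 95 kb past the gene end) |

Half-open boundaries assigned toward the TSS-distal side prevent double
counting, so the six categories partition every base exactly —
`genome_region_fractions()` sums to 1 to 1e−9 and is tested for exact
equality against a per-base brute-force oracle. The nearest-TSS rule also
governs summits inside another gene's body: a summit in gene A's body but
within 1 kb of gene B's nearer TSS is labelled TSS via B, because "closest
gene" wins by construction. How overlapping or nested genes should be
handled is genuinely open in this class of annotation tools; nearest TSS
with a lexicographic tie-break is our documented choice, deterministic
across runs and platforms. Distance is unsigned for both strands — a signed
convention would make minus-strand deserts asymmetric for no analytic gain.

`genome_region_fractions()` gives the expected label distribution of peaks
placed uniformly at random; `label_distribution()` gives the observed one.
The test suite links the two: uniform random summits converge to the base
fractions within binomial error.

## Peak-to-gene association and the enrichment test

`associate_peaks()` keeps, per peak, the two genes nearest by TSS distance,
then retains those within ±1 kb of the summit. A peak can therefore
contribute 0, 1 or 2 association rows; signed distances are reported in
gene orientation (downstream positive). The deliberately tight window
trades sensitivity for specificity: with thousands of peaks, distance-based
assignment beyond the TSS neighbourhood is unreliable, so enrichment claims
are restricted to promoter-proximal binding.

`intersect_de_with_associations()` then builds the population construction
for the exact test: population = platform symbols; successes in the
population = peak-associated genes restricted to the platform; sample = the
up- (or down-) regulated set; successes = the intersection.
`hypergeom_tail()` is the inclusive upper tail P(X ≥ k), computed in log
space (`phyper`), which matches enrichment-test convention. Note that
`filter_de()` filters on **raw** p ≤ 0.01 and linear fold change ≥ 2 (both
boundaries inclusive), with no multiple-testing correction — the sets it
produces are descriptive short-lists on the platform's own scale, not
FDR-controlled discoveries, and downstream p-values must be read
accordingly. Probes collapse to symbols by "any passing probe counts";
symbols with passing probes in both directions are dropped with a warning,
since a single direction cannot be assigned.

The χ² comparison (`chi2_2x2()`) defaults to no continuity correction, with
Yates available by flag; both variants are exercised in the acceptance
tests. `peak_overlap()` computes, per query peak, the fraction of its bases
covered by the union of subject peaks (union semantics keep the fraction
≤ 1), passing on a strict `> min_frac`. Because "overlap" in the literature
may mean ≥ 1 bp or a fraction criterion, both counts are returned: the
fraction table and the any-overlap count as an attribute.

## qPCR quantification

`fit_efficiency()` regresses mean Ct on log10 input amount;
E = 10^(−1/slope), so perfect doubling chemistry gives slope ≈ −3.32 and
E = 2. Zero-concentration wells are excluded, at least three distinct
positive concentrations are required, and a non-negative slope warns rather
than errors. The fit is scale-equivariant: multiplying all concentrations
by a constant changes the intercept only.

Two Pfaffl-type ratios are provided with fixed, documented sign
conventions, both anchored by the invariant *ratio > 1 exactly when the
target amplifies earlier than the reference does*:

* `expression_fc()`: ΔCt = Ct(control) − Ct(case) per assay,
  FC = E_tar^ΔCt_tar / E_ref^ΔCt_ref;
* `chip_enrichment_fc()`: ΔCt = Ct(input) − Ct(ChIP) per region,
  FC = E_tar^ΔCt_tar / E_ref^ΔCt_ref.

At E = 2 the ChIP ratio reduces to 2^(ΔCt_tar − ΔCt_ref), the familiar
ΔΔCt — asserted to 1e−12 in the tests. Replicates are averaged before the
ratio (per-replicate error propagation is out of scope), and zero or
non-finite Cts are treated as missing wells, never as Ct = 0.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions; all stages derive their random
streams from one seed (each stage at a fixed offset, so stages are
reproducible standalone and inside `run_all()`), and identical
configurations are bit-identical, file outputs included.

* **Genome**: i.i.d. bases at GC 0.37 (fish-like). Default 6 Mb over 3
  chromosomes — large enough that background motif statistics are stable,
  small enough that a full run takes seconds.
* **Genes**: 500 non-overlapping models, log-uniform lengths 1–15 kb,
  strands 50/50. Placement distributes free space as normalised exponential
  gaps between genes laid end to end — this guarantees non-overlap at any
  feasible density in one pass, where rejection sampling would stall at
  high occupancy.
* **Peaks**: 400 peaks, log-uniform widths 200–1500 bp (matching the
  several-hundred-bp scale of real peak calls), 30 % targeted into TSS
  windows. Scores decrease strictly with rank. Each peak carries a planted
  RCGTG with its rank bin's probability (defaults 0.95/0.85/0.70/0.55,
  reproducing a rank-decaying HRE fraction with an overall rate near 0.75),
  written **into the genome sequence** at summit + Laplace(0, b = 30 bp),
  so the scanner is tested through real sequence rather than bookkeeping.
  b = 30 puts the bulk of planted motifs within ±100 bp of the summit, the
  concentration scale characteristic of directly bound ChIP peaks. Planted
  motifs never overwrite one another (collisions are resampled); the truth
  table distinguishes planted from background matches, and recovery tests
  use planted-only assertions plus a measured background rate.
* **Expression**: genes with a realised TSS peak are up-regulated at odds
  `peak_de_odds` (default 4) times the baseline, with the baseline solved
  numerically so the overall up fraction hits `de_fraction_up` (0.10;
  down 0.15). DE genes draw fold changes beyond the 2-fold boundary and
  p < 0.01; null genes stay inside the boundary with uniform p. About 10 %
  of genes get a second concordant probe to exercise the probe-collapse
  rule.
* **qPCR**: Ct = baseline − log_E(template) + N(0, 0.1 cycles), with ChIP
  template multiplied by 22 for enriched regions (the magnitude of a strong
  promoter-HRE pull-down) under a global 2 % recovery factor that cancels
  in the ratio; assay efficiency 1.95.

Not emulated: read-level data (FASTQ, coverage, fragment-size effects),
peak-caller behaviour (peaks are simulated post-calling, the pipeline's
entry point), chromatin context, gene families and duplicated loci,
platform-specific probe effects, and any correlation structure between
neighbouring genes. Passing the recovery tests therefore demonstrates that
the pipeline inverts its own generative model faithfully — not that the
model captures every property of real ChIP-seq data.

## Numerical and calibration notes

* Rank-bin HRE recovery is compared against the model-implied detection
  probability, not the raw planted probability: a planted motif is detected
  only if its Laplace offset keeps the whole 5-mer inside the ±50 bp window
  (probability `1 − ½e^(−50/b) − ½e^(−45/b)`), and background matches add
  detections on top (rate measured empirically on the motif-free genome).
  Ignoring either correction would mis-state the expected fraction by tens
  of percentage points at b = 30.
* The Laplace scale is recovered by its maximum-likelihood estimator, the
  mean absolute offset.
* Statistical recovery tests use 3-standard-deviation bands derived from
  the binomial/log-odds standard errors at the configured sample sizes
  (problem sizes used: 10 Mb for the background rate; 2–4 Mb genomes with
  450–800 genes/peaks for recovery; 60 seeded runs for null calibration).
* Score ties in significance ranking break by ascending chromosome and
  start, so binned fractions are invariant to input row order.
* Empty gene sets classify everything as Desert with a warning rather than
  erroring, so gene-free scaffolds flow through.
* Chromosome names are matched exactly between files; a mismatch is a hard
  error listing the offenders, because silent "chr" aliasing is a classic
  source of empty results.
* The peak-file dialect is narrowPeak (BED6+4, summit offset in column 10,
  −1 = absent, replaced by the interval midpoint); summits are stored as
  absolute positions so no downstream code repeats offset arithmetic.

## Worked example

```{r example, eval = FALSE}
report <- run_all(sim_config(seed = 42))
print(report)
```

The report's invariants — HRE + non-HRE counts summing to the peak total,
label fractions summing to 1, association counts bounded by peak counts —
are asserted by the test suite on every run.

## Known limitations

* Gene-level TSSs only; transcript-level TSS sets and alternative promoters
  are not represented.
* The association rule is distance-based; enhancers acting through
  chromatin contacts are invisible to it by design.
* The hypergeometric construction treats gene symbols as exchangeable;
  platform redundancy beyond the simulated two-probe case is not modelled.
* `genome_region_fractions()` is exact but linear in genome size; for
  genomes far beyond 1 Gb a closed-form interval-arithmetic variant would
  be preferable.
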