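# hrescope

Summit-centred hypoxia response element (HRE) analysis for ChIP-seq peak
sets, and their integration with expression data and qPCR validation.

## What problem this solves

Hypoxia-inducible factor (HIF) binds the short consensus RCGTG (R = A or
G). On random sequence that 5-mer occurs about once every 256 bp on either
strand, so merely finding it proves nothing. What distinguishes genuine
HIF binding in ChIP-seq data is structure around the evidence:

* RCGTG concentrates **near peak summits** rather than uniformly across
  peaks;
* the fraction of peaks containing it **decays with significance rank**;
* peaks sit preferentially near **transcription start sites** (TSS);
* genes with summit-proximal peaks are **enriched among up-regulated
  genes**;
* candidate regions validate by **ChIP-qPCR fold enrichment** over input.

hrescope implements that chain of evidence as a reusable, tested R
pipeline for anyone annotating transcription-factor peak sets against a
short consensus — with a seeded synthetic-data generator so the whole
pipeline is verifiable end to end without downloading anything.

## The statistics at its core

**Motif scanning.** A position is a hit when its 5-mer is ACGTG/GCGTG
(forward) or CACGT/CACGC (reverse-complement read). `peak_has_hre()` tests
the window `[summit − w, summit + w)` (default w = 50 bp, whole 5-mer
inside); `summit_distribution()` histograms match offsets in ±500 bp;
`binned_hre_fraction()` reports the HRE fraction per significance-rank bin.

**Region classification.** Summits are labelled against the nearest-TSS
gene using a strand-aware template — TSS (±1 kb), Promoter (to −5 kb),
Inside (gene body), Proximal (+5 kb), Distal (+90 kb), Desert — and
`genome_region_fractions()` gives the exact base-level null distribution
of those labels.

**Enrichment.** For a platform of N genes of which K are peak-associated,
an n-gene DE set sharing k genes is scored by the exact hypergeometric
upper tail

P(X ≥ k) = Σ_{j≥k} C(K, j) C(N−K, n−j) / C(N, n),

plus Pearson χ² for 2×2 comparisons and Spearman's ρ for fold-change
concordance. `peak_overlap()` computes per-peak covered fractions with
union semantics and a strict > 50 % pass rule.

**qPCR.** Amplification efficiency E = 10^(−1/slope) from a dilution
series; efficiency-corrected (Pfaffl-type) ratios for expression
(ΔCt = Ct_control − Ct_case) and ChIP enrichment
(ΔCt = Ct_input − Ct_ChIP):

FC = E_tar^ΔCt_tar / E_ref^ΔCt_ref.

## Worked example

```r
library(hrescope)
report <- run_all(sim_config(seed = 42))
print(report)
```

```
HRE pipeline report
  peaks: 400 (282 with HRE near summit, 70.5%)
  HRE fraction by significance bin: 0.82 0.77 0.72 0.51 
  summit regions: TSS 42.2%, Promoter 10.2%, Inside 23.0%, Proximal 18.5%, Distal 6.0%, Desert 0.0% 
  TSS associations: 179 (from 169 peaks, 161 genes)
  DE: 51 up / 75 down of 500 platform genes
  up-genes with TSS peak: 28 (hypergeometric p = 0.00034, OR 2.89)
  down-genes with TSS peak: 24 (p = 0.565)
  comparison peaks overlapping: 20 of 100 (19 pass >50%)
  qPCR efficiency: 1.919; median ChIP enrichment: 20.8-fold
```

Reading it: the generator planted motifs at rates decaying with rank
(0.95/0.85/0.70/0.55) — the recovered bin fractions (0.82…0.51) show the
decay through real sequence scanning; up-regulated genes were planted with
4× odds of carrying a TSS peak — the intersection test recovers a
significant enrichment (p = 3.4×10⁻⁴) while down-regulated genes show none
(p = 0.57); the qPCR stage recovers the planted assay efficiency (1.95)
and ~22-fold ChIP enrichment from noisy Ct tables.

Individual stages are exported (`scan_rcgtg`, `peak_has_hre`,
`classify_summits`, `associate_peaks`, `filter_de`, `hypergeom_tail`,
`peak_overlap`, `fit_efficiency`, `chip_enrichment_fc`, …) and read/write
the standard formats (FASTA, narrowPeak, BED6, headered TSV). A thin
command-line front end with one subcommand per stage is installed at
`system.file("scripts", "hrescope", package = "hrescope")`.

## Method details

See the methods vignette, `vignettes/hre-peak-integration.Rmd`, for the
models, parameter defaults and units, the generator's scope and
limitations, and the reasoning behind the open design choices.
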