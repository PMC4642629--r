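Package: hrescope
Title: Summit-Centred Hypoxia Response Element Analysis for ChIP-seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integration analysis for transcription-factor ChIP-seq peak sets
    and expression data, built around the hypoxia response element (HRE, the
    RCGTG consensus bound by the HIF dimer). Provides summit-centred RCGTG
    consensus scanning on both strands, significance-rank-binned HRE fractions,
    summit-relative motif distributions, classification of peak summits into
    six genomic-context categories (TSS, promoter, gene body, proximal, distal,
    desert) with genome-wide base fractions, nearest-TSS peak-to-gene
    association, differential-expression intersection with exact hypergeometric
    and chi-squared enrichment tests, interval-overlap fractions between peak
    sets, and efficiency-corrected (Pfaffl-type) qPCR quantification for both
    expression validation and ChIP enrichment. A seeded synthetic-data
    generator produces genomes with planted motifs, gene models, peak sets,
    expression tables and Ct tables so every stage is testable end-to-end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
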