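# Independent reference implementations used only to check the package:
# deliberately naive (loops, enumeration, per-base sets), sharing no code
# with the implementation under test.

# All RCGTG hits in a sequence via substring enumeration.
oracle_scan <- function(seq) {
  fwd <- c("ACGTG", "GCGTG")
  rev <- c("CACGT", "CACGC")
  n <- nchar(seq)
  pos <- integer(0)
  strand <- character(0)
  if (n >= 5) {
    for (i in 1:(n - 4)) {
      mer <- substr(seq, i, i + 4)
      if (mer %in% fwd) { pos <- c(pos, i - 1L); strand <- c(strand, "+") }
      if (mer %in% rev) { pos <- c(pos, i - 1L); strand <- c(strand, "-") }
    }
  }
  ord <- order(pos, strand)
  data.frame(position = pos[ord], strand = strand[ord],
             stringsAsFactors = FALSE)
}

# Scalar six-category classification of one position against a gene table,
# re-deriving the per-gene template from the definitions.
oracle_classify <- function(pos, chrom, genes, bounds = region_bounds()) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return("Desert")
  d <- abs(g$tss - pos)
  cand <- which(d == min(d))
  i <- cand[order(g$gene_id[cand])][1]
  tss <- g$tss[i]
  if (pos >= tss - bounds$tss && pos < tss + bounds$tss) return("TSS")
  if (g$strand[i] == "+") {
    prom <- c(tss - bounds$promoter, tss - bounds$tss)
    env <- c(tss - bounds$promoter, max(g$end[i], tss + bounds$tss))
  } else {
    prom <- c(tss + bounds$tss, tss + bounds$promoter)
    env <- c(min(g$start[i], tss - bounds$tss), tss + bounds$promoter)
  }
  if (pos >= prom[1] && pos < prom[2]) return("Promoter")
  if (pos >= g$start[i] && pos < g$end[i]) return("Inside")
  if ((pos >= env[1] - bounds$proximal && pos < env[1]) ||
      (pos >= env[2] && pos < env[2] + bounds$proximal)) return("Proximal")
  if ((pos >= env[1] - bounds$proximal - bounds$distal &&
       pos < env[1] - bounds$proximal) ||
      (pos >= env[2] + bounds$proximal &&
       pos < env[2] + bounds$proximal + bounds$distal)) return("Distal")
  "Desert"
}

# Exact hypergeometric upper tail by direct summation of binomial
# coefficients (no phyper).
oracle_hyper <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Covered fraction of one query interval by a subject set, per-base.
oracle_covered_fraction <- function(chrom, start, end, subjects) {
  pos <- start:(end - 1)
  covered <- rep(FALSE, length(pos))
  s <- subjects[subjects$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(s))) {
    covered <- covered | (pos >= s$start[i] & pos < s$end[i])
  }
  mean(covered)
}

# Random peak table on a given genome.
random_peaks <- function(n, genome, width = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- nchar(genome)
  chrom <- sample(names(genome), n, replace = TRUE)
  summit <- vapply(chrom, function(cc) {
    sample(seq.int(width, lens[[cc]] - width), 1)
  }, numeric(1))
  data.frame(chrom = chrom, start = as.integer(summit - width %/% 2),
             end = as.integer(summit + width %/% 2),
             name = sprintf("rp%03d", seq_len(n)),
             score = stats::runif(n, 51, 500),
             summit = as.integer(summit), stringsAsFactors = FALSE)
}

# Random i.i.d. genome as a named character vector.
random_genome <- function(lens, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  stats::setNames(seqs, paste0("chr", seq_along(lens)))
}

# Laplace CDF for offset-distribution checks.
plaplace <- function(q, b) {
  ifelse(q < 0, 0.5 * exp(q / b), 1 - 0.5 * exp(-q / b))
}

# Small gene table builder.
make_genes <- function(chrom, start, end, strand,
                       gene_id = sprintf("g%02d", seq_along(start))) {
  g <- data.frame(chrom = chrom, start = as.integer(start),
                  end = as.integer(end), gene_id = gene_id,
                  score = rep(0, length(start)),
                  strand = strand, stringsAsFactors = FALSE)
  g$tss <- gene_tss(g)
  g
}

# Small peak table builder (summit defaults to the midpoint).
make_peaks <- function(chrom, start, end,
                       summit = as.integer(floor((start + end) / 2)),
                       score = 100,
                       name = sprintf("pk%02d", seq_along(start))) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = name, score = score, summit = as.integer(summit),
             stringsAsFactors = FALSE)
}
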