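#' Filter a differential-expression table into up/down gene sets
#'
#' Applies the raw-p and linear fold-change cut-offs (both boundaries
#' inclusive: FC >= `fc_min` or FC <= 1/`fc_min`, p <= `p_max`) and collapses
#' probes to unique gene symbols. A symbol is up-regulated if any passing
#' probe is up; symbols whose passing probes disagree in direction are
#' excluded with a warning. No multiple-testing correction is applied: the
#' filter operates on raw p-values by design, so the sets are descriptive
#' short-lists, not FDR-controlled discoveries.
#'
#' @param records Expression data.frame (see [read_expression()]).
#' @param fc_min Linear fold-change cut-off (>= 1).
#' @param p_max Raw p-value cut-off.
#' @return A list with character vectors `up`, `down` and `universe` (all
#'   distinct symbols on the platform).
#' @export
filter_de <- function(records, fc_min = 2, p_max = 0.01) {
  stopifnot(fc_min >= 1, p_max >= 0, p_max <= 1)
  sym <- records$symbol
  keep <- !is.na(sym) & nzchar(sym)
  records <- records[keep, , drop = FALSE]
  pass <- records$p_value <= p_max
  up <- unique(records$symbol[pass & records$fold_change >= fc_min])
  down <- unique(records$symbol[pass & records$fold_change <= 1 / fc_min])
  conflict <- intersect(up, down)
  if (length(conflict)) {
    warning(length(conflict),
            " symbol(s) with passing probes in both directions excluded: ",
            paste(utils::head(conflict, 5L), collapse = ", "))
    up <- setdiff(up, conflict)
    down <- setdiff(down, conflict)
  }
  list(up = up, down = down, universe = unique(records$symbol))
}

#' Exact hypergeometric upper tail P(X >= k)
#'
#' The enrichment statistic for gene-set intersections: the probability of
#' observing at least `k` successes when drawing `n` items without
#' replacement from a population of `N` containing `K` successes. The
#' inclusive upper tail is computed exactly (log-space stable) for
#' populations of 10^4--10^5 genes.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Sample size.
#' @param k Observed successes in the sample.
#' @return The tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  args <- c(N = N, K = K, n = n, k = k)
  if (any(args != round(args)) || any(args < 0)) {
    stop("N, K, n, k must be non-negative integers")
  }
  if (k > n || n > N || K > N) {
    stop("require k <= n <= N and K <= N, got N=", N, " K=", K,
         " n=", n, " k=", k)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pearson chi-squared test on a 2x2 proportion comparison
#'
#' @param successes_a,total_a Successes and total in group A.
#' @param successes_b,total_b Successes and total in group B.
#' @param yates Apply the Yates continuity correction.
#' @return A list with `statistic` and `p_value`.
#' @export
chi2_2x2 <- function(successes_a, total_a, successes_b, total_b,
                     yates = FALSE) {
  if (total_a <= 0 || total_b <= 0) stop("group totals must be positive")
  if (successes_a < 0 || successes_b < 0 ||
      successes_a > total_a || successes_b > total_b) {
    stop("successes must lie in [0, total]")
  }
  m <- matrix(c(successes_a, total_a - successes_a,
                successes_b, total_b - successes_b), nrow = 2)
  if (any(rowSums(m) == 0)) stop("zero marginal total in the 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Fraction of each query peak covered by a subject peak set
#'
#' Computes, per query interval, the fraction of its bases covered by the
#' union of subject intervals (union semantics: overlapping subject peaks
#' never push the fraction above 1). A query "passes" when its covered
#' fraction strictly exceeds `min_frac`. The count of queries with any
#' overlap at all (>= 1 bp) is attached as attribute `n_any_overlap`.
#'
#' @param query_peaks,subject_peaks Peak data.frames.
#' @param min_frac Strict lower bound on the covered fraction for `passes`.
#' @return A data.frame with columns `name`, `covered_fraction`, `passes`,
#'   in query input order, with attribute `n_any_overlap`.
#' @export
peak_overlap <- function(query_peaks, subject_peaks, min_frac = 0.5) {
  validate_peaks(query_peaks)
  validate_peaks(subject_peaks)
  q <- GenomicRanges::GRanges(query_peaks$chrom,
                              IRanges::IRanges(query_peaks$start + 1L,
                                               query_peaks$end))
  s <- GenomicRanges::reduce(
    GenomicRanges::GRanges(subject_peaks$chrom,
                           IRanges::IRanges(subject_peaks$start + 1L,
                                            subject_peaks$end)))
  # disjoint chromosome sets between query and subject are legitimate here
  ov <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  inter <- suppressWarnings(
    GenomicRanges::pintersect(q[S4Vectors::queryHits(ov)],
                              s[S4Vectors::subjectHits(ov)]))
  covered <- numeric(length(q))
  if (length(ov)) {
    w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(w))] <- as.numeric(w)
  }
  frac <- covered / (query_peaks$end - query_peaks$start)
  out <- data.frame(name = query_peaks$name, covered_fraction = frac,
                    passes = frac > min_frac, stringsAsFactors = FALSE)
  attr(out, "n_any_overlap") <- sum(frac > 0)
  out
}

#' Intersect DE gene sets with peak-associated genes
#'
#' Builds the population construction for the enrichment test: the
#' population is the set of platform symbols, the successes in the population
#' are the peak-associated genes restricted to the platform, the sample is
#' the up- (or down-) regulated set, and the observed successes are the
#' intersection. Returns the counts, the exact hypergeometric upper-tail
#' p-values, and the sample odds ratios.
#'
#' @param de_sets Output of [filter_de()].
#' @param associations Output of [associate_peaks()] (column `gene_id` is
#'   matched against platform symbols).
#' @param universe Platform gene symbols; defaults to `de_sets$universe`.
#' @return A list with elements `population`, `assoc_in_universe`, and for
#'   each direction `n`, `k`, `p` and `odds_ratio`.
#' @export
intersect_de_with_associations <- function(de_sets, associations,
                                           universe = de_sets$universe) {
  if (!length(universe)) stop("empty gene universe")
  universe <- unique(universe)
  assoc <- intersect(unique(associations$gene_id), universe)
  N <- length(universe)
  K <- length(assoc)
  one <- function(set) {
    set <- intersect(set, universe)
    n <- length(set)
    k <- length(intersect(set, assoc))
    p <- hypergeom_tail(N, K, n, k)
    # sample odds of carrying a peak for in-set vs out-of-set genes
    or <- (k * (N - n - K + k)) / ((n - k) * (K - k))
    list(n = n, k = k, p = p, odds_ratio = or)
  }
  list(population = N, assoc_in_universe = K,
       up = one(de_sets$up), down = one(de_sets$down))
}

#' Spearman rank correlation between two fold-change vectors
#'
#' Rank correlation with mid-ranks for ties; the concordance statistic used
#' to validate array fold changes against qPCR fold changes.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient rho.
#' @export
spearman_concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: rank correlation undefined")
  }
  stats::cor(x, y, method = "spearman")
}
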