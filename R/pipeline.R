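#' Run the full synthetic-data analysis pipeline
#'
#' Chains simulate -> motif scan -> region classification -> peak-to-gene
#' association -> differential-expression intersection -> peak-set overlap ->
#' qPCR quantification, and collects the headline numbers in a report. All
#' stage parameters default to the values the analysis is calibrated for: a
#' 100 bp summit window (`half_width = 50`), significance bins of 1000 peaks,
#' a +-1 kb TSS association window with the two nearest genes, region bounds
#' of 1/5/5/90 kb, a strict 50 % overlap threshold, and DE cut-offs of
#' fold change >= 2 at p <= 0.01.
#'
#' A second, smaller "comparison" peak set (emulating a low-signal condition)
#' is simulated alongside the main set to exercise the overlap stage.
#'
#' @param config A [sim_config()] describing the synthetic inputs.
#' @param outdir Optional directory; when given, all stage outputs are
#'   written as TSV with provenance headers plus a JSON report.
#' @param half_width Summit window half-width for HRE detection (bp).
#' @param bin_size Peaks per significance bin; defaults to a quarter of the
#'   peak set so the rank decay is visible at any scale.
#' @param bounds Region bounds, see [region_bounds()].
#' @param n_nearest,tss_window Association rule parameters.
#' @param fc_min,p_max DE filter cut-offs.
#' @param min_frac Strict overlap-fraction threshold.
#' @return A list of class `hre_report`; see Details.
#' @details The report contains: peak and HRE counts, per-bin HRE fractions,
#'   the summit-offset profile, region-label distribution, genome base
#'   fractions, association counts, DE set sizes, the hypergeometric
#'   intersection (counts, p-values, odds ratio), overlap counts against the
#'   comparison peak set, the fitted qPCR efficiency and the ChIP enrichment
#'   table.
#' @export
run_all <- function(config = sim_config(), outdir = NULL,
                    half_width = 50L, bin_size = NULL,
                    bounds = region_bounds(), n_nearest = 2L,
                    tss_window = 1000L, fc_min = 2, p_max = 0.01,
                    min_frac = 0.5) {
  if (!inherits(config, "sim_config")) {
    stop("config must be a sim_config object")
  }
  genome <- simulate_genome(config)
  genes <- simulate_genes(config, genome)
  sim <- simulate_peaks(config, genome, genes)
  genome <- sim$genome
  peaks <- sim$peaks
  expr <- simulate_expression(config, genes, peaks, tss_window = tss_window)
  wt_peaks <- simulate_comparison_peaks(config, genome, peaks)

  if (is.null(bin_size)) bin_size <- max(1L, ceiling(nrow(peaks) / 4))
  has_hre <- peak_has_hre(peaks, genome, half_width = half_width)
  bins <- binned_hre_fraction(peaks, genome, bin_size = bin_size,
                              half_width = half_width)
  profile <- summit_distribution(peaks, genome)

  labels <- label_distribution(peaks, genes, bounds)
  fractions <- genome_region_fractions(genes, chrom_sizes(genome), bounds)
  assoc <- associate_peaks(peaks, genes, n_nearest = n_nearest,
                           tss_window = tss_window)

  de <- filter_de(expr$records, fc_min = fc_min, p_max = p_max)
  enrich <- intersect_de_with_associations(de, assoc)

  overlap <- peak_overlap(wt_peaks, peaks, min_frac = min_frac)

  dil <- simulate_dilution(config)
  curve <- fit_efficiency(dil$concentration, dil$ct)
  ct_tab <- simulate_qpcr(config)
  chip_fc <- chip_enrichment_table(ct_tab, reference = "control01")

  report <- list(
    config = config,
    n_peaks = nrow(peaks),
    n_hre = sum(has_hre),
    n_non_hre = sum(!has_hre),
    hre_fraction = mean(has_hre),
    bin_summary = bins,
    summit_profile = profile,
    label_distribution = labels,
    genome_fractions = fractions,
    n_associations = nrow(assoc),
    n_assoc_peaks = length(unique(assoc$name)),
    n_assoc_genes = length(unique(assoc$gene_id)),
    de = list(n_up = length(de$up), n_down = length(de$down),
              universe = length(de$universe)),
    enrichment = enrich,
    overlap = list(n_query = nrow(overlap),
                   n_any = attr(overlap, "n_any_overlap"),
                   n_pass = sum(overlap$passes)),
    qpcr = list(efficiency = curve$efficiency, slope = curve$slope,
                enrichment = chip_fc)
  )
  class(report) <- "hre_report"

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    prm <- list(seed = config$seed, half_width = half_width,
                bin_size = bin_size, tss_window = tss_window,
                n_nearest = n_nearest, fc_min = fc_min, p_max = p_max,
                min_frac = min_frac)
    write_fasta(genome, file.path(outdir, "genome.fa"))
    utils::write.table(chrom_sizes(genome),
                       file.path(outdir, "chrom.sizes"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_genes(genes, file.path(outdir, "genes.bed"))
    write_peaks(peaks, file.path(outdir, "peaks.narrowPeak"))
    write_peaks(wt_peaks, file.path(outdir, "comparison.narrowPeak"))
    write_tsv(sim$truth, file.path(outdir, "truth.tsv"), prm)
    write_tsv(expr$records, file.path(outdir, "expression.tsv"), prm)
    write_tsv(ct_tab, file.path(outdir, "qpcr_ct.tsv"), prm)
    write_tsv(bins, file.path(outdir, "hre_bins.tsv"), prm)
    write_tsv(labels, file.path(outdir, "region_labels.tsv"), prm)
    write_tsv(assoc, file.path(outdir, "associations.tsv"), prm)
    write_tsv(chip_fc, file.path(outdir, "chip_enrichment.tsv"), prm)
    jsonlite::write_json(report_summary(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# The low-signal comparison peak set: ~25% the size of the main set, ~12% of
# it placed over main-set summits as short peaks, the rest uniform.
simulate_comparison_peaks <- function(config, genome, peaks) {
  stage_seed(config, 5L)
  n <- max(4L, round(config$n_peaks / 4))
  n_shared <- round(0.123 * n)
  chrom_len <- nchar(genome)
  widths <- pmax(40L, round(stats::rnorm(n, 114, 25)))
  shared <- sample(nrow(peaks), min(n_shared, nrow(peaks)))
  chrom <- c(peaks$chrom[shared],
             sample(names(genome), n - length(shared), replace = TRUE,
                    prob = chrom_len / sum(chrom_len)))
  summit <- c(peaks$summit[shared],
              floor(stats::runif(n - length(shared)) *
                      chrom_len[chrom[-seq_along(shared)]]))
  up <- round(widths / 2)
  start <- pmax(0L, summit - up)
  end <- pmin(as.integer(chrom_len[chrom]), summit + (widths - up))
  summit <- pmin(pmax(summit, start), end - 1L)
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end),
                    name = sprintf("cmp%04d", seq_len(n)),
                    score = 51 + (n:1) * 100 / n,
                    summit = as.integer(summit), stringsAsFactors = FALSE)
  validate_peaks(out)
  out
}

# Flat numeric summary used for the JSON report.
report_summary <- function(report) {
  list(
    n_peaks = report$n_peaks,
    n_hre = report$n_hre,
    n_non_hre = report$n_non_hre,
    hre_fraction = report$hre_fraction,
    n_associations = report$n_associations,
    n_assoc_peaks = report$n_assoc_peaks,
    n_up = report$de$n_up,
    n_down = report$de$n_down,
    universe = report$de$universe,
    k_up = report$enrichment$up$k,
    p_up = report$enrichment$up$p,
    k_down = report$enrichment$down$k,
    p_down = report$enrichment$down$p,
    odds_ratio_up = report$enrichment$up$odds_ratio,
    overlap_any = report$overlap$n_any,
    overlap_pass = report$overlap$n_pass,
    qpcr_efficiency = report$qpcr$efficiency,
    chip_enrichment_median =
      stats::median(report$qpcr$enrichment$fold_change)
  )
}

#' @export
print.hre_report <- function(x, ...) {
  cat("HRE pipeline report\n")
  cat(sprintf("  peaks: %d (%d with HRE near summit, %.1f%%)\n",
              x$n_peaks, x$n_hre, 100 * x$hre_fraction))
  cat("  HRE fraction by significance bin:",
      paste(sprintf("%.2f", x$bin_summary$hre_fraction), collapse = " "),
      "\n")
  lf <- x$label_distribution
  cat("  summit regions:",
      paste(sprintf("%s %.1f%%", lf$label, 100 * lf$fraction),
            collapse = ", "), "\n")
  cat(sprintf("  TSS associations: %d (from %d peaks, %d genes)\n",
              x$n_associations, x$n_assoc_peaks, x$n_assoc_genes))
  cat(sprintf("  DE: %d up / %d down of %d platform genes\n",
              x$de$n_up, x$de$n_down, x$de$universe))
  cat(sprintf("  up-genes with TSS peak: %d (hypergeometric p = %.3g, OR %.2f)\n",
              x$enrichment$up$k, x$enrichment$up$p,
              x$enrichment$up$odds_ratio))
  cat(sprintf("  down-genes with TSS peak: %d (p = %.3g)\n",
              x$enrichment$down$k, x$enrichment$down$p))
  cat(sprintf("  comparison peaks overlapping: %d of %d (%d pass >50%%)\n",
              x$overlap$n_any, x$overlap$n_query, x$overlap$n_pass))
  cat(sprintf("  qPCR efficiency: %.3f; median ChIP enrichment: %.1f-fold\n",
              x$qpcr$efficiency,
              stats::median(x$qpcr$enrichment$fold_change)))
  invisible(x)
}
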