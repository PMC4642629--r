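#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' random genome at a fish-like GC content; non-overlapping stranded gene
#' models; significance-ranked peaks whose planted RCGTG motifs concentrate
#' near summits with Laplace-distributed offsets and decay in frequency with
#' rank; an expression table in which up-regulated genes are enriched for
#' TSS-proximal peaks at a configurable odds ratio; and Ct tables generated
#' from a log-linear amplification model with configurable ChIP enrichment.
#' Identical configuration and seed give bit-identical outputs.
#'
#' @param seed Integer seed; every stage derives its stream from it.
#' @param genome_length Total genome size in bp (>= 10 kb).
#' @param n_chromosomes Number of chromosomes (equal sizes, remainder on the
#'   last).
#' @param gc_content Genome GC fraction.
#' @param n_genes Number of gene models.
#' @param gene_length_range Log-uniform gene length range in bp.
#' @param n_peaks Number of peaks.
#' @param peak_width_range Log-uniform peak width range in bp.
#' @param tss_target_frac Fraction of peaks whose summit is placed within the
#'   TSS window of a randomly chosen gene.
#' @param motif_prob_by_rank Probability that a peak carries a planted motif,
#'   per consecutive significance-rank bin (bins split the ranking evenly).
#' @param summit_offset_scale Laplace scale b (bp) of planted motif offsets
#'   from the summit.
#' @param de_fraction_up,de_fraction_down Fractions of genes up-/down-
#'   regulated.
#' @param peak_de_odds Odds that an up-regulated gene carries a TSS peak,
#'   relative to a non-up gene.
#' @param chip_enrichment Fold pull-down of enriched regions in ChIP
#'   material (> 1).
#' @param qpcr_efficiency Amplification efficiency of simulated assays.
#' @param ct_noise_sd Gaussian Ct noise in cycles.
#' @param ct_baseline Ct of one unit of input template.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 6e6,
                       n_chromosomes = 3L,
                       gc_content = 0.37,
                       n_genes = 500L,
                       gene_length_range = c(1000, 15000),
                       n_peaks = 400L,
                       peak_width_range = c(200, 1500),
                       tss_target_frac = 0.3,
                       motif_prob_by_rank = c(0.95, 0.85, 0.7, 0.55),
                       summit_offset_scale = 30,
                       de_fraction_up = 0.1,
                       de_fraction_down = 0.15,
                       peak_de_odds = 4,
                       chip_enrichment = 22,
                       qpcr_efficiency = 1.95,
                       ct_noise_sd = 0.1,
                       ct_baseline = 25) {
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              n_chromosomes = as.integer(n_chromosomes),
              gc_content = gc_content, n_genes = as.integer(n_genes),
              gene_length_range = gene_length_range,
              n_peaks = as.integer(n_peaks),
              peak_width_range = peak_width_range,
              tss_target_frac = tss_target_frac,
              motif_prob_by_rank = motif_prob_by_rank,
              summit_offset_scale = summit_offset_scale,
              de_fraction_up = de_fraction_up,
              de_fraction_down = de_fraction_down,
              peak_de_odds = peak_de_odds,
              chip_enrichment = chip_enrichment,
              qpcr_efficiency = qpcr_efficiency,
              ct_noise_sd = ct_noise_sd, ct_baseline = ct_baseline)
  if (cfg$genome_length < 1e4) stop("genome_length must be >= 10 kb")
  probs <- c(cfg$gc_content, cfg$tss_target_frac, cfg$motif_prob_by_rank,
             cfg$de_fraction_up, cfg$de_fraction_down)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$de_fraction_up + cfg$de_fraction_down > 1) {
    stop("de_fraction_up + de_fraction_down must be <= 1")
  }
  if (cfg$peak_de_odds <= 0) stop("peak_de_odds must be > 0")
  if (cfg$chip_enrichment < 1) stop("chip_enrichment must be >= 1")
  if (cfg$qpcr_efficiency <= 1) stop("qpcr_efficiency must be > 1")
  if (cfg$ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# Each stage seeds its own stream at a fixed offset from the run seed, so a
# stage is reproducible both inside run_all() and when called standalone.
stage_seed <- function(config, stage) {
  set.seed((config$seed %% 2147480000L) + stage)
}

#' Simulate a genome
#'
#' I.i.d. bases at the configured GC content, split over equally sized
#' chromosomes named chr1, chr2, ...
#'
#' @param config A [sim_config()].
#' @return Named character vector of chromosome sequences.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stage_seed(config, 0L)
  gc <- config$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  per <- floor(config$genome_length / config$n_chromosomes)
  lens <- rep(per, config$n_chromosomes)
  lens[config$n_chromosomes] <-
    config$genome_length - per * (config$n_chromosomes - 1L)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  stats::setNames(seqs, paste0("chr", seq_along(seqs)))
}

#' Simulate non-overlapping stranded gene models
#'
#' Gene lengths are log-uniform over the configured range; strands are
#' assigned 50/50. Genes are placed per chromosome by distributing the free
#' space between them as normalised exponential gaps, which guarantees
#' non-overlap at any feasible density in a single pass.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return Gene data.frame (`chrom`, `start`, `end`, `gene_id`, `score`,
#'   `strand`, `tss`).
#' @export
simulate_genes <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  force(genome)  # evaluate before seeding: lazy args must not disturb the stream
  stage_seed(config, 1L)
  n <- config$n_genes
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      score = numeric(0), strand = character(0),
                      tss = integer(0), stringsAsFactors = FALSE))
  }
  lr <- log10(config$gene_length_range)
  lens <- round(10^stats::runif(n, lr[1], lr[2]))
  chrom_len <- nchar(genome)
  chrom <- sample(names(genome), n, replace = TRUE,
                  prob = chrom_len / sum(chrom_len))
  rows <- lapply(names(genome), function(cc) {
    idx <- which(chrom == cc)
    if (!length(idx)) return(NULL)
    gl <- lens[idx]
    free <- chrom_len[[cc]] - sum(gl)
    if (free < 0) {
      stop("cannot place ", length(idx), " genes totalling ", sum(gl),
           " bp on ", cc, " (", chrom_len[[cc]], " bp)")
    }
    gaps <- stats::rexp(length(idx) + 1L)
    gaps <- floor(gaps / sum(gaps) * free)
    starts <- cumsum(c(0L, gl[-length(gl)])) + cumsum(gaps[-length(gaps)])
    data.frame(chrom = cc, start = as.integer(starts),
               end = as.integer(starts + gl), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$gene_id <- sprintf("g%04d", seq_len(nrow(out)))
  out$score <- 0
  out$strand <- sample(c("+", "-"), nrow(out), replace = TRUE)
  out$tss <- gene_tss(out)
  rownames(out) <- NULL
  out
}

#' Simulate a significance-ranked peak set with planted motifs
#'
#' A configured fraction of peaks is targeted at gene TSS windows, the rest
#' placed uniformly. Scores decrease with rank; each peak carries a planted
#' RCGTG 5-mer with the probability of its rank bin, written into the genome
#' at `summit + Laplace(0, b)` so the scanning stage is exercised through
#' real sequence. A planted motif is resampled if it would fall outside the
#' chromosome or overwrite a previously planted motif. The returned truth
#' table distinguishes planted motifs from background chance matches.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param genes Output of [simulate_genes()].
#' @return A list with `peaks` (peak data.frame), `genome` (sequences with
#'   motifs written in) and `truth` (per-peak data.frame: `name`, `rank`,
#'   `score`, `planted`, `motif_start`, `motif_strand`, `offset`,
#'   `target_gene`).
#' @export
simulate_peaks <- function(config, genome, genes) {
  stopifnot(inherits(config, "sim_config"))
  force(genome); force(genes)
  stage_seed(config, 2L)
  n <- config$n_peaks
  chrom_len <- nchar(genome)
  wr <- log10(config$peak_width_range)
  widths <- round(10^stats::runif(n, wr[1], wr[2]))

  n_tss <- round(config$tss_target_frac * n)
  n_tss <- min(n_tss, nrow(genes))
  target_gene <- rep(NA_character_, n)
  chrom <- character(n)
  summit <- integer(n)
  if (n_tss > 0L) {
    gi <- sample(nrow(genes), n_tss)
    target_gene[seq_len(n_tss)] <- genes$gene_id[gi]
    chrom[seq_len(n_tss)] <- genes$chrom[gi]
    summit[seq_len(n_tss)] <- genes$tss[gi] +
      round(stats::runif(n_tss, -900, 900))
  }
  if (n > n_tss) {
    idx <- seq.int(n_tss + 1L, n)
    chrom[idx] <- sample(names(genome), length(idx), replace = TRUE,
                         prob = chrom_len / sum(chrom_len))
    summit[idx] <- floor(stats::runif(length(idx)) * chrom_len[chrom[idx]])
  }
  # summit placed at a uniform interior fraction of the width, peak clipped
  # to the chromosome
  up <- round(widths * stats::runif(n, 0.25, 0.75))
  start <- pmax(0L, summit - up)
  end <- pmin(as.integer(chrom_len[chrom]), summit + (widths - up))
  summit <- pmin(pmax(summit, start), end - 1L)

  rank <- sample(n)  # significance rank independent of genomic placement
  score <- 51 + (n - rank) * 450 / n
  m <- length(config$motif_prob_by_rank)
  bin <- ceiling(rank * m / n)
  plant <- stats::runif(n) < config$motif_prob_by_rank[bin]

  fwd5 <- c("ACGTG", "GCGTG")
  rev5 <- c("CACGT", "CACGC")
  motif_start <- rep(NA_integer_, n)
  motif_strand <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n)
  occupied <- lapply(genome, function(x) integer(0))
  raw_genome <- lapply(genome, charToRaw)  # avoid whole-string copies
  b <- config$summit_offset_scale
  for (j in which(plant)) {
    L <- chrom_len[[chrom[j]]]
    for (try in 1:200) {
      o <- as.integer(round(stats::rexp(1, 1 / b) * sample(c(-1L, 1L), 1)))
      ms <- summit[j] + o
      if (ms < 0L || ms > L - 5L) next
      occ <- occupied[[chrom[j]]]
      if (length(occ) && any(abs(occ - ms) < 5L)) next
      strand <- sample(c("+", "-"), 1)
      mer <- if (strand == "+") sample(fwd5, 1) else sample(rev5, 1)
      raw_genome[[chrom[j]]][(ms + 1L):(ms + 5L)] <- charToRaw(mer)
      occupied[[chrom[j]]] <- c(occ, ms)
      motif_start[j] <- ms
      motif_strand[j] <- strand
      offset[j] <- o
      break
    }
    if (is.na(motif_start[j])) plant[j] <- FALSE
  }
  genome <- vapply(raw_genome, rawToChar, character(1))

  name <- sprintf("peak%04d", seq_len(n))
  peaks <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(end), name = name, score = score,
                      summit = as.integer(summit), stringsAsFactors = FALSE)
  validate_peaks(peaks)
  truth <- data.frame(name = name, rank = rank, score = score,
                      planted = plant, motif_start = motif_start,
                      motif_strand = motif_strand, offset = offset,
                      target_gene = target_gene, stringsAsFactors = FALSE)
  list(peaks = peaks, genome = genome, truth = truth)
}

#' Simulate an expression table tied to TSS-peak status
#'
#' Genes carrying a peak within the TSS window are up-regulated at
#' `peak_de_odds` times the odds of peak-free genes; the baseline is solved
#' so the overall up fraction matches `de_fraction_up`. Down-regulated genes
#' are drawn uniformly from the remainder. DE genes receive linear fold
#' changes beyond the 2-fold boundary (log-normal tail) and p-values below
#' 0.01; null genes stay inside the boundary with uniform p-values.
#'
#' @param config A [sim_config()].
#' @param genes Output of [simulate_genes()].
#' @param peaks Peak data.frame (used to determine realised TSS-peak status).
#' @param tss_window Window around the TSS defining "carries a peak".
#' @return A list with `records` (expression data.frame: `probe_id`,
#'   `symbol`, `fold_change`, `p_value`, `direction`) and `truth` (per-gene
#'   data.frame: `symbol`, `status`, `has_tss_peak`).
#' @export
simulate_expression <- function(config, genes, peaks, tss_window = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  force(genes); force(peaks)
  stage_seed(config, 3L)
  n <- nrow(genes)
  has_peak <- vapply(seq_len(n), function(i) {
    sel <- peaks$chrom == genes$chrom[i]
    any(abs(peaks$summit[sel] - genes$tss[i]) <= tss_window)
  }, logical(1))
  f <- mean(has_peak)
  u <- config$de_fraction_up
  odds <- config$peak_de_odds
  # baseline up-probability p0 solving f*p1 + (1-f)*p0 = u with
  # odds(p1) = peak_de_odds * odds(p0)
  p1_of <- function(p0) odds * p0 / (1 - p0 + odds * p0)
  p0 <- if (u == 0) 0 else
    stats::uniroot(function(p0) f * p1_of(p0) + (1 - f) * p0 - u,
                   c(1e-12, 0.999))$root
  p_up <- ifelse(has_peak, p1_of(p0), p0)
  status <- ifelse(stats::runif(n) < p_up, "up", "null")
  n_down <- round(config$de_fraction_down * n)
  pool <- which(status == "null")
  if (n_down > 0L && length(pool)) {
    status[sample(pool, min(n_down, length(pool)))] <- "down"
  }

  log2fc <- numeric(n)
  de <- status != "null"
  log2fc[status == "up"] <- 1 + abs(stats::rnorm(sum(status == "up"), 0, 0.8))
  log2fc[status == "down"] <- -1 - abs(stats::rnorm(sum(status == "down"),
                                                    0, 0.8))
  null_fc <- stats::rnorm(sum(!de), 0, 0.35)
  log2fc[!de] <- pmin(pmax(null_fc, -0.99), 0.99)
  pval <- numeric(n)
  pval[de] <- stats::runif(sum(de), 0, 0.01)
  pval[!de] <- stats::runif(sum(!de))

  records <- data.frame(probe_id = sprintf("probe%05d", seq_len(n)),
                        symbol = genes$gene_id,
                        fold_change = 2^log2fc, p_value = pval,
                        direction = ifelse(log2fc >= 0, "up", "down"),
                        stringsAsFactors = FALSE)
  # a second concordant probe for ~10% of genes, as on real platforms
  dup <- which(stats::runif(n) < 0.1)
  if (length(dup)) {
    extra <- records[dup, , drop = FALSE]
    extra$probe_id <- sprintf("probe%05d", n + seq_along(dup))
    extra$fold_change <- extra$fold_change * 2^stats::rnorm(length(dup), 0, 0.05)
    records <- rbind(records, extra)
  }
  rownames(records) <- NULL
  truth <- data.frame(symbol = genes$gene_id, status = status,
                      has_tss_peak = has_peak, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Simulate a ChIP-qPCR Ct table
#'
#' Ct values follow the log-linear amplification model
#' `Ct = baseline - log_E(template)` plus Gaussian noise; ChIP template is
#' multiplied by `chip_enrichment` for enriched regions, with a global
#' pull-down factor shared by all regions (which cancels in the Pfaffl-
#' variant ratio).
#'
#' @param config A [sim_config()].
#' @param targets Names of enriched regions.
#' @param controls Names of non-enriched control regions.
#' @param replicates Technical replicates per (region, condition).
#' @return A data.frame with columns `region`, `condition`, `replicate`,
#'   `ct`, `efficiency` and `enriched`.
#' @export
simulate_qpcr <- function(config, targets = sprintf("target%02d", 1:5),
                          controls = "control01", replicates = 3L) {
  stopifnot(inherits(config, "sim_config"))
  stage_seed(config, 4L)
  E <- config$qpcr_efficiency
  pulldown <- 0.02  # global ChIP recovery; cancels in the ratio
  regions <- c(targets, controls)
  enriched <- c(rep(TRUE, length(targets)), rep(FALSE, length(controls)))
  grid <- expand.grid(replicate = seq_len(replicates),
                      condition = c("input", "chip"),
                      region = regions, stringsAsFactors = FALSE)
  grid$enriched <- enriched[match(grid$region, regions)]
  amount <- ifelse(grid$condition == "input", 1,
                   pulldown * ifelse(grid$enriched, config$chip_enrichment, 1))
  grid$ct <- config$ct_baseline - log(amount) / log(E) +
    stats::rnorm(nrow(grid), 0, config$ct_noise_sd)
  grid$efficiency <- E
  grid[, c("region", "condition", "replicate", "ct", "efficiency",
           "enriched")]
}

#' Simulate a qPCR dilution series
#'
#' @param config A [sim_config()] (uses `qpcr_efficiency` and `ct_noise_sd`).
#' @param concentrations Input amounts; a zero concentration yields NA.
#' @param intercept Ct at one unit of input.
#' @return A data.frame with columns `concentration` and `ct`.
#' @export
simulate_dilution <- function(config,
                              concentrations = c(300, 100, 30, 10, 3, 1),
                              intercept = 30) {
  stopifnot(inherits(config, "sim_config"))
  stage_seed(config, 6L)
  E <- config$qpcr_efficiency
  ct <- ifelse(concentrations > 0,
               intercept - log10(concentrations) / log10(E) +
                 stats::rnorm(length(concentrations), 0, config$ct_noise_sd),
               NA_real_)
  data.frame(concentration = concentrations, ct = ct)
}
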