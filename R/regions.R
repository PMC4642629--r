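#' Genomic-context region bounds
#'
#' The six-category scheme classifies a position against the gene whose TSS
#' is nearest. Per gene (strand-aware, all intervals 0-based half-open):
#' \describe{
#'   \item{TSS}{`[tss - tss, tss + tss)` around the transcription start site.}
#'   \item{Promoter}{the 5' stretch from the TSS region out to `promoter` bp
#'     upstream, `[tss - promoter, tss - tss_bound)` for + strand genes.}
#'   \item{Inside}{the gene body (introns and exons) minus the TSS region.}
#'   \item{Proximal}{`proximal` bp flanking the promoter/inside envelope on
#'     both sides.}
#'   \item{Distal}{`distal` bp flanking the proximal regions.}
#'   \item{Desert}{anything beyond the distal envelope.}
#' }
#' With the defaults the desert starts 100 kb upstream of the TSS and 95 kb
#' downstream of the gene end.
#'
#' @param tss,promoter,proximal,distal Extents in bp.
#' @return A named list of bounds.
#' @export
region_bounds <- function(tss = 1000L, promoter = 5000L, proximal = 5000L,
                          distal = 90000L) {
  b <- list(tss = as.integer(tss), promoter = as.integer(promoter),
            proximal = as.integer(proximal), distal = as.integer(distal))
  if (any(unlist(b) < 0L)) stop("region bounds must be non-negative")
  if (b$promoter < b$tss) stop("promoter bound must be >= tss bound")
  b
}

#' Region label levels, promoter-proximal to desert
#' @export
region_labels <- function() {
  c("TSS", "Promoter", "Inside", "Proximal", "Distal", "Desert")
}

# Per-gene template geometry. env_lo/env_hi bound the promoter+TSS+body
# envelope; proximal and distal flank it symmetrically in genome coordinates.
gene_templates <- function(genes, bounds) {
  plus <- genes$strand == "+"
  tss <- genes$tss
  env_lo <- ifelse(plus, tss - bounds$promoter,
                   pmin(genes$start, tss - bounds$tss))
  env_hi <- ifelse(plus, pmax(genes$end, tss + bounds$tss),
                   tss + bounds$promoter)
  prom_lo <- ifelse(plus, tss - bounds$promoter, tss + bounds$tss)
  prom_hi <- ifelse(plus, tss - bounds$tss, tss + bounds$promoter)
  list(tss = tss, plus = plus, start = genes$start, end = genes$end,
       env_lo = env_lo, env_hi = env_hi, prom_lo = prom_lo, prom_hi = prom_hi)
}

# Nearest-TSS gene (unsigned distance) for 0-based positions on one
# chromosome; ties between equidistant TSSs are broken by lexicographic
# gene_id. Returns row indices into `genes` (NA when the chromosome holds no
# gene).
nearest_tss_gene <- function(chrom, pos, genes) {
  out <- rep(NA_integer_, length(pos))
  for (cc in unique(chrom)) {
    sel <- which(chrom == cc)
    g <- which(genes$chrom == cc)
    if (!length(g)) next
    # one representative gene per unique TSS position: smallest gene_id
    ord <- g[order(genes$tss[g], genes$gene_id[g])]
    keep <- !duplicated(genes$tss[ord])
    reps <- ord[keep]
    ts <- genes$tss[reps]
    p <- pos[sel]
    i <- findInterval(p, ts)
    dl <- rep.int(Inf, length(p))
    dr <- rep.int(Inf, length(p))
    has_l <- i >= 1L
    has_r <- i < length(ts)
    dl[has_l] <- p[has_l] - ts[i[has_l]]
    dr[has_r] <- ts[i[has_r] + 1L] - p[has_r]
    choose_left <- dl < dr
    tie <- which(dl == dr & is.finite(dl))
    if (length(tie)) {
      # equidistant: lexicographically smaller gene_id wins
      choose_left[tie] <- genes$gene_id[reps[i[tie]]] <=
        genes$gene_id[reps[i[tie] + 1L]]
    }
    idx <- i + 1L
    idx[choose_left] <- i[choose_left]
    out[sel] <- reps[idx]
  }
  out
}

# Integer label codes (1..6 following region_labels()) for positions against
# their nearest-TSS gene; `tpl` is gene_templates(genes, bounds) precomputed
# over the full gene table. Returns list(code, gene_index).
classify_core <- function(chrom, pos, genes, bounds, tpl) {
  gi <- nearest_tss_gene(chrom, pos, genes)
  code <- rep.int(6L, length(pos))  # Desert
  ok <- which(!is.na(gi))
  if (length(ok)) {
    g <- gi[ok]
    p <- pos[ok]
    tss <- tpl$tss[g]
    env_lo <- tpl$env_lo[g]; env_hi <- tpl$env_hi[g]
    sub <- rep.int(6L, length(ok))
    d_lo <- env_lo - bounds$proximal
    d_hi <- env_hi + bounds$proximal
    sub[(p >= d_lo - bounds$distal & p < d_lo) |
          (p >= d_hi & p < d_hi + bounds$distal)] <- 5L
    sub[(p >= d_lo & p < env_lo) | (p >= env_hi & p < d_hi)] <- 4L
    sub[p >= tpl$start[g] & p < tpl$end[g] &
          p >= env_lo & p < env_hi] <- 3L
    sub[p >= tpl$prom_lo[g] & p < tpl$prom_hi[g]] <- 2L
    sub[p >= tss - bounds$tss & p < tss + bounds$tss] <- 1L
    code[ok] <- sub
  }
  list(code = code, gene_index = gi)
}

# Vectorised label assignment for positions against their nearest-TSS gene.
classify_positions <- function(chrom, pos, genes, bounds) {
  tpl <- gene_templates(genes, bounds)
  res <- classify_core(chrom, pos, genes, bounds, tpl)
  gene <- ifelse(res$code == 6L, NA_character_, genes$gene_id[res$gene_index])
  data.frame(label = factor(region_labels()[res$code],
                            levels = region_labels()),
             gene_id = gene, stringsAsFactors = FALSE)
}

#' Classify peak summits into genomic-context categories
#'
#' Each summit is classified against the gene whose TSS is nearest (single
#' nearest gene rule, unsigned distance, ties broken by lexicographic
#' gene_id), into exactly one of the six labels of [region_bounds()]. An
#' empty gene set yields Desert for all summits, with a warning.
#'
#' @param peaks Peak data.frame.
#' @param genes Gene data.frame (see [read_genes()]).
#' @param bounds Region bounds, see [region_bounds()].
#' @return A data.frame with columns `name`, `label` (factor over the six
#'   categories) and `gene_id` (the deciding gene, NA for Desert).
#' @export
classify_summits <- function(peaks, genes, bounds = region_bounds()) {
  validate_peaks(peaks)
  if (nrow(genes) == 0L) {
    warning("empty gene set: all summits classified as Desert")
    return(data.frame(name = peaks$name,
                      label = factor(rep("Desert", nrow(peaks)),
                                     levels = region_labels()),
                      gene_id = NA_character_, stringsAsFactors = FALSE))
  }
  res <- classify_positions(peaks$chrom, peaks$summit, genes, bounds)
  data.frame(name = peaks$name, label = res$label, gene_id = res$gene_id,
             stringsAsFactors = FALSE)
}

#' Genome-wide base fractions per region category
#'
#' Classifies every base of the genome by the same nearest-TSS semantics as
#' [classify_summits()] and returns the fraction of bases per label. This is
#' the expected label distribution for peaks placed uniformly at random, i.e.
#' the null against which an observed peak-label distribution is read.
#'
#' @param genes Gene data.frame.
#' @param chromosome_lengths data.frame with columns `chrom` and `length`.
#' @param bounds Region bounds.
#' @return A data.frame with columns `label`, `bases` and `fraction`;
#'   fractions sum to 1.
#' @export
genome_region_fractions <- function(genes, chromosome_lengths,
                                    bounds = region_bounds()) {
  stopifnot(all(c("chrom", "length") %in% names(chromosome_lengths)))
  missing <- setdiff(unique(genes$chrom), chromosome_lengths$chrom)
  if (length(missing)) {
    stop("gene chromosome(s) not in chromosome_lengths: ",
         paste(missing, collapse = ", "))
  }
  lens <- stats::setNames(chromosome_lengths$length, chromosome_lengths$chrom)
  for (i in seq_len(nrow(genes))) {
    if (genes$start[i] < 0L || genes$end[i] > lens[[genes$chrom[i]]]) {
      stop("gene ", genes$gene_id[i], " outside chromosome bounds")
    }
  }
  counts <- stats::setNames(numeric(length(region_labels())), region_labels())
  tpl <- gene_templates(genes, bounds)
  chunk <- 1000000L
  for (cc in chromosome_lengths$chrom) {
    len <- lens[[cc]]
    done <- 0L
    while (done < len) {
      pos <- seq.int(done, min(done + chunk, len) - 1L)
      res <- classify_core(rep(cc, length(pos)), pos, genes, bounds, tpl)
      counts <- counts + tabulate(res$code, nbins = 6L)
      done <- done + chunk
    }
  }
  data.frame(label = factor(region_labels(), levels = region_labels()),
             bases = as.numeric(counts),
             fraction = as.numeric(counts) / sum(counts))
}

#' Distribution of peak summits over region categories
#'
#' @param peaks Peak data.frame.
#' @param genes Gene data.frame.
#' @param bounds Region bounds.
#' @return A data.frame with columns `label`, `count` and `fraction`;
#'   fractions sum to 1.
#' @export
label_distribution <- function(peaks, genes, bounds = region_bounds()) {
  cls <- classify_summits(peaks, genes, bounds)
  tab <- table(cls$label)
  data.frame(label = factor(names(tab), levels = region_labels()),
             count = as.integer(tab),
             fraction = as.integer(tab) / nrow(peaks))
}

#' Associate peaks with genes by the two-nearest-genes TSS-window rule
#'
#' For each peak, the `n_nearest` genes by unsigned TSS-to-summit distance on
#' the same chromosome are found; of those, only genes whose TSS lies within
#' `tss_window` bp of the summit are retained. A peak can thus yield 0, 1 or
#' up to `n_nearest` association rows. Equidistant candidates are ordered by
#' gene_id. The signed distance is reported in gene orientation: positive
#' when the summit lies downstream of the TSS.
#'
#' @param peaks Peak data.frame.
#' @param genes Gene data.frame.
#' @param n_nearest Number of nearest genes to consider per peak.
#' @param tss_window Retention window around the TSS in bp.
#' @return A data.frame with columns `name` (peak), `gene_id` and `distance`.
#' @export
associate_peaks <- function(peaks, genes, n_nearest = 2L, tss_window = 1000L) {
  validate_peaks(peaks)
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  rows <- lapply(seq_len(nrow(peaks)), function(j) {
    g <- by_chrom[[peaks$chrom[j]]]
    if (is.null(g)) return(NULL)
    s <- peaks$summit[j]
    d_abs <- abs(genes$tss[g] - s)
    ord <- g[order(d_abs, genes$gene_id[g])]
    near <- ord[seq_len(min(n_nearest, length(ord)))]
    keep <- near[abs(genes$tss[near] - s) <= tss_window]
    if (!length(keep)) return(NULL)
    signed <- ifelse(genes$strand[keep] == "+",
                     s - genes$tss[keep], genes$tss[keep] - s)
    data.frame(name = peaks$name[j], gene_id = genes$gene_id[keep],
               distance = as.integer(signed), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(name = character(0), gene_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
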