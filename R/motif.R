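#' Scan a sequence region for the RCGTG consensus on both strands
#'
#' The hypoxia response element consensus bound by the HIF dimer is RCGTG
#' (R = A or G, IUPAC). A position is a forward-strand hit when the 5-mer
#' starting there is ACGTG or GCGTG, and a reverse-strand hit when the 5-mer
#' read on the reverse complement matches (i.e. the forward 5-mer is CACGT or
#' CACGC). The palindromic CACGTG therefore yields two hits at overlapping
#' positions, one per strand: it genuinely binds bidirectionally. N never
#' matches.
#'
#' @param sequence A single character string (upper-case nucleotides).
#' @param region_start,region_end 0-based half-open bounds of the region to
#'   scan; default the whole sequence.
#' @return A data.frame with columns `position` (0-based match start on the
#'   forward strand) and `strand` ("+" or "-"), sorted by position then strand.
#'   Regions shorter than 5 bp return zero rows.
#' @export
scan_rcgtg <- function(sequence, region_start = 0L,
                       region_end = nchar(sequence)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  len <- nchar(sequence)
  if (region_start < 0L || region_end > len || region_start > region_end) {
    stop("region [", region_start, ", ", region_end,
         ") outside sequence of length ", len)
  }
  empty <- data.frame(position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (region_end - region_start < 5L) return(empty)
  r <- charToRaw(substr(sequence, region_start + 1L, region_end))
  n <- length(r)
  isA <- r == as.raw(65L); isC <- r == as.raw(67L)
  isG <- r == as.raw(71L); isT <- r == as.raw(84L)
  i <- seq_len(n - 4L)
  fwd <- (isA[i] | isG[i]) & isC[i + 1L] & isG[i + 2L] & isT[i + 3L] &
    isG[i + 4L]
  rev <- isC[i] & isA[i + 1L] & isC[i + 2L] & isG[i + 3L] &
    (isT[i + 4L] | isC[i + 4L])
  pos <- c(which(fwd), which(rev)) + region_start - 1L
  strand <- rep(c("+", "-"), c(sum(fwd), sum(rev)))
  ord <- order(pos, strand)
  data.frame(position = as.integer(pos[ord]), strand = strand[ord],
             stringsAsFactors = FALSE)
}

#' Reverse complement of a nucleotide string
#'
#' @param sequence A single character string over A, C, G, T, N.
#' @return The reverse complement.
#' @export
revcomp <- function(sequence) {
  rawToChar(rev(charToRaw(chartr("ACGTacgt", "TGCAtgca", sequence))))
}

#' Does a peak contain an HRE near its summit?
#'
#' Reads the "100 bp surrounding the summit" window as
#' `[summit - half_width, summit + half_width)` with the full 5-mer required
#' inside (match start in `[summit - half_width, summit + half_width - 5]`),
#' the conservative reading. Set `full_motif = FALSE` to require only the
#' match start inside the window. Windows are clipped at chromosome bounds.
#'
#' @param peaks Peak data.frame (see [read_peaks()]).
#' @param genome Named character vector of chromosome sequences.
#' @param half_width Half-width of the summit-centred window in bp.
#' @param full_motif Require the whole 5-mer inside the window (default).
#' @return Logical vector, one element per peak.
#' @export
peak_has_hre <- function(peaks, genome, half_width = 50L, full_motif = TRUE) {
  validate_peaks(peaks)
  check_chromosomes(peaks, genome, "peaks")
  lens <- nchar(genome)
  vapply(seq_len(nrow(peaks)), function(j) {
    chrom <- peaks$chrom[j]
    s <- peaks$summit[j]
    len <- lens[[chrom]]
    lo <- max(0L, s - half_width)
    hi <- if (full_motif) s + half_width else s + half_width + 4L
    hi <- min(len, hi)
    if (hi - lo < 5L) return(FALSE)
    hits <- scan_rcgtg(genome[[chrom]], lo, hi)
    if (!full_motif) hits <- hits[hits$position < s + half_width, , drop = FALSE]
    nrow(hits) > 0L
  }, logical(1))
}

#' Summit-relative distribution of RCGTG matches
#'
#' Collects, over all peaks, the signed offsets from each peak summit to every
#' RCGTG match start within `summit +- half_width`, and bins them. A
#' concentration of counts around offset 0 is the signature of genuine
#' summit-centred binding as opposed to the high genomic background of this
#' short consensus.
#'
#' @param peaks Peak data.frame.
#' @param genome Named character vector of chromosome sequences.
#' @param half_width Profile half-width in bp.
#' @param bin_width Histogram bin width in bp.
#' @return A data.frame with columns `bin_start`, `bin_end` (offset bounds)
#'   and `count`; all collected offsets are attached as attribute `offsets`.
#' @export
summit_distribution <- function(peaks, genome, half_width = 500L,
                                bin_width = 10L) {
  validate_peaks(peaks)
  if (nrow(peaks) == 0L) stop("no peaks supplied")
  check_chromosomes(peaks, genome, "peaks")
  lens <- nchar(genome)
  offsets <- unlist(lapply(seq_len(nrow(peaks)), function(j) {
    chrom <- peaks$chrom[j]
    s <- peaks$summit[j]
    lo <- max(0L, s - half_width)
    hi <- min(lens[[chrom]], s + half_width + 5L)
    if (hi - lo < 5L) return(integer(0))
    hits <- scan_rcgtg(genome[[chrom]], lo, hi)
    off <- hits$position - s
    off[off >= -half_width & off <= half_width]
  }))
  breaks <- seq(-half_width, half_width, by = bin_width)
  if (breaks[length(breaks)] < half_width) breaks <- c(breaks, half_width)
  counts <- tabulate(findInterval(offsets, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  out <- data.frame(bin_start = breaks[-length(breaks)],
                    bin_end = breaks[-1L], count = counts)
  attr(out, "offsets") <- offsets
  out
}

#' HRE fraction in significance-ranked peak bins
#'
#' Peaks are sorted by descending significance score (ties broken by
#' ascending chromosome then start, for deterministic output), partitioned
#' into consecutive bins of `bin_size` (the last bin may be short and is
#' retained), and the fraction of peaks containing an HRE near the summit is
#' computed per bin. For genuine binding data the fraction decays with rank.
#'
#' @param peaks Peak data.frame with scores.
#' @param genome Named character vector of chromosome sequences.
#' @param bin_size Number of peaks per rank bin.
#' @param half_width Summit window half-width passed to [peak_has_hre()].
#' @return A data.frame with columns `bin_index`, `bin_size` (peaks in the
#'   bin) and `hre_fraction`.
#' @export
binned_hre_fraction <- function(peaks, genome, bin_size = 1000L,
                                half_width = 50L) {
  if (bin_size < 1L) stop("bin_size must be >= 1")
  validate_peaks(peaks)
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  has <- peak_has_hre(peaks[ord, , drop = FALSE], genome,
                      half_width = half_width)
  n <- length(has)
  bin <- ceiling(seq_len(n) / bin_size)
  data.frame(bin_index = seq_len(max(bin)),
             bin_size = as.integer(tabulate(bin)),
             hre_fraction = as.numeric(tapply(has, bin, mean)),
             row.names = NULL)
}
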