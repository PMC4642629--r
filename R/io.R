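#' Read a genome from a FASTA file
#'
#' Sequences are upper-cased on read and any character outside A, C, G, T, N
#' is mapped to N with a warning. N never matches a motif, so ambiguity codes
#' are deliberately collapsed to "unknown".
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one upper-case sequence per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning("non-ACGTN characters in ", sum(bad),
            " record(s) mapped to N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  names(seqs) <- ids
  seqs
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return The path, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(genome)) {
    writeLines(paste0(">", names(genome)[i]), con)
    s <- genome[[i]]
    n <- nchar(s)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Chromosome sizes of a genome
#'
#' @param genome Named character vector of sequences.
#' @return A data.frame with columns `chrom` and `length`.
#' @export
chrom_sizes <- function(genome) {
  data.frame(chrom = names(genome), length = nchar(genome),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a chromosome-sizes table (UCSC two-column dialect)
#'
#' @param path Path to a two-column TSV (chromosome, length).
#' @return A data.frame with columns `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom-sizes file not found: ", path)
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("chrom-sizes file must have two columns")
  len <- suppressWarnings(as.numeric(d[[2]]))
  if (anyNA(len)) stop("non-numeric chromosome length in ", path)
  data.frame(chrom = as.character(d[[1]]), length = as.integer(len),
             stringsAsFactors = FALSE)
}

#' Read ChIP-seq peaks (narrowPeak / BED6+4)
#'
#' Coordinates are 0-based half-open (BED native). The summit is stored as an
#' absolute genomic position: column 10 is the summit offset from `start`; an
#' offset of -1 means "absent" and the interval midpoint (floor) is used, so
#' every peak carries a defined summit.
#'
#' @param path Path to a tab-separated narrowPeak file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `summit`, preserving input order.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 10L) stop("narrowPeak requires 10 tab-separated columns, got ",
                          ncol(d))
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("non-numeric ", what, " in ", path)
    v
  }
  start <- num(d[[2]], "start"); end <- num(d[[3]], "end")
  score <- num(d[[5]], "score"); offset <- num(d[[10]], "summit offset")
  if (any(end <= start)) {
    stop("peak with end <= start at line(s): ",
         paste(utils::head(which(end <= start), 5L), collapse = ", "))
  }
  if (any(score < 0)) stop("negative peak score in ", path)
  if (any(offset >= end - start)) {
    stop("summit offset outside the peak at line(s): ",
         paste(utils::head(which(offset >= end - start), 5L), collapse = ", "))
  }
  if (any(offset < -1)) stop("summit offset must be >= -1")
  summit <- ifelse(offset >= 0, start + offset, floor((start + end) / 2))
  peaks <- data.frame(chrom = as.character(d[[1]]),
                      start = as.integer(start), end = as.integer(end),
                      name = as.character(d[[4]]), score = score,
                      summit = as.integer(summit), stringsAsFactors = FALSE)
  validate_peaks(peaks)
  peaks
}

#' Write peaks as narrowPeak
#'
#' @param peaks Peak data.frame (see [read_peaks()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  validate_peaks(peaks)
  d <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                  peaks$score, ".", -1, -1, -1, peaks$summit - peaks$start)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("chrom", "start", "end", "name", "score", "summit") %in%
                  names(peaks)))
  with(peaks, {
    if (any(start >= end)) stop("peak with start >= end")
    if (any(summit < start | summit >= end)) {
      stop("peak summit outside [start, end)")
    }
    if (any(score < 0)) stop("negative peak score")
  })
  invisible(peaks)
}

#' Read gene models (BED6)
#'
#' The TSS is derived strand-aware from the 0-based half-open interval:
#' `start` for + strand genes, `end - 1` for - strand genes.
#'
#' @param path Path to a BED6 file (name column holds the gene id).
#' @return A data.frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `score`, `strand`, `tss`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("gene file not found: ", path)
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 6L) stop("BED6 requires 6 columns (strand in column 6), got ",
                         ncol(d))
  start <- suppressWarnings(as.numeric(d[[2]]))
  end <- suppressWarnings(as.numeric(d[[3]]))
  if (anyNA(start) || anyNA(end)) stop("malformed coordinates in ", path)
  if (any(end <= start)) stop("gene with end <= start in ", path)
  strand <- as.character(d[[6]])
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-', got: ",
         paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  }
  gene_id <- as.character(d[[4]])
  if (anyDuplicated(gene_id)) stop("duplicate gene ids in ", path)
  genes <- data.frame(chrom = as.character(d[[1]]),
                      start = as.integer(start), end = as.integer(end),
                      gene_id = gene_id,
                      score = suppressWarnings(as.numeric(d[[5]])),
                      strand = strand, stringsAsFactors = FALSE)
  genes$tss <- gene_tss(genes)
  genes
}

#' Strand-aware transcription start sites
#'
#' @param genes Gene data.frame with `start`, `end`, `strand`.
#' @return Integer vector of TSS positions (0-based).
#' @export
gene_tss <- function(genes) {
  as.integer(ifelse(genes$strand == "+", genes$start, genes$end - 1L))
}

#' Write gene models as BED6
#'
#' @param genes Gene data.frame (see [read_genes()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genes <- function(genes, path) {
  score <- if ("score" %in% names(genes)) genes$score else 0
  d <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                  score, genes$strand)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects a TSV with a header naming `probe_id`, `symbol`, `p_value` and a
#' fold-change column: `fold_change` (linear scale, down-regulation encoded as
#' values below 1) or `log2_fold_change` (signed). The dialect is declared via
#' `fc_scale`; all records are returned on the uniform linear scale.
#'
#' @param path Path to the TSV.
#' @param fc_scale Either "linear" or "log2".
#' @return A data.frame with columns `probe_id`, `symbol`, `fold_change`
#'   (linear), `p_value`, `direction` ("up" when fold_change >= 1).
#' @export
read_expression <- function(path, fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (!file.exists(path)) stop("expression table not found: ", path)
  d <- utils::read.delim(path, header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  fc_col <- if (fc_scale == "linear") "fold_change" else "log2_fold_change"
  need <- c("probe_id", "symbol", fc_col, "p_value")
  if (!all(need %in% names(d))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  fc <- as.numeric(d[[fc_col]])
  if (fc_scale == "log2") fc <- 2^fc
  p <- as.numeric(d$p_value)
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    stop("fold changes must be positive and finite on the linear scale")
  }
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  data.frame(probe_id = as.character(d$probe_id),
             symbol = as.character(d$symbol),
             fold_change = fc, p_value = p,
             direction = ifelse(fc >= 1, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Write a data.frame as TSV with a provenance header
#'
#' The header records the tool version and the parameters used, as commented
#' lines, so every stage output is self-describing.
#'
#' @param d A data.frame.
#' @param path Output path.
#' @param params Optional named list of parameters to record.
#' @return The path, invisibly.
#' @export
write_tsv <- function(d, path, params = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("hrescope"))
  writeLines(paste0("# hrescope ", ver), con)
  if (length(params)) {
    writeLines(paste0("# params: ",
                      paste(names(params), unlist(params), sep = "=",
                            collapse = " ")), con)
  }
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Exact chromosome-name matching between an interval set and a genome;
# any mismatch is a hard error listing the offending names.
check_chromosomes <- function(intervals, genome, what = "intervals") {
  missing <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing)) {
    stop("chromosome(s) in ", what, " absent from the genome: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
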