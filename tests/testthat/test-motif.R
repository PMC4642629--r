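test_that("scan_rcgtg finds the consensus and its reverse complement", {
  hits <- scan_rcgtg("ACGTG")
  expect_equal(hits$position, 0L)
  expect_equal(hits$strand, "+")

  hits <- scan_rcgtg("CACGT")
  expect_equal(hits$position, 0L)
  expect_equal(hits$strand, "-")

  # palindromic CACGTG yields one hit per strand at overlapping positions
  hits <- scan_rcgtg("CACGTG")
  expect_equal(hits$position, c(0L, 1L))
  expect_equal(hits$strand, c("-", "+"))

  # N never matches
  expect_equal(nrow(scan_rcgtg("NCGTG")), 0L)
  # short regions return empty, not an error
  expect_equal(nrow(scan_rcgtg("ACGTGACGTG", 0, 4)), 0L)
  expect_error(scan_rcgtg("ACGTG", 0, 10), "outside sequence")
})

test_that("exactly 4 of the 1024 5-mers match on either strand", {
  bases <- c("A", "C", "G", "T")
  mers <- apply(expand.grid(bases, bases, bases, bases, bases), 1, paste,
                collapse = "")
  n_hits <- vapply(mers, function(m) nrow(scan_rcgtg(m)), integer(1))
  expect_equal(sum(n_hits > 0), 4L)
  expect_equal(sort(mers[n_hits > 0]), c("ACGTG", "CACGC", "CACGT", "GCGTG"))
  # per-position match probability on uniform sequence is 4/1024 = 1/256
  expect_equal(sum(n_hits), 4L)
})

test_that("scan agrees with substring enumeration on random sequence", {
  set.seed(71)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 400, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    expect_equal(scan_rcgtg(s), oracle_scan(s))
  }
})

test_that("scanning is strand-symmetric under reverse complement", {
  set.seed(72)
  s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
             collapse = "")
  fwd <- scan_rcgtg(s)
  rev <- scan_rcgtg(revcomp(s))
  # a + hit at p maps to a - hit at n - 5 - p on the reverse complement
  mirrored <- data.frame(position = nchar(s) - 5L - rev$position,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         stringsAsFactors = FALSE)
  mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
  rownames(mirrored) <- NULL
  expect_equal(mirrored, fwd)
})

test_that("peak_has_hre applies the window rule at exact boundaries", {
  pad <- strrep("T", 200)
  # motif start exactly at summit - 50: inside
  s1 <- paste0(pad, "ACGTG", strrep("T", 200))
  g <- c(chr1 = s1)
  p <- make_peaks("chr1", 150, 350, summit = 250)
  expect_true(peak_has_hre(p, g, half_width = 50))
  # motif start at summit + 46: the 5-mer exits the window
  g2 <- c(chr1 = paste0(strrep("T", 296), "ACGTG", strrep("T", 200)))
  p2 <- make_peaks("chr1", 150, 350, summit = 250)
  expect_false(peak_has_hre(p2, g2, half_width = 50))
  # ... but the relaxed match-start-only rule accepts it
  expect_true(peak_has_hre(p2, g2, half_width = 50, full_motif = FALSE))
  # motif start at summit + 45 is the last admissible position
  g3 <- c(chr1 = paste0(strrep("T", 295), "ACGTG", strrep("T", 200)))
  expect_true(peak_has_hre(p2, g3, half_width = 50))
})

test_that("windows are clipped at chromosome bounds without error", {
  g <- c(chr1 = paste0("ACGTG", strrep("T", 60)))
  p <- make_peaks("chr1", 0, 20, summit = 2)
  expect_true(peak_has_hre(p, g, half_width = 50))
  p_end <- make_peaks("chr1", 50, 65, summit = 63)
  expect_false(peak_has_hre(p_end, g, half_width = 50))
})

test_that("enlarging the window never loses a detected HRE", {
  genome <- random_genome(20000, gc = 0.4, seed = 73)
  peaks <- random_peaks(60, genome, seed = 74)
  h25 <- peak_has_hre(peaks, genome, half_width = 25)
  h50 <- peak_has_hre(peaks, genome, half_width = 50)
  h100 <- peak_has_hre(peaks, genome, half_width = 100)
  expect_true(all(h50[h25]))
  expect_true(all(h100[h50]))
})

test_that("planted summit motifs are detected and scrambled peaks stay at background", {
  # plant ACGTG at the summit for half of 200 peaks on an A/T-only genome
  # (zero background), leave the rest motif-free
  set.seed(75)
  L <- 50000
  base <- paste(sample(c("A", "T"), L, replace = TRUE), collapse = "")
  raw <- charToRaw(base)
  summits <- seq.int(200, L - 200, length.out = 200)
  planted <- rep(c(TRUE, FALSE), 100)
  for (i in which(planted)) {
    raw[(summits[i] + 1):(summits[i] + 5)] <- charToRaw("ACGTG")
  }
  g <- c(chr1 = rawToChar(raw))
  peaks <- make_peaks("chr1", summits - 100, summits + 100,
                      summit = summits,
                      name = sprintf("pk%03d", seq_along(summits)))
  has <- peak_has_hre(peaks, g, half_width = 50)
  expect_true(all(has[planted]))
  expect_false(any(has[!planted]))
})

test_that("summit_distribution counts offsets and a summit motif lands in the 0 bin", {
  g <- c(chr1 = paste0(strrep("T", 500), "ACGTG", strrep("T", 500)))
  p <- make_peaks("chr1", 400, 600, summit = 500)
  prof <- summit_distribution(p, g, half_width = 100, bin_width = 10)
  expect_equal(sum(prof$count), 1L)
  hit_bin <- prof[prof$count == 1, ]
  expect_true(hit_bin$bin_start <= 0 && hit_bin$bin_end > 0)
  expect_equal(attr(prof, "offsets"), 0L)
})

test_that("summit profile is mirrored on the reverse-complemented genome", {
  genome <- random_genome(30000, gc = 0.45, seed = 76)
  peaks <- random_peaks(40, genome, seed = 77)
  prof <- summit_distribution(peaks, genome, half_width = 200, bin_width = 400)
  g_rc <- c(chr1 = revcomp(genome[["chr1"]]))
  L <- nchar(genome[["chr1"]])
  peaks_rc <- peaks
  # mirror summits; a match START at offset o maps to offset -(o + 4)
  peaks_rc$summit <- L - 1L - peaks$summit
  peaks_rc$start <- L - peaks$end
  peaks_rc$end <- L - peaks$start
  prof_rc <- summit_distribution(peaks_rc, g_rc, half_width = 200,
                                 bin_width = 400)
  # a +-hw window on match STARTS covers offsets [-hw, hw] forward but maps
  # to [-(hw+4), hw-4] on the mirror; compare on the common range
  off <- sort(attr(prof, "offsets"))
  off_rc <- sort(-(attr(prof_rc, "offsets") + 4L))
  expect_equal(off[off <= 196], off_rc[off_rc >= -200 & off_rc <= 196])
})

test_that("binned_hre_fraction partitions peaks by rank with a short last bin", {
  genome <- random_genome(100000, gc = 0, seed = 78)  # A/T only: no background
  peaks <- random_peaks(25, genome, seed = 79)
  peaks$score <- seq(500, 52, length.out = 25)
  bins <- binned_hre_fraction(peaks, genome, bin_size = 10)
  expect_equal(bins$bin_size, c(10L, 10L, 5L))
  expect_equal(bins$hre_fraction, c(0, 0, 0))
  expect_error(binned_hre_fraction(peaks, genome, bin_size = 0), "bin_size")
})

test_that("all-motif peak sets give fraction 1 and rank ties break by coordinate", {
  set.seed(80)
  L <- 30000
  raw <- charToRaw(paste(rep("T", L), collapse = ""))
  summits <- seq.int(200, L - 200, length.out = 30)
  for (s in summits) raw[(s + 1):(s + 5)] <- charToRaw("GCGTG")
  g <- c(chr1 = rawToChar(raw))
  peaks <- make_peaks("chr1", summits - 50, summits + 50, summit = summits,
                      score = 77, name = sprintf("pk%03d", seq_along(summits)))
  bins <- binned_hre_fraction(peaks, g, bin_size = 10)
  expect_equal(bins$hre_fraction, c(1, 1, 1))
  # equal scores: deterministic under row shuffling
  shuffled <- peaks[sample(nrow(peaks)), ]
  expect_equal(binned_hre_fraction(shuffled, g, bin_size = 10), bins)
})
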