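# Consensus peaks, normalization, FDR grid, two-round differential calling.

summitsAt <- function(pos) {
  GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))
}

test_that("consensus peaks follow the majority rule", {
  reps <- list(summitsAt(c(100, 500)), summitsAt(105), summitsAt(2000))
  cons <- consensusPeaks(reps)
  # 100 and 105 co-occur in two replicates; 500 and 2000 are singletons
  expect_equal(length(cons), 1)
  expect_equal(S4Vectors::mcols(cons)$support, 2)
  expect_equal(S4Vectors::mcols(cons)$summit, 102)  # median of 100, 105
  expect_equal(GenomicRanges::width(cons), 150)
  # summits 150 bp apart do not group; 149 bp apart do
  expect_equal(length(consensusPeaks(list(summitsAt(100), summitsAt(250),
                                          summitsAt(5000)))), 0)
  expect_equal(length(consensusPeaks(list(summitsAt(100), summitsAt(249),
                                          summitsAt(5000)))), 1)
})

test_that("consensus output is invariant to replicate order", {
  set.seed(301)
  reps <- lapply(1:3, function(i) summitsAt(sort(sample.int(100000, 50))))
  a <- consensusPeaks(reps)
  b <- consensusPeaks(rev(reps))
  expect_identical(GenomicRanges::granges(a), GenomicRanges::granges(b))
  expect_identical(S4Vectors::mcols(a)$support, S4Vectors::mcols(b)$support)
})

test_that("master consensus collapses overlaps and conserves disjoint peaks", {
  p1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 150))
  p2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 250))
  p3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1149))
  # identical inputs: idempotent
  same <- masterConsensus(list(c(p1, p3), c(p1, p3)))
  expect_equal(length(same), 2)
  expect_equal(GenomicRanges::start(same), c(1, 1000))
  # overlapping peaks collapse to one
  over <- masterConsensus(list(p1, p2))
  expect_equal(length(over), 1)
  expect_equal(GenomicRanges::width(over), 250)
  # disjoint union conserves the count, and the result never overlaps
  uni <- masterConsensus(list(p1, p3))
  expect_equal(length(uni), 2)
  expect_false(is.null(names(uni)))
})

test_that("normalization equalizes reads-in-peaks and conserves the grand total", {
  raw <- cbind(s1 = c(50, 50), s2 = c(100, 200))
  norm <- normalizeCounts(raw)
  # totals 100 and 300 -> scales 0.5 and 1.5
  expect_equal(norm[, "s1"], raw[, "s1"] / 0.5)
  expect_equal(unname(norm[1, "s1"]), 100)
  expect_equal(unname(colSums(norm)), c(200, 200))
  expect_equal(sum(norm), sum(raw))
  # equal totals: identity
  eq <- cbind(a = c(10, 20), b = c(15, 15))
  expect_equal(normalizeCounts(eq), eq)
  expect_error(normalizeCounts(cbind(a = c(0, 0))), "total")
})

test_that("FDR grid endpoints and spacing are geometric and inclusive", {
  counts <- matrix(50, nrow = 4, ncol = 5,
                   dimnames = list(paste0("p", 1:4), NULL))
  si <- data.frame(signal = c("control", "control_low_density",
                              "signalA", "signalB", "both"),
                   dose = c("none", "none", "low", "low", "low"))
  g <- fdrGrid(counts, si)
  expect_equal(length(fcThresholds(g)), 50)
  expect_equal(fcThresholds(g)[1], 1.1)
  expect_equal(fcThresholds(g)[50], 10)
  expect_equal(countThresholds(g)[1], 10)
  expect_equal(countThresholds(g)[50], 237)
  r <- fcThresholds(g)[-1] / fcThresholds(g)[-50]
  expect_equal(max(r) - min(r), 0, tolerance = 1e-9)
})

test_that("the estimated FDR reproduces the printed formula on toy counts", {
  # 2 experimental conditions; in the loosest cell the experimental
  # conditions call 40 peaks total while the two extra controls call 3 and
  # 1 (mean 2): FDR = 2 * 2 / 40 = 0.1
  nPeak <- 60
  ids <- sprintf("p%02d", seq_len(nPeak))
  base <- 50
  mk <- function(v) matrix(rep(v, 3), ncol = 3)
  ctrl <- mk(rep(base, nPeak))
  condA <- rep(base, nPeak); condA[1:25] <- 500
  condB <- rep(base, nPeak); condB[26:40] <- 500
  xlo <- rep(base, nPeak); xlo[41:43] <- 500
  xhi <- rep(base, nPeak); xhi[44] <- 500
  counts <- cbind(ctrl, mk(xlo), mk(xhi), mk(condA), mk(condB))
  rownames(counts) <- ids
  si <- data.frame(
    signal = rep(c("control", "control_low_density",
                   "control_high_density", "signalA", "signalB"), each = 3),
    dose = rep(c("none", "none", "none", "low", "low"), each = 3))
  g <- fdrGrid(counts, si)  # counts enter as already-normalized values
  expect_equal(g@nDiff[1, 1], 40)
  expect_equal(g@nFalsePos[1, 1], 2)
  expect_equal(estimatedFdr(g)[1, 1], 2 * 2 / 40)
  # extra controls identical to reference: FDR 0 everywhere defined
  counts0 <- cbind(ctrl, mk(rep(base, nPeak)), mk(rep(base, nPeak)),
                   mk(condA), mk(condB))
  rownames(counts0) <- ids
  g0 <- fdrGrid(counts0, si)
  fdr0 <- estimatedFdr(g0)
  expect_true(all(fdr0[!is.na(fdr0)] == 0))
})

test_that("pooled calls are monotone: stricter cells are subsets of looser", {
  set.seed(302)
  nPeak <- 300
  counts <- matrix(rpois(nPeak * 15, 60), nrow = nPeak,
                   dimnames = list(sprintf("p%03d", 1:nPeak), NULL))
  counts[1:30, 10:15] <- counts[1:30, 10:15] * 8  # true signal
  si <- data.frame(
    signal = rep(c("control", "control_low_density",
                   "control_high_density", "signalA", "both"), each = 3),
    dose = rep(c("none", "none", "none", "low", "low"), each = 3))
  norm <- normalizeCounts(counts)
  g <- fdrGrid(norm, si)
  strict <- g@calls$fcBin >= 10 & g@calls$countBin >= 10
  loose <- g@calls$fcBin >= 5 & g@calls$countBin >= 5
  expect_true(all(!strict | loose))
  # single qualifying cell returns exactly its calls
  fakeFdr <- matrix(NA_real_, 50, 50)
  fakeFdr[10, 10] <- 0
  g2 <- g; g2@fdr <- fakeFdr
  r <- callDifferentialPeaks(g2, 0.0025)
  manual <- g@calls[!g@calls$isControl & g@calls$fcBin >= 10 &
                      g@calls$countBin >= 10, ]
  expect_setequal(paste(r$calls$peak_id, r$calls$condition),
                  paste(manual$peak_id, manual$condition))
})

test_that("merging is inclusive at the merge distance", {
  mkGr <- function(bStart) {
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1, bStart, 5000),
                                                  width = 150))
    names(gr) <- c("a", "b", "c")
    gr
  }
  counts <- matrix(100, nrow = 3, ncol = 9,
                   dimnames = list(c("a", "b", "c"), NULL))
  counts[, 7:9] <- 400
  si <- data.frame(signal = rep(c("control", "control_low_density",
                                  "both"), each = 3),
                   dose = rep(c("none", "none", "low"), each = 3))
  round1 <- list(peaks = c("a", "b", "c"))
  # gap between a (ends at 150) and b starting at 401 is 250 bp -> merged
  r <- mergeAndRecall(round1, mkGr(401), counts, si)
  expect_equal(length(r$peaks), 2)
  expect_equal(unname(r$counts[1, 1]), 200)  # member counts summed
  # 251 bp apart -> not merged
  r2 <- mergeAndRecall(round1, mkGr(402), counts, si)
  expect_equal(length(r2$peaks), 3)
})

test_that("second round matches a brute-force threshold check", {
  set.seed(303)
  nPeak <- 120
  ids <- sprintf("p%03d", seq_len(nPeak))
  counts <- matrix(rpois(nPeak * 12, 50), nrow = nPeak,
                   dimnames = list(ids, NULL))
  counts[1:15, 7:9] <- counts[1:15, 7:9] * 6
  si <- data.frame(signal = rep(c("control", "control_low_density",
                                  "signalA", "both"), each = 3),
                   dose = rep(c("none", "none", "low", "low"), each = 3))
  norm <- normalizeCounts(counts)
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(seq(1, by = 1000,
                                                    length.out = nPeak),
                                                width = 150))
  names(gr) <- ids
  g <- fdrGrid(norm, si)
  r1 <- callDifferentialPeaks(g, 0.25)  # loose cell threshold for the toy
  r2 <- mergeAndRecall(r1, gr, norm, si)
  # brute force on the merged counts
  lab <- ifelse(si$dose == "none", si$signal,
                paste(si$signal, si$dose, sep = "_"))
  cm <- vapply(unique(lab), function(g2)
    rowMeans(r2$counts[, lab == g2, drop = FALSE]),
    numeric(nrow(r2$counts)))
  ref <- cm[, "control"]
  for (cond in c("signalA_low", "both_low")) {
    m <- cm[, cond]
    fc <- pmax((m + 1) / (ref + 1), (ref + 1) / (m + 1))
    want <- rownames(cm)[fc >= 1.5 & pmax(m, ref) >= 30]
    got <- r2$calls$peak_id[r2$calls$condition == cond]
    expect_setequal(got, want)
  }
})

test_that("pure-null input yields no confident cells or a flagged FDR", {
  set.seed(304)
  nPeak <- 200
  counts <- matrix(rpois(nPeak * 12, 80), nrow = nPeak,
                   dimnames = list(sprintf("p%03d", 1:nPeak), NULL))
  si <- data.frame(signal = rep(c("control", "control_low_density",
                                  "control_high_density", "both"),
                                each = 3),
                   dose = rep(c("none", "none", "none", "low"), each = 3))
  g <- fdrGrid(normalizeCounts(counts), si)
  r1 <- suppressWarnings(callDifferentialPeaks(g, 0.0025))
  # every call would be a false positive by construction; the caller must
  # not produce calls in bulk (a handful of corner-cell flukes can slip
  # through because cells are selected for zero control calls)
  expect_lt(length(r1$peaks), 0.05 * nPeak)
})
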