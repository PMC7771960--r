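# Peak-gene links, exclusivity, motif analyses, shuffle null, Welch test.

mkPeaks <- function(mids, ids = sprintf("p%02d", seq_along(mids))) {
  p <- GenomicRanges::GRanges("chrS", IRanges::IRanges(mids - 74,
                                                       width = 150))
  names(p) <- ids
  p
}

test_that("peak-gene links agree with brute force on a random layout", {
  set.seed(501)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60), chrom = "chrS",
                      tss = sample.int(3e6, 60), strand = "+")
  mids <- sample.int(3e6, 500)
  peaks <- mkPeaks(mids, sprintf("p%03d", 1:500))
  links <- linkPeaksToGenes(peaks, genes, 100000)
  brute <- sum(vapply(genes$tss + 1, function(t)
    sum(abs(mids - t) <= 100000), numeric(1)))
  expect_equal(nrow(links), brute)
  expect_true(all(links$distance <= 100000))
})

test_that("exclusivity labels use the inclusive 90% major fraction", {
  r <- data.frame(feature_id = c("p1", "p2", "p3", "p4"), dose = "medium",
                  dA = c(9, 8, 0, 0), dB = c(1, 2, 5, 0))
  lab <- labelExclusivePeaks(r)
  expect_equal(as.character(lab$label), c("A_dominant", "shared",
                                          "B_dominant", NA))
  expect_equal(lab$majorFraction, c(0.9, 0.8, 1, NA))
})

test_that("dual-dominant gene fraction counts genes with both peak types", {
  links <- data.frame(gene_id = c("g1", "g1", "g2", "g2"),
                      peak_id = c("p1", "p3", "p1", "p2"),
                      distance = 0, withinWindow = TRUE)
  labels <- data.frame(feature_id = c("p1", "p2", "p3"), dose = "medium",
                       majorFraction = 1,
                       label = c("A_dominant", "A_dominant", "B_dominant"))
  gc <- data.frame(feature_id = c("g1", "g2"), category = "additive")
  out <- dualDominantGeneFraction(links, labels, gc, nBoot = 100, seed = 1)
  expect_equal(out$fraction, 0.5)  # g1 yes, g2 has only A-dominant peaks
})

test_that("motif group counts collapse by maximum over members", {
  m <- matrix(0, 1, 4, dimnames = list("p1", c("JUN", "FOS", "JDP2",
                                               "BACH1")))
  m["p1", ] <- c(3, 2, 2, 1)
  gm <- collapseMotifGroups(m)
  expect_equal(unname(gm["p1", "AP-1"]), 3)
  # density: 4 collapsed matches in a 300-bp peak = 2 per 150 bp
  p <- GenomicRanges::GRanges("chrS", IRanges::IRanges(1, width = 300))
  names(p) <- "p1"
  m2 <- matrix(4, 1, 1, dimnames = list("p1", "CTCF"))
  cat1 <- data.frame(feature_id = "p1", category = "additive")
  dens <- motifDensity(p, m2, cat1, nBoot = 10, seed = 1)
  expect_equal(dens$meanDensity[dens$group == "CTCF"], 2)
})

test_that("identical match matrices give identical class densities", {
  peaks <- mkPeaks(c(1000, 3000, 5000, 7000) * 10)
  set.seed(502)
  m <- matrix(rpois(4 * 3, 1), 4, 3,
              dimnames = list(names(peaks), c("CTCF", "JUN", "RARA")))
  cats <- data.frame(feature_id = names(peaks),
                     category = rep(c("additive", "super_additive"),
                                    each = 2))
  # both classes see the same per-peak densities if rows are equal
  m[] <- rep(m[1, ], each = 4)
  dens <- motifDensity(peaks, m, cats, nBoot = 10, seed = 2)
  for (g in unique(dens$group)) {
    v <- dens$meanDensity[dens$group == g]
    expect_equal(v[1], v[2])
  }
})

test_that("shuffle null conserves per-peak totals and detects clustering", {
  set.seed(503)
  n <- 120
  peaks <- sprintf("p%03d", 1:n)
  groups <- motifGroups()
  # clustered construction: RA-dominant matches and TGFB-dominant matches
  # concentrated in disjoint peak subsets
  m <- matrix(0, n, 2, dimnames = list(peaks, c("RARA", "SMAD3")))
  m[1:40, "RARA"] <- rpois(40, 3) + 1
  m[61:100, "SMAD3"] <- rpois(40, 3) + 1
  cats <- data.frame(feature_id = peaks, category = "additive")
  out <- dualMotifShuffleNull(cats, m, groups, nShuffles = 200, seed = 3)
  expect_true(out$totalsConserved)
  expect_equal(out$observed, 0)  # disjoint by construction
  expect_gt(out$nullMean, out$observed)
  expect_lt(out$pLower, 0.05)
  # all peaks carrying exactly one match can never dual-match
  m1 <- matrix(0, n, 2, dimnames = list(peaks, c("RARA", "SMAD3")))
  m1[, "RARA"] <- 1
  out1 <- dualMotifShuffleNull(cats, m1, groups, nShuffles = 50, seed = 4)
  expect_equal(out1$observed, 0)
  expect_equal(out1$nullMean, 0)
})

test_that("enrichment score is the fractional change at motif-bearing peaks", {
  n <- 10
  peaks <- sprintf("p%02d", 1:n)
  m <- matrix(0, n, 2, dimnames = list(peaks, c("RARA", "CTCF")))
  m[1:4, "RARA"] <- 1
  norm <- matrix(100, n, 6, dimnames = list(peaks, NULL))
  si <- data.frame(signal = rep(c("control", "signalA"), each = 3),
                   dose = rep(c("none", "low"), each = 3))
  norm[1:4, 4:6] <- 119
  sc <- motifEnrichmentScore(m, norm, si, "signalA")
  expect_equal(sc$score[sc$motif == "RARA"], 0.19)
  expect_true(is.na(sc$score[sc$motif == "CTCF"]))
  # condition identical to reference: score 0
  norm0 <- matrix(100, n, 6, dimnames = list(peaks, NULL))
  sc0 <- motifEnrichmentScore(m, norm0, si, "signalA")
  expect_equal(sc0$score[sc0$motif == "RARA"], 0)
})

test_that("motif-conditional d finds planted super-additive carriers", {
  set.seed(504)
  n <- 200
  peaks <- sprintf("p%03d", 1:n)
  m <- matrix(0, n, 1, dimnames = list(peaks, "SMAD3"))
  carriers <- 1:80
  m[carriers, 1] <- 1
  d <- rnorm(n, 0, 0.05)
  d[carriers] <- d[carriers] + 0.5
  recs <- data.frame(feature_id = peaks, d = d)
  out <- motifConditionalD(m, recs, "SMAD3", nBoot = 200, seed = 5)
  expect_equal(out$median, 0.5, tolerance = 0.05)
  expect_true(out$ciLo <= out$median && out$median <= out$ciHi)
  # motif carried by every peak: median equals the global median
  mAll <- matrix(1, n, 1, dimnames = list(peaks, "SMAD3"))
  outAll <- motifConditionalD(mAll, recs, "SMAD3", nBoot = 10, seed = 6)
  expect_equal(outAll$median, median(d))
})

test_that("Welch test matches an independent oracle and handles edge cases", {
  expect_equal(welchTest(c(1, 2, 3), c(1, 2, 3)), 1)
  x <- c(5.1, 4.9, 5.0, 5.2); y <- c(6.0, 6.1, 5.9)
  expect_equal(welchTest(x, y), welchOracle(x, y), tolerance = 1e-10)
  set.seed(505)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), 0.5, 2)
    expect_equal(welchTest(a, b), welchOracle(a, b), tolerance = 1e-10)
  }
  expect_lt(welchTest(c(1, 2, 3), c(11, 12, 13) + rnorm(3, 0, 1e-3)),
            0.01)
  expect_equal(welchTest(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_error(welchTest(1, c(1, 2)), "at least 2")
})

test_that("bootstrap CIs contain the estimate and shrink with variance", {
  links <- data.frame(gene_id = rep(sprintf("g%02d", 1:30), each = 2),
                      peak_id = rep(sprintf("p%02d", 1:30), 2),
                      distance = 0, withinWindow = TRUE)
  pc <- data.frame(feature_id = sprintf("p%02d", 1:30),
                   category = "additive")
  gc <- data.frame(feature_id = sprintf("g%02d", 1:30),
                   category = "multiplicative")
  out <- peakClassCountsByGeneCategory(links, pc, gc, nBoot = 500,
                                       seed = 7)
  # every gene has exactly 2 additive peaks: zero-width CI at 2
  expect_equal(out$meanCount, 2)
  expect_equal(out$ciLo, 2)
  expect_equal(out$ciHi, 2)
})
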