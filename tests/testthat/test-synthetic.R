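# Ground-truth generators.

test_that("zero noise reproduces the condition means exactly", {
  cfg <- synthConfig(nGenes = 20, cvRange = c(0, 0), seed = 7)
  g <- generateExpressionData(cfg)
  m <- SummarizedExperiment::assay(g$se)
  cd <- SummarizedExperiment::colData(g$se)
  ctrl <- m[, cd$signal == "control", drop = FALSE]
  expect_equal(unname(ctrl[, 1]), g$truth$truth_x0)
  expect_equal(ctrl[, 1], ctrl[, 2])  # replicates identical
  both <- m[, cd$signal == "both" & cd$dose == "medium", drop = FALSE]
  expect_equal(unname(both[, 1]),
               g$truth$truth_x0 + g$truth$truth_dA + g$truth$truth_dB,
               tolerance = 1e-12)
})

test_that("cTrue = 0 cohorts are additive on average", {
  cfg <- synthConfig(nGenes = 300, cTrue = 0, seed = 8)
  g <- generateExpressionData(cfg)
  resp <- responseEstimates(g$se)
  med <- resp[resp$dose == "medium", ]
  # mean combined response tracks the additive prediction within MC error
  relDiff <- (med$xAB - med$predAdd) / med$predAdd
  expect_lt(abs(mean(relDiff)), 0.02)
})

test_that("downstream estimation recovers cTrue and the CVs", {
  # identical ground truth (same seed), increasing replicate count
  estFor <- function(nRep) {
    cfg <- synthConfig(nGenes = 400, nReplicates = nRep,
                       cTrue = function(n) rnorm(n, 0.5, 0.25), seed = 9)
    g <- generateExpressionData(cfg)
    resp <- responseEstimates(g$se)
    med <- resp[resp$dose == "medium", ]
    truth <- g$truth[match(med$feature_id, g$truth$gene_id), ]
    list(cHat = computeC(med$x0, med$dA, med$dB, med$xAB),
         resp = med, truth = truth)
  }
  e5 <- estFor(5); e50 <- estFor(50)
  expect_equal(e5$truth$truth_c, e50$truth$truth_c)
  # truth-defined reliable subset (large interaction scale)
  scl <- with(e50$truth, truth_dA * truth_dB / truth_x0)
  rel <- scl >= 2 & scl >= e50$truth$truth_x0
  rmse <- function(e) sqrt(mean((e$cHat[rel] - e$truth$truth_c[rel])^2))
  # estimator noise shrinks as replicates grow, bias washes out
  expect_lt(rmse(e50), rmse(e5))
  expect_lt(abs(mean(e50$cHat[rel] - e50$truth$truth_c[rel])), 0.05)
  expect_lt(abs(mean(e50$resp$cvAB - e50$truth$truth_cv_both)), 0.01)
})

test_that("negative implied combined means are rejected with a warning", {
  cfg <- synthConfig(nGenes = 30,
                     cTrue = function(n) rep(c(-80, 0), length.out = n),
                     seed = 10)
  expect_warning(g <- generateExpressionData(cfg), "rejected")
  expect_lt(nrow(g$truth), 30)
  expect_true(all(g$truth$truth_c == 0))
  cfgAll <- synthConfig(nGenes = 5, cTrue = -80, seed = 10)
  expect_error(generateExpressionData(cfgAll), "every gene")
})

test_that("dTrue = 0 peaks have additive combined means", {
  cfg <- synthConfig(nPeaks = 200, nGenes = 50, cvRange = c(0, 0),
                     dTrue = 0, seed = 11)
  pk <- generatePeakData(cfg)
  resp <- responseEstimates(pk$se)
  d <- computeD(resp$predAdd, resp$xAB)
  expect_equal(max(abs(d)), 0, tolerance = 1e-9)
  # and dTrue = 0.5 shifts them by construction
  cfg2 <- synthConfig(nPeaks = 50, nGenes = 50, cvRange = c(0, 0),
                      dTrue = 0.5, seed = 12)
  pk2 <- generatePeakData(cfg2)
  resp2 <- responseEstimates(pk2$se)
  expect_equal(unname(computeD(resp2$predAdd, resp2$xAB)),
               rep(0.5, nrow(resp2)), tolerance = 1e-9)
})

test_that("peak dataset carries pure-null extra controls and summits", {
  cfg <- synthConfig(nPeaks = 100, nGenes = 20, seed = 13,
                     summitDropout = 0)
  pk <- generatePeakData(cfg)
  cd <- SummarizedExperiment::colData(pk$se)
  expect_true(all(c("control_low_density", "control_high_density") %in%
                    cd$signal))
  expect_length(pk$summits, 3)
  # zero dropout: every replicate has one summit per true peak
  expect_equal(unique(vapply(pk$summits, length, integer(1))), 100)
  # majority rule recovers every true peak
  cons <- consensusPeaks(pk$summits)
  expect_equal(length(cons), 100)
  hits <- GenomicRanges::findOverlaps(cons, pk$peaks)
  expect_equal(length(unique(S4Vectors::subjectHits(hits))), 100)
})

test_that("genome layout places window membership by construction", {
  genes <- data.frame(gene_id = "g1", chrom = "chrS", tss = 1000000,
                      strand = "+")
  mkPeak <- function(mid) {
    p <- GenomicRanges::GRanges("chrS",
                                IRanges::IRanges(mid - 74, width = 150))
    names(p) <- "p1"
    p
  }
  # midpoint of [s, s+149] (1-based) is s + 74
  near <- linkPeaksToGenes(mkPeak(1000000 + 1 + 99999), genes)
  far <- linkPeaksToGenes(mkPeak(1000000 + 1 + 100001), genes)
  expect_equal(nrow(near), 1)
  expect_equal(near$distance, 99999)
  expect_equal(nrow(far), 0)
})

test_that("random layouts agree with a brute-force window check", {
  cfg <- synthConfig(nGenes = 40, nPeaks = 500, genomeLength = 5e6,
                     peakPlacement = "uniform", seed = 14)
  lay <- generateGenomeLayout(cfg)
  links <- linkPeaksToGenes(lay$peaks, lay$genes, windowBp = 100000)
  mids <- GenomicRanges::start(lay$peaks) +
    floor((GenomicRanges::width(lay$peaks) - 1) / 2)
  brute <- 0
  for (i in seq_len(nrow(lay$genes))) {
    tss1 <- lay$genes$tss[i] + 1
    brute <- brute + sum(abs(mids - tss1) <= 100000)
  }
  expect_equal(nrow(links), brute)
  # peaks never overlap
  expect_equal(length(GenomicRanges::reduce(lay$peaks, min.gapwidth = 0L)),
               length(lay$peaks))
})

test_that("motif matrix is Poisson without clustering, overdispersed with", {
  cfg <- synthConfig(nPeaks = 2000, nGenes = 50, motifClustering = 0,
                     motifMeanPer150 = 0.5, seed = 15)
  lay <- generateGenomeLayout(cfg)
  m <- generateMotifMatrix(lay$peaks, cfg)
  disp <- apply(m, 2, function(v) var(v) / mean(v))
  expect_true(all(disp > 0.8 & disp < 1.25))
  cfg2 <- synthConfig(nPeaks = 2000, nGenes = 50, motifClustering = 2,
                      motifMeanPer150 = 0.5, seed = 16)
  m2 <- generateMotifMatrix(lay$peaks, cfg2)
  disp2 <- apply(m2, 2, function(v) var(v) / mean(v))
  expect_gt(median(disp2), 1.5)
  # unknown motif names are rejected
  cfg3 <- synthConfig(motifRates = c(NOSUCH = 1), seed = 17)
  expect_error(generateMotifMatrix(lay$peaks, cfg3), "unknown motif")
})
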