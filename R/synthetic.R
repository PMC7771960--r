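## Synthetic data with known ground truth.
##
## The generator emulates the statistical structure the analysis assumes:
## per-feature folded-Gaussian replicate noise with a dose-shared CV, known
## baseline/effect/c (or d) parameters per feature, extra density controls
## drawn from the identical control distribution (pure null), a toy genome
## layout of TSSs and non-overlapping peaks, and clustered motif matches.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a cohort of upregulated features: gene baselines
#' log-uniform in 1-500 TPM with single-signal fold changes log-uniform in
#' 1.5-4; peak baselines log-uniform in 20-500 normalized fragment counts
#' with fold changes log-uniform in 1.25-3; per-feature per-signal CVs
#' uniform in 0.05-0.3; three replicates and three doses whose effects
#' scale by 0.5/1/1.5.
#'
#' @param nGenes,nPeaks Feature counts.
#' @param nReplicates Replicates per condition and dose (default 3).
#' @param doses Dose names (default low/medium/high).
#' @param doseFactors Multipliers applied to the base effects per dose.
#' @param cvRange Uniform range for the true CVs.
#' @param baselineRange,foldRange Log-uniform ranges for gene baselines
#'   (TPM) and per-signal fold changes.
#' @param peakBaselineRange,peakFoldRange Same for peaks (normalized
#'   fragment counts).
#' @param cTrue,dTrue Ground-truth interaction values: scalar, per-feature
#'   vector, or `function(n)` returning `n` draws.
#' @param extraControls Add the two extra density-control sample groups to
#'   the peak dataset (default `TRUE`).
#' @param summitDropout Probability that a replicate misses a true peak's
#'   summit (default 0).
#' @param summitJitter Max absolute uniform jitter of summit positions in
#'   bp (default 10).
#' @param genomeLength Toy chromosome length (default 2e7 bp).
#' @param peakWidth True peak width (default 150 bp).
#' @param peakPlacement `"near_genes"` (distances drawn from
#'   `peakDistanceRange` around a random TSS) or `"uniform"`.
#' @param peakDistanceRange Signed distance range for `"near_genes"`
#'   placement (default +/-150 kb, spanning both sides of the 100 kb
#'   window).
#' @param motifMeanPer150 Mean motif matches per 150 bp per motif (default
#'   0.1).
#' @param motifRates Optional named per-motif rates overriding
#'   `motifMeanPer150`; unknown motif names are an error at generation
#'   time.
#' @param motifClustering Overdispersion of motif matches across peaks; 0
#'   gives Poisson counts, larger values concentrate a motif's matches in
#'   fewer peaks (negative-binomial with size `1/clustering`).
#' @param seed Optional integer seed used by the generators.
#' @return A validated list of class `SynthConfig`.
#' @export
synthConfig <- function(nGenes = 1000, nPeaks = 1000, nReplicates = 3,
                        doses = c("low", "medium", "high"),
                        doseFactors = c(low = 0.5, medium = 1, high = 1.5),
                        cvRange = c(0.05, 0.3),
                        baselineRange = c(1, 500), foldRange = c(1.5, 4),
                        peakBaselineRange = c(20, 500),
                        peakFoldRange = c(1.25, 3),
                        cTrue = 0, dTrue = 0, extraControls = TRUE,
                        summitDropout = 0, summitJitter = 10,
                        genomeLength = 2e7, peakWidth = 150,
                        peakPlacement = c("near_genes", "uniform"),
                        peakDistanceRange = c(-150000, 150000),
                        motifMeanPer150 = 0.1, motifRates = NULL,
                        motifClustering = 0, seed = NULL) {
  cfg <- list(nGenes = nGenes, nPeaks = nPeaks, nReplicates = nReplicates,
              doses = doses, doseFactors = doseFactors, cvRange = cvRange,
              baselineRange = baselineRange, foldRange = foldRange,
              peakBaselineRange = peakBaselineRange,
              peakFoldRange = peakFoldRange, cTrue = cTrue, dTrue = dTrue,
              extraControls = extraControls, summitDropout = summitDropout,
              summitJitter = summitJitter, genomeLength = genomeLength,
              peakWidth = peakWidth,
              peakPlacement = match.arg(peakPlacement),
              peakDistanceRange = peakDistanceRange,
              motifMeanPer150 = motifMeanPer150, motifRates = motifRates,
              motifClustering = motifClustering, seed = seed)
  rng <- function(r, name) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stop("degenerate range for ", name)
  }
  stopifnot(nGenes >= 1, nPeaks >= 1, nReplicates >= 2,
            length(doses) >= 1, length(doseFactors) == length(doses),
            all(doseFactors > 0), summitDropout >= 0, summitDropout <= 1,
            motifClustering >= 0)
  rng(cvRange, "cvRange"); rng(baselineRange, "baselineRange")
  rng(foldRange, "foldRange"); rng(peakBaselineRange, "peakBaselineRange")
  rng(peakFoldRange, "peakFoldRange")
  if (any(cvRange < 0)) stop("cvRange must be non-negative")
  names(cfg$doseFactors) <- doses
  class(cfg) <- "SynthConfig"
  cfg
}

runifLog <- function(n, range) {
  if (range[1] == range[2]) return(rep(range[1], n))
  exp(runif(n, log(range[1]), log(range[2])))
}

resolveTruthParam <- function(p, n) {
  if (is.function(p)) p(n)
  else if (length(p) == 1) rep(p, n)
  else if (length(p) == n) p
  else stop("ground-truth parameter has length ", length(p),
            " but ", n, " features were requested")
}

## replicate draws for one feature set under the folded-Gaussian model
drawReplicates <- function(mu, cv, nRep) {
  n <- length(mu)
  matrix(abs(rnorm(n * nRep, mean = rep(mu, nRep),
                   sd = rep(pmax(mu * cv, 0), nRep))),
         nrow = n, ncol = nRep)
}

## shared machinery for the expression and peak generators
simulateFeatureTable <- function(ids, x0, dA1, dB1, inter, cvs, cfg,
                                 extraControls, combinedMean) {
  n <- length(ids)
  mats <- list(); sig <- character(); dos <- character(); rep_ <- integer()
  add <- function(m, s, d) {
    for (r in seq_len(ncol(m))) {
      mats[[length(mats) + 1]] <<- m[, r]
      sig <<- c(sig, s); dos <<- c(dos, d)
      rep_ <<- c(rep_, r)
    }
  }
  add(drawReplicates(x0, cvs$control, cfg$nReplicates), "control", "none")
  if (extraControls) {
    add(drawReplicates(x0, cvs$control, cfg$nReplicates),
        "control_low_density", "none")
    add(drawReplicates(x0, cvs$control, cfg$nReplicates),
        "control_high_density", "none")
  }
  for (d in cfg$doses) {
    f <- cfg$doseFactors[[d]]
    muA <- x0 + dA1 * f
    muB <- x0 + dB1 * f
    muAB <- combinedMean(x0, dA1 * f, dB1 * f, inter)
    add(drawReplicates(muA, cvs$signalA, cfg$nReplicates), "signalA", d)
    add(drawReplicates(muB, cvs$signalB, cfg$nReplicates), "signalB", d)
    add(drawReplicates(muAB, cvs$both, cfg$nReplicates), "both", d)
  }
  values <- do.call(cbind, mats)
  rownames(values) <- ids
  list(values = values, signal = sig, dose = dos, replicate = rep_)
}

#' Generate a synthetic expression dataset
#'
#' Per gene, condition and dose, draws replicates from the folded Gaussian
#' `|Normal(mu, (mu cv)^2)|` with `mu_control = x0`,
#' `mu_A = x0 + dA`, `mu_B = x0 + dB` and
#' `mu_both = x0 + dA + dB + c dA dB / x0`. Genes whose implied combined
#' mean would be negative (extreme negative `cTrue`) are rejected with a
#' warning.
#'
#' @param cfg A [synthConfig()].
#' @return List: `se` (a [SignalExperiment] of TPM values), `truth`
#'   (data.frame of `truth_`-prefixed ground-truth parameters), `de`
#'   (surrogate differential-expression table for the combined treatment:
#'   `gene_id`, `dose`, `log2fc`, `padj`, computed from the true means).
#' @export
generateExpressionData <- function(cfg = synthConfig()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$nGenes
  ids <- sprintf("gene_%05d", seq_len(n))
  x0 <- runifLog(n, cfg$baselineRange)
  dA1 <- x0 * (runifLog(n, cfg$foldRange) - 1)
  dB1 <- x0 * (runifLog(n, cfg$foldRange) - 1)
  cTrue <- resolveTruthParam(cfg$cTrue, n)
  cvs <- list(control = runif(n, cfg$cvRange[1], cfg$cvRange[2]),
              signalA = runif(n, cfg$cvRange[1], cfg$cvRange[2]),
              signalB = runif(n, cfg$cvRange[1], cfg$cvRange[2]),
              both = runif(n, cfg$cvRange[1], cfg$cvRange[2]))
  ## reject genes whose combined mean would go negative at any dose
  bad <- rep(FALSE, n)
  for (f in cfg$doseFactors)
    bad <- bad | (x0 + (dA1 + dB1) * f + cTrue * dA1 * dB1 * f^2 / x0) < 0
  if (all(bad))
    stop("every gene was rejected (negative implied combined means); ",
         "cTrue is too extreme for the requested effect sizes")
  if (any(bad)) {
    warning(sum(bad), " gene(s) rejected: negative implied combined mean")
    keep <- !bad
    ids <- ids[keep]; x0 <- x0[keep]; dA1 <- dA1[keep]; dB1 <- dB1[keep]
    cTrue <- cTrue[keep]
    cvs <- lapply(cvs, function(v) v[keep])
    n <- sum(keep)
  }
  tab <- simulateFeatureTable(
    ids, x0, dA1, dB1, cTrue, cvs, cfg, extraControls = FALSE,
    combinedMean = function(x0, dA, dB, c) x0 + dA + dB + c * dA * dB / x0)
  se <- SignalExperiment(tab$values, tab$signal, tab$dose, tab$replicate)
  truth <- data.frame(gene_id = ids, truth_x0 = x0, truth_dA = dA1,
                      truth_dB = dB1, truth_c = cTrue,
                      truth_cv_control = cvs$control,
                      truth_cv_signalA = cvs$signalA,
                      truth_cv_signalB = cvs$signalB,
                      truth_cv_both = cvs$both,
                      stringsAsFactors = FALSE)
  de <- do.call(rbind, lapply(cfg$doses, function(d) {
    f <- cfg$doseFactors[[d]]
    muAB <- x0 + (dA1 + dB1) * f + cTrue * dA1 * dB1 * f^2 / x0
    lfc <- log2(muAB / x0)
    data.frame(gene_id = ids, dose = d, log2fc = lfc,
               padj = ifelse(abs(lfc) > 0.1, 1e-4, 0.5),
               stringsAsFactors = FALSE)
  }))
  list(se = se, truth = truth, de = de)
}

#' Generate a toy genome layout
#'
#' Places gene TSSs and non-overlapping peaks on one toy chromosome so
#' that window membership is known by construction.
#'
#' @param cfg A [synthConfig()].
#' @return List: `genes` (data.frame `gene_id`, `chrom`, `tss` 0-based,
#'   `strand`) and `peaks` (named `GRanges`).
#' @export
generateGenomeLayout <- function(cfg = synthConfig()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- cfg$genomeLength
  w <- cfg$peakWidth
  if (cfg$nPeaks * w * 4 > L || cfg$nGenes * 10 > L)
    stop("genome too small for the requested number of features")
  genes <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(cfg$nGenes)), chrom = "chrS",
    tss = sort(sample.int(L - 1, cfg$nGenes)),
    strand = sample(c("+", "-"), cfg$nGenes, replace = TRUE),
    stringsAsFactors = FALSE)
  drawMid <- function(k) {
    if (cfg$peakPlacement == "near_genes") {
      anchor <- genes$tss[sample.int(nrow(genes), k, replace = TRUE)]
      off <- round(runif(k, cfg$peakDistanceRange[1],
                         cfg$peakDistanceRange[2]))
      pmin(pmax(anchor + off, w), L - w)
    } else {
      round(runif(k, w, L - w))
    }
  }
  mids <- drawMid(cfg$nPeaks)
  for (i in seq_len(200)) {
    o <- order(mids)
    gap <- diff(mids[o])
    clash <- o[which(gap < w) + 1]
    if (length(clash) == 0) break
    mids[clash] <- drawMid(length(clash))
    if (i == 200) stop("genome too small: could not place non-overlapping peaks")
  }
  mids <- sort(mids)
  peaks <- GRanges("chrS", IRanges(start = mids - floor(w / 2), width = w))
  names(peaks) <- sprintf("peak_%05d", seq_along(peaks))
  list(genes = genes, peaks = peaks)
}

#' Generate a synthetic peak dataset
#'
#' Like [generateExpressionData()] but for ATAC-seq peak integrals: the
#' combined-treatment mean is `(x0 + dA + dB) * (1 + d)`, two extra
#' control sample groups are drawn from the identical control distribution
#' (pure null), and per-replicate summit files place one summit per true
#' peak with configurable dropout.
#'
#' @param cfg A [synthConfig()].
#' @param layout Optional output of [generateGenomeLayout()]; generated
#'   (with the config seed) when missing.
#' @return List: `se` ([SignalExperiment] with peak `rowRanges`),
#'   `counts` (the raw matrix), `summits` (list of per-replicate
#'   `GRanges`), `peaks` (`GRanges`), `truth` (data.frame).
#' @export
generatePeakData <- function(cfg = synthConfig(), layout = NULL) {
  if (is.null(layout)) layout <- generateGenomeLayout(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  peaks <- layout$peaks
  n <- length(peaks)
  ids <- names(peaks)
  x0 <- runifLog(n, cfg$peakBaselineRange)
  dA1 <- x0 * (runifLog(n, cfg$peakFoldRange) - 1)
  dB1 <- x0 * (runifLog(n, cfg$peakFoldRange) - 1)
  dTrue <- resolveTruthParam(cfg$dTrue, n)
  cvs <- list(control = runif(n, cfg$cvRange[1], cfg$cvRange[2]),
              signalA = runif(n, cfg$cvRange[1], cfg$cvRange[2]),
              signalB = runif(n, cfg$cvRange[1], cfg$cvRange[2]),
              both = runif(n, cfg$cvRange[1], cfg$cvRange[2]))
  tab <- simulateFeatureTable(
    ids, x0, dA1, dB1, dTrue, cvs, cfg, extraControls = cfg$extraControls,
    combinedMean = function(x0, dA, dB, d) (x0 + dA + dB) * (1 + d))
  se <- SignalExperiment(tab$values, tab$signal, tab$dose, tab$replicate,
                         rowRanges = peaks)
  summitPos <- start(peaks) + floor(cfg$peakWidth / 2)
  summits <- lapply(seq_len(cfg$nReplicates), function(r) {
    keep <- runif(n) >= cfg$summitDropout
    jit <- round(runif(sum(keep), -cfg$summitJitter, cfg$summitJitter))
    GRanges("chrS", IRanges(summitPos[keep] + jit, width = 1))
  })
  truth <- data.frame(peak_id = ids,
                      chrom = as.character(seqnames(peaks)),
                      start = start(peaks) - 1L, end = end(peaks),
                      truth_x0 = x0, truth_dA = dA1, truth_dB = dB1,
                      truth_d = dTrue,
                      truth_cv_control = cvs$control,
                      truth_cv_both = cvs$both,
                      stringsAsFactors = FALSE)
  list(se = se, counts = assay(se), summits = summits, peaks = peaks,
       truth = truth)
}

#' Generate a synthetic motif match matrix
#'
#' Per-peak match counts for the named motifs. Without clustering each
#' motif's counts are Poisson across peaks (rate proportional to peak
#' width); positive clustering concentrates a motif's matches in fewer
#' peaks via a negative-binomial with the same mean, emulating the
#' clustering of binding sites for the same factor.
#'
#' @param peaks Named `GRanges`.
#' @param cfg A [synthConfig()]; `motifRates` entries must name motifs in
#'   `groups`.
#' @param groups Motif group table (default [motifGroups()]).
#' @return Integer matrix, peaks x motifs.
#' @export
generateMotifMatrix <- function(peaks, cfg = synthConfig(),
                                groups = motifGroups()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 2L)
  motifs <- groups$motif
  rates <- setNames(rep(cfg$motifMeanPer150, length(motifs)), motifs)
  if (!is.null(cfg$motifRates)) {
    unknown <- setdiff(names(cfg$motifRates), motifs)
    if (length(unknown) > 0)
      stop("unknown motif name(s) in motifRates: ",
           paste(unknown, collapse = ", "))
    rates[names(cfg$motifRates)] <- cfg$motifRates
  }
  wUnits <- width(peaks) / 150
  n <- length(peaks)
  out <- vapply(motifs, function(m) {
    mu <- rates[[m]] * wUnits
    if (cfg$motifClustering == 0) as.numeric(rpois(n, mu))
    else rnbinom(n, size = 1 / cfg$motifClustering, mu = mu)
  }, numeric(n))
  dimnames(out) <- list(names(peaks), motifs)
  out
}
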