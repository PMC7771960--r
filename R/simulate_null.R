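## Monte Carlo null distributions for c and d values.
##
## New replicate sets are drawn from folded Gaussians (absolute value of a
## Gaussian draw, avoiding negative expression or fragment counts) with the
## fitted per-condition parameters, except that the combined-treatment mean
## is replaced by a perfectly additive or perfectly multiplicative
## prediction. Means of the simulated replicates are then pushed through the
## same c/d computation as the real data.

rfoldnorm <- function(n, mean, sd) abs(rnorm(n, mean, sd))

#' Simulate c (or d) values under an additive/multiplicative/mixture null
#'
#' For every valid (feature, dose) response estimate, draws `nReplicates`
#' folded-Gaussian observations per condition (control, signal A, signal B,
#' combined) with standard deviation `mean * CV(signal)`, setting the
#' combined-treatment mean to the additive prediction, the multiplicative
#' prediction, or per-feature to one of the two in mixture mode; averages
#' the replicates; and computes the statistic from the simulated means.
#'
#' @param responses Output of [responseEstimates()] (carries the per-signal
#'   CVs).
#' @param mode `"additive"`, `"multiplicative"` or `"mixture"`.
#' @param stat `"c"` (default, 250 simulations per feature) or `"d"`
#'   (default 10 simulations).
#' @param nSims Simulations per (feature, dose).
#' @param nReplicates Replicates per simulated condition (default 3).
#' @param mixtureProbAdd For mixture mode: named numeric of per-dose
#'   probabilities of assigning a feature additive rather than
#'   multiplicative behaviour (see [mixtureWeights()]); a single unnamed
#'   number applies to all doses.
#' @param seed Optional integer seed.
#' @return data.frame `feature_id`, `dose`, `sim`, `value`,
#'   `assigned_mode`. Features lacking a valid estimate are skipped; the
#'   number skipped is reported in `attr(, "nSkipped")`.
#' @export
simulateNull <- function(responses,
                         mode = c("additive", "multiplicative", "mixture"),
                         stat = c("c", "d"),
                         nSims = NULL, nReplicates = 3,
                         mixtureProbAdd = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stat <- match.arg(stat)
  if (is.null(nSims)) nSims <- if (stat == "c") 250L else 10L
  if (!is.null(seed)) set.seed(seed)
  r <- responses[responses$valid &
                   is.finite(responses$predAdd) &
                   is.finite(responses$predMult), , drop = FALSE]
  nSkipped <- nrow(responses) - nrow(r)
  n <- nrow(r)
  if (n == 0) stop("no valid response estimates to simulate from")

  if (mode == "mixture") {
    if (is.null(mixtureProbAdd))
      stop("mixture mode needs mixtureProbAdd (see mixtureWeights())")
    p <- if (is.null(names(mixtureProbAdd))) {
      rep(mixtureProbAdd[1], n)
    } else {
      as.numeric(mixtureProbAdd[r$dose])
    }
    if (any(is.na(p))) stop("mixtureProbAdd lacks a probability for a dose")
    assigned <- ifelse(runif(n) < p, "additive", "multiplicative")
  } else {
    assigned <- rep(mode, n)
  }
  muAB <- ifelse(assigned == "additive", r$predAdd, r$predMult)

  simMeans <- function(mu, cv) {
    ## (n features x nSims) simulated replicate means, column-major layout
    ## feature-fastest so row i of the result is feature i %% n
    m <- rep(mu, times = nSims)
    s <- rep(mu * cv, times = nSims)
    draws <- matrix(rfoldnorm(n * nSims * nReplicates,
                              rep(m, times = nReplicates),
                              rep(pmax(s, 0), times = nReplicates)),
                    ncol = nReplicates)
    rowMeans(draws)
  }
  m0 <- simMeans(r$x0, r$cv0)
  mA <- simMeans(r$x0 + r$dA, r$cvA)
  mB <- simMeans(r$x0 + r$dB, r$cvB)
  mAB <- simMeans(muAB, r$cvAB)

  value <- if (stat == "c") {
    computeC(m0, mA - m0, mB - m0, mAB)
  } else {
    computeD(mA + mB - m0, mAB)
  }
  out <- data.frame(feature_id = rep(r$feature_id, times = nSims),
                    dose = rep(r$dose, times = nSims),
                    sim = rep(seq_len(nSims), each = n),
                    value = value,
                    assigned_mode = rep(assigned, times = nSims),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "nSkipped") <- nSkipped
  out
}

#' Mixture weights from observed categorical classifications
#'
#' Per dose, the probability of assigning a simulated feature additive
#' behaviour is the observed frequency of additive classifications
#' renormalized over the additive and multiplicative categories only.
#'
#' @param classified Output of [classifyGeneResponses()].
#' @return Named numeric vector, one probability per dose.
#' @export
mixtureWeights <- function(classified) {
  doses <- unique(classified$dose)
  vapply(setNames(doses, doses), function(d) {
    cc <- classified$category[classified$dose == d]
    nA <- sum(cc == "additive", na.rm = TRUE)
    nM <- sum(cc == "multiplicative", na.rm = TRUE)
    if (nA + nM == 0) NA_real_ else nA / (nA + nM)
  }, numeric(1))
}

#' Sliding-window histogram
#'
#' Overlapping bins of fixed width advanced by `step` (default half the
#' width), with edges aligned to multiples of `step` so that bin edges fall
#' exactly at 0 and 1. Bins are half-open `[lo, hi)`.
#'
#' @param x Numeric values.
#' @param binWidth Bin width (default 0.25).
#' @param step Distance between successive bin starts; `step == binWidth`
#'   gives an ordinary non-overlapping histogram.
#' @param range Optional `c(lo, hi)` limits; defaults to cover `x`.
#' @return data.frame `lo`, `hi`, `center`, `count`.
#' @export
slidingHistogram <- function(x, binWidth = 0.25, step = binWidth / 2,
                             range = NULL) {
  stopifnot(binWidth > 0, step > 0, step <= binWidth)
  x <- x[is.finite(x)]
  if (is.null(range)) range <- c(min(x), max(x))
  lo <- floor(range[1] / step) * step
  hi <- ceiling(range[2] / step) * step
  nStarts <- max(1, round((hi - lo) / step))
  starts <- lo + (seq_len(nStarts) - 1) * step
  counts <- vapply(starts, function(s)
    sum(x >= s & x < s + binWidth), integer(1))
  data.frame(lo = starts, hi = starts + binWidth,
             center = starts + binWidth / 2, count = counts)
}

histBarsAbutting <- function(h, anchors = c(0, 1), tol = 1e-8) {
  sel <- rep(FALSE, nrow(h))
  for (a in anchors)
    sel <- sel | abs(h$hi - a) < tol | abs(h$lo - a) < tol
  which(sel)
}

#' Scale a simulated histogram to the observed one
#'
#' Least-squares scale factor over the four histogram bars directly
#' abutting c = 0 and c = 1 (the two bars ending at and the two starting at
#' each anchor, on a binning with edges at the anchors): the closed form
#' minimizer of `sum((observed - scale * simulated)^2)` is
#' `sum(o * s) / sum(s^2)`.
#'
#' @param observed,simulated Histogram data.frames from
#'   [slidingHistogram()] on identical binning.
#' @param anchors Anchor points (default `c(0, 1)`).
#' @return Non-negative scalar scale factor.
#' @export
fitMixtureScale <- function(observed, simulated, anchors = c(0, 1)) {
  if (!isTRUE(all.equal(observed$lo, simulated$lo)))
    stop("histograms are not on an identical binning")
  idx <- histBarsAbutting(observed, anchors)
  o <- observed$count[idx]
  s <- simulated$count[idx]
  if (all(s == 0)) stop("all anchor bars of the simulated histogram are zero")
  sum(o * s) / sum(s^2)
}

#' Fit a Gaussian to the residual histogram after removing the additive
#' component
#'
#' Subtracts the (scaled) additive component of a simulated c-value
#' histogram from the observed histogram and fits a Gaussian density bump
#' `k * exp(-(x - mu)^2 / (2 sigma^2))` to the residual by nonlinear least
#' squares, locally within `fitRange`. A residual with no positive mass is
#' flagged degenerate instead of fitted.
#'
#' @param observed Observed c-value histogram ([slidingHistogram()]).
#' @param additiveSim Histogram of the additive simulation component on the
#'   same binning.
#' @param scale Scale factor for the additive component (e.g. from
#'   [fitMixtureScale()] applied to the mixture, times the additive mixture
#'   weight).
#' @param fitRange Range of c over which to fit (default `c(-4, 5)`).
#' @return List: `mu`, `sigma`, `amplitude`, `converged`, `degenerate`,
#'   and the residual table used (`residual`).
#' @export
residualSecondaryPeak <- function(observed, additiveSim, scale,
                                  fitRange = c(-4, 5)) {
  if (!isTRUE(all.equal(observed$lo, additiveSim$lo)))
    stop("histograms are not on an identical binning")
  res <- observed$count - scale * additiveSim$count
  keep <- observed$center >= fitRange[1] & observed$center <= fitRange[2]
  df <- data.frame(x = observed$center[keep], y = res[keep])
  out <- list(mu = NA_real_, sigma = NA_real_, amplitude = NA_real_,
              converged = FALSE, degenerate = FALSE, residual = df)
  if (nrow(df) < 4 || max(df$y) <= 0 ||
      sum(pmax(df$y, 0)) < 1) {
    out$degenerate <- TRUE
    return(out)
  }
  start <- list(k = max(df$y), mu = df$x[which.max(df$y)], sigma = 0.5)
  fit <- tryCatch(
    nls(y ~ k * exp(-(x - mu)^2 / (2 * sigma^2)), data = df,
        start = start, algorithm = "port",
        lower = c(k = 0, mu = min(df$x), sigma = 1e-3),
        upper = c(k = Inf, mu = max(df$x), sigma = diff(fitRange))),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ k * exp(-(x - mu)^2 / (2 * sigma^2)),
                        data = df, start = start,
                        lower = c(0, min(df$x), 1e-3)),
      error = function(e) NULL)
  if (is.null(fit)) {
    out$degenerate <- TRUE
    return(out)
  }
  cf <- coef(fit)
  out$mu <- unname(cf["mu"])
  out$sigma <- abs(unname(cf["sigma"]))
  out$amplitude <- unname(cf["k"])
  out$converged <- TRUE
  out
}

#' Poisson tail probabilities for c-value histogram bins
#'
#' Repeatedly re-simulates a purely additive cohort (one simulated
#' observation per feature per run), builds sliding-window histograms, and
#' asks per bin how improbable the observed count is if all combined
#' responses were additive: the observed histogram is scaled so its peak
#' height at c = 0 (sum of the two bars abutting 0) matches the mean
#' simulated peak height, the per-bin simulated counts provide the Poisson
#' rate, and the p value is the upper tail
#' `P(Poisson(lambda) >= k_observed)`. Bins whose center falls inside the
#' exclusion zone around 0 are omitted (there the additive peak itself
#' dominates and the Poisson description breaks down).
#'
#' @param observedC Observed c values.
#' @param responses Output of [responseEstimates()].
#' @param binWidth,step Histogram geometry (defaults 0.25 and 0.125).
#' @param nReps Number of simulation runs (default 1000).
#' @param exclusion Exclusion zone, open interval (default `c(-0.3, 0.3)`).
#' @param range Histogram range (default `c(-5, 6)`; values outside are
#'   dropped).
#' @param seed Optional integer seed.
#' @return data.frame `lo`, `hi`, `center`, `lambda`, `kObserved`,
#'   `pValue`, `flagged` (TRUE where `lambda == 0` with observations).
#' @export
poissonBinPvalues <- function(observedC, responses, binWidth = 0.25,
                              step = 0.125, nReps = 1000,
                              exclusion = c(-0.3, 0.3), range = c(-5, 6),
                              seed = NULL) {
  sims <- simulateNull(responses, mode = "additive", stat = "c",
                       nSims = nReps, seed = seed)
  obsHist <- slidingHistogram(observedC, binWidth, step, range)
  ## per-run simulated counts for every bin
  v <- sims$value
  runIdx <- sims$sim
  counts <- matrix(0, nrow = nrow(obsHist), ncol = nReps)
  for (b in seq_len(nrow(obsHist))) {
    inBin <- !is.na(v) & v >= obsHist$lo[b] & v < obsHist$hi[b]
    counts[b, ] <- tabulate(runIdx[inBin], nbins = nReps)
  }
  lambda <- rowMeans(counts)
  peakBins <- histBarsAbutting(obsHist, anchors = 0)
  simPeak <- sum(lambda[peakBins])
  obsPeak <- sum(obsHist$count[peakBins])
  if (obsPeak == 0) stop("observed histogram has no mass at c = 0")
  k <- round(obsHist$count * simPeak / obsPeak)
  p <- ppois(k - 1, lambda, lower.tail = FALSE)
  flagged <- lambda == 0 & k > 0
  p[flagged] <- 0
  keep <- !(obsHist$center > exclusion[1] & obsHist$center < exclusion[2])
  data.frame(lo = obsHist$lo, hi = obsHist$hi, center = obsHist$center,
             lambda = lambda, kObserved = k, pValue = p,
             flagged = flagged)[keep, , drop = FALSE]
}
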