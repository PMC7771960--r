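## Shared-CV Gaussian noise model and confidence-interval classification.
##
## Each replicate observation of a feature (gene TPM or peak normalized
## fragment count) is modelled as a draw from Gaussian(xbar, (xbar * CV)^2),
## where one coefficient of variation is shared by all doses of a signal.
## Pooling the CV across doses uses the information of all nine samples of a
## signal instead of the three samples of one dose.

rowSds <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

#' Pooled coefficient of variation across doses
#'
#' Per-dose CV uses the small-sample unbiased estimator
#' \eqn{(1 + 1/(4n)) \, s/\bar{x}} with \eqn{s} the sample (n-1) standard
#' deviation; the pooled value is the arithmetic mean over doses. Doses with
#' a non-positive mean are excluded from pooling.
#'
#' @param repsByDose List of numeric vectors, one per dose, each the
#'   replicate values at that dose.
#' @return Pooled CV (scalar); `NA` if no dose has a positive mean and at
#'   least two replicates.
#' @examples
#' estimateCV(list(c(9, 10, 11)))  # (1 + 1/12) * 1/10
#' @export
estimateCV <- function(repsByDose) {
  cvs <- vapply(repsByDose, function(v) {
    n <- length(v)
    if (n < 2) return(NA_real_)
    m <- mean(v)
    if (!is.finite(m) || m <= 0) return(NA_real_)
    (1 + 1 / (4 * n)) * sd(v) / m
  }, numeric(1))
  if (all(is.na(cvs))) NA_real_ else mean(cvs, na.rm = TRUE)
}

#' Estimate the shared-CV noise model of a SignalExperiment
#'
#' For every feature and signal, computes per-dose means and the pooled CV
#' (see [estimateCV()]); the modelled per-dose standard deviation is
#' `mean * cv`.
#'
#' @param se A [SignalExperiment].
#' @param assayName Assay to use (default first).
#' @return A data.frame with one row per (feature, signal, dose):
#'   `feature_id`, `signal`, `dose`, `mean`, `cv` (shared within the
#'   signal), `sd`. Features whose dose mean is non-positive keep the row
#'   but that dose does not contribute to the pooled CV.
#' @export
estimateNoise <- function(se, assayName = 1L) {
  stopifnot(is(se, "SignalExperiment"))
  x <- assay(se, assayName)
  cd <- colData(se)
  groups <- unique(data.frame(signal = cd$signal, dose = cd$dose,
                              stringsAsFactors = FALSE))
  ## per-(signal, dose) means and raw per-dose CVs
  parts <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- cd$signal == groups$signal[i] & cd$dose == groups$dose[i]
    sub <- x[, sel, drop = FALSE]
    n <- ncol(sub)
    m <- rowMeans(sub)
    s <- rowSds(sub)
    cvDose <- ifelse(is.finite(m) & m > 0 & n >= 2,
                     (1 + 1 / (4 * n)) * s / m, NA_real_)
    data.frame(feature_id = rownames(x), signal = groups$signal[i],
               dose = groups$dose[i], mean = m, cvDose = cvDose,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  ## pool the CV over doses within each (feature, signal)
  key <- paste(out$feature_id, out$signal, sep = "\r")
  pooled <- tapply(out$cvDose, key, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  out$cv <- as.numeric(pooled[key])
  out$sd <- out$mean * out$cv
  out$cvDose <- NULL
  rownames(out) <- NULL
  out[order(out$feature_id, out$signal, match(out$dose, doseLevels())), ,
      drop = FALSE]
}

#' Per-feature response estimates with a confidence interval
#'
#' For every feature and treated dose, assembles the baseline mean
#' \eqn{x_0} (normal-density control), the single-signal effects
#' \eqn{\Delta_A = \bar{x}_A - x_0} and \eqn{\Delta_B = \bar{x}_B - x_0} at
#' the matched dose, the combined-treatment mean \eqn{\bar{x}_{AB}}, the
#' additive prediction \eqn{x_0 + \Delta_A + \Delta_B}, the multiplicative
#' prediction \eqn{x_0 (\bar{x}_A/x_0)(\bar{x}_B/x_0)}, and a confidence
#' interval for the combined treatment,
#' \eqn{\bar{x}_{AB} \pm z \cdot \bar{x}_{AB} \mathrm{CV}_{both}}. The
#' interval describes the estimated Gaussian of single observations (the
#' modelled replicate noise), so normal quantiles are used.
#'
#' @param se A [SignalExperiment] containing control, signalA, signalB and
#'   both samples.
#' @param noise Output of [estimateNoise()] (computed if missing).
#' @param ciLevel Confidence level (default 0.80).
#' @return data.frame with one row per (feature, dose): `feature_id`,
#'   `dose`, `x0`, `dA`, `dB`, `xAB`, `cv0`, `cvA`, `cvB`, `cvAB`, `sd`,
#'   `ciLo`, `ciHi`, `predAdd`, `predMult`, `valid`. Rows with `x0 <= 0` or
#'   an unavailable CV are flagged `valid = FALSE` (predictions involving
#'   `1/x0` set to `NA`).
#' @export
responseEstimates <- function(se, noise = estimateNoise(se), ciLevel = 0.80) {
  stopifnot(ciLevel > 0, ciLevel < 1)
  pick <- function(sig, dose) {
    sel <- noise$signal == sig & noise$dose == dose
    setNames(noise$mean[sel], noise$feature_id[sel])
  }
  cvOf <- function(sig) {
    sel <- noise$signal == sig
    sub <- noise[sel, c("feature_id", "cv")]
    sub <- sub[!duplicated(sub$feature_id), ]
    setNames(sub$cv, sub$feature_id)
  }
  feats <- unique(noise$feature_id)
  x0 <- pick("control", "none")[feats]
  cv0 <- cvOf("control")[feats]
  cvA <- cvOf("signalA")[feats]
  cvB <- cvOf("signalB")[feats]
  cvAB <- cvOf("both")[feats]
  doses <- intersect(doseLevels(),
                     unique(noise$dose[noise$signal == "both"]))
  z <- qnorm((1 + ciLevel) / 2)
  rows <- lapply(doses, function(d) {
    xA <- pick("signalA", d)[feats]
    xB <- pick("signalB", d)[feats]
    xAB <- pick("both", d)[feats]
    dA <- xA - x0
    dB <- xB - x0
    s <- xAB * cvAB
    predAdd <- x0 + dA + dB
    predMult <- ifelse(x0 > 0, xA * xB / x0, NA_real_)
    valid <- is.finite(x0) & x0 > 0 & is.finite(xAB) & is.finite(dA) &
      is.finite(dB) & is.finite(cvAB)
    data.frame(feature_id = feats, dose = d, x0 = x0, dA = dA, dB = dB,
               xAB = xAB, cv0 = cv0, cvA = cvA, cvB = cvB, cvAB = cvAB,
               sd = s, ciLo = xAB - z * s, ciHi = xAB + z * s,
               predAdd = predAdd, predMult = predMult,
               valid = valid & !is.na(valid),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$feature_id, match(out$dose, doseLevels())), , drop = FALSE]
}

#' Categorical classification of combined gene responses
#'
#' Compares the hypothetical perfectly additive and perfectly multiplicative
#' predictions to the confidence interval of the combined-treatment value:
#' both predictions above the interval is sub-additive, only the additive
#' prediction inside is additive, both outside on opposite sides is
#' between-additive-and-multiplicative, only the multiplicative prediction
#' inside is multiplicative, both below is super-multiplicative, and both
#' inside is ambiguous. Interval endpoints are inclusive.
#'
#' @param responses Output of [responseEstimates()].
#' @return The input with a `category` column (factor with levels
#'   sub_additive, additive, between_add_mult, multiplicative,
#'   super_multiplicative, ambiguous); `NA` for invalid rows or rows where
#'   the additive prediction exceeds the multiplicative one (mixed-sign
#'   effects, outside the classification's domain).
#' @export
classifyGeneResponses <- function(responses) {
  r <- responses
  lv <- c("sub_additive", "additive", "between_add_mult",
          "multiplicative", "super_multiplicative", "ambiguous")
  addIn <- r$predAdd >= r$ciLo & r$predAdd <= r$ciHi
  mulIn <- r$predMult >= r$ciLo & r$predMult <= r$ciHi
  cat <- rep(NA_character_, nrow(r))
  ok <- r$valid & is.finite(r$predAdd) & is.finite(r$predMult) &
    r$predAdd <= r$predMult
  cat[ok & r$predAdd > r$ciHi & r$predMult > r$ciHi] <- "sub_additive"
  cat[ok & addIn & r$predMult > r$ciHi] <- "additive"
  cat[ok & r$predAdd < r$ciLo & r$predMult > r$ciHi] <- "between_add_mult"
  cat[ok & r$predAdd < r$ciLo & mulIn] <- "multiplicative"
  cat[ok & r$predAdd < r$ciLo & r$predMult < r$ciLo] <- "super_multiplicative"
  cat[ok & addIn & mulIn] <- "ambiguous"
  r$category <- factor(cat, levels = lv)
  r
}

#' Categorical classification of combined peak responses
#'
#' A peak is additive when the additive prediction lies within the
#' confidence interval of the combined-treatment normalized fragment
#' counts, sub-additive when the prediction is above the interval (observed
#' accessibility lower than predicted), and super-additive when below.
#'
#' @inheritParams classifyGeneResponses
#' @return Input with a `category` factor column (sub_additive, additive,
#'   super_additive); `NA` for invalid rows.
#' @export
classifyPeakResponses <- function(responses) {
  r <- responses
  cat <- rep(NA_character_, nrow(r))
  ok <- r$valid & is.finite(r$predAdd)
  cat[ok & r$predAdd > r$ciHi] <- "sub_additive"
  cat[ok & r$predAdd >= r$ciLo & r$predAdd <= r$ciHi] <- "additive"
  cat[ok & r$predAdd < r$ciLo] <- "super_additive"
  r$category <- factor(cat, levels = c("sub_additive", "additive",
                                       "super_additive"))
  r
}
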