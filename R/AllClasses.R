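## Central S4 containers.
##
## SignalExperiment wraps a SummarizedExperiment whose columns are replicate
## samples of a two-signal dosing design; FdrGrid holds the empirical-FDR
## threshold lattice used by the differential peak caller.

#' Valid signal and dose labels
#'
#' The dosing design distinguishes the vehicle control at normal seeding
#' density, two extra controls at perturbed seeding density (pure-null
#' samples used to estimate false discovery rates), each single signal, and
#' the combined treatment.
#'
#' @return Character vector of allowed levels.
#' @export
signalLevels <- function() {
  c("control", "control_low_density", "control_high_density",
    "signalA", "signalB", "both")
}

#' @rdname signalLevels
#' @export
doseLevels <- function() c("none", "low", "medium", "high")

#' Names of the control-like signal levels
#' @return Character vector.
#' @export
controlLevels <- function() {
  c("control", "control_low_density", "control_high_density")
}

#' SignalExperiment: replicate measurements under a two-signal design
#'
#' An extension of [SummarizedExperiment::SummarizedExperiment] whose
#' `colData` carries the experimental design: `signal` (one of
#' [signalLevels()]), `dose` (one of [doseLevels()]; `none` for controls) and
#' `replicate` (positive integer). Rows are features: genes with TPM values
#' or ATAC-seq peaks with normalized fragment counts; peak objects carry
#' their coordinates as `rowRanges`.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @export
setClass("SignalExperiment", contains = "RangedSummarizedExperiment")

setValidity("SignalExperiment", function(object) {
  cd <- colData(object)
  need <- c("signal", "dose", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss) > 0)
    return(paste("colData is missing column(s):", paste(miss, collapse = ", ")))
  sig <- as.character(cd$signal)
  dos <- as.character(cd$dose)
  if (!all(sig %in% signalLevels()))
    return("signal contains values outside signalLevels()")
  if (!all(dos %in% doseLevels()))
    return("dose contains values outside doseLevels()")
  ctrl <- sig %in% controlLevels()
  if (any(dos[ctrl] != "none"))
    return("control samples must have dose 'none'")
  if (any(dos[!ctrl] == "none"))
    return("treated samples must have a dose of low/medium/high")
  rep <- cd$replicate
  if (!is.numeric(rep) || any(rep < 1) || any(rep != round(rep)))
    return("replicate must be a positive integer")
  key <- paste(sig, dos, rep)
  if (anyDuplicated(key))
    return("(signal, dose, replicate) triples must be unique")
  if (length(assays(object)) < 1)
    return("at least one assay is required")
  TRUE
})

#' Construct a SignalExperiment
#'
#' @param values Numeric matrix, features x samples (TPM or normalized
#'   fragment counts).
#' @param signal,dose,replicate Per-sample design vectors (recycled checks
#'   apply); see [signalLevels()] and [doseLevels()].
#' @param rowRanges Optional [GenomicRanges::GRanges] of feature coordinates
#'   (used for peaks).
#' @param assayName Name for the single assay (default `"value"`).
#'
#' @return A `SignalExperiment`.
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 2,
#'             dimnames = list(c("g1", "g2"), NULL))
#' se <- SignalExperiment(m,
#'   signal = rep(c("control", "signalA"), each = 3),
#'   dose = rep(c("none", "low"), each = 3),
#'   replicate = rep(1:3, 2))
#' @export
SignalExperiment <- function(values, signal, dose, replicate,
                             rowRanges = NULL, assayName = "value") {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste(signal, dose, replicate, sep = "_")
  cd <- DataFrame(signal = as.character(signal),
                  dose = as.character(dose),
                  replicate = as.integer(replicate),
                  row.names = colnames(values))
  al <- setNames(list(values), assayName)
  se <- if (is.null(rowRanges)) {
    as(SummarizedExperiment(assays = al, colData = cd),
       "RangedSummarizedExperiment")
  } else {
    names(rowRanges) <- rownames(values)
    SummarizedExperiment(assays = al, colData = cd, rowRanges = rowRanges)
  }
  new("SignalExperiment", se)
}

setMethod("show", "SignalExperiment", function(object) {
  callNextMethod()
  cd <- colData(object)
  tab <- table(signal = cd$signal, dose = cd$dose)
  cat("design: ", sum(tab > 0), " signal/dose groups, ",
      nrow(cd), " samples\n", sep = "")
})

#' Feature identifiers of a SignalExperiment
#' @param x A `SignalExperiment`.
#' @return Character vector of row names.
#' @export
featureIds <- function(x) rownames(x)

#' Empirical-FDR threshold grid
#'
#' Result of [fdrGrid()]: a lattice of minimum fold-change x minimum count
#' thresholds where every cell holds the number of differential calls in
#' experimental conditions, the false-positive estimate from extra control
#' samples, and the estimated FDR.
#'
#' @slot fcThresholds,countThresholds Numeric, geometric threshold steps.
#' @slot nDiff Integer matrix (fc x count) of experimental differential calls.
#' @slot nFalsePos Numeric matrix of estimated false positives per cell.
#' @slot fdr Numeric matrix of estimated FDR (NA where 0/0).
#' @slot calls data.frame of per-(peak, condition) fold changes, max counts
#'   and their grid-bin indices, for experimental and extra-control
#'   conditions alike.
#' @slot nConditions Integer, number of experimental condition-dose
#'   combinations compared against the reference control.
#' @export
setClass("FdrGrid", representation(
  fcThresholds = "numeric",
  countThresholds = "numeric",
  nDiff = "matrix",
  nFalsePos = "matrix",
  fdr = "matrix",
  calls = "data.frame",
  nConditions = "integer"
))

setMethod("show", "FdrGrid", function(object) {
  cat("FdrGrid: ", length(object@fcThresholds), " x ",
      length(object@countThresholds), " cells\n", sep = "")
  cat("  fold-change thresholds: [",
      signif(min(object@fcThresholds), 4), ", ",
      signif(max(object@fcThresholds), 4), "]\n", sep = "")
  cat("  count thresholds: [", signif(min(object@countThresholds), 4), ", ",
      signif(max(object@countThresholds), 4), "]\n", sep = "")
  cat("  experimental conditions: ", object@nConditions, "\n", sep = "")
  ok <- !is.na(object@fdr)
  if (any(ok))
    cat("  estimated FDR range over defined cells: [",
        signif(min(object@fdr[ok]), 3), ", ",
        signif(max(object@fdr[ok]), 3), "]\n", sep = "")
})

#' @describeIn FdrGrid Estimated FDR matrix accessor.
#' @param x An `FdrGrid`.
#' @export
estimatedFdr <- function(x) x@fdr

#' @describeIn FdrGrid Threshold accessors.
#' @export
fcThresholds <- function(x) x@fcThresholds

#' @describeIn FdrGrid Threshold accessors.
#' @export
countThresholds <- function(x) x@countThresholds
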