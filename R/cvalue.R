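## Combined response factor (c value) and its chromatin analogue (d value),
## plus the master-set and reliability filters.

#' Combined response factor (c value)
#'
#' The c value places a feature's combined two-signal response on a
#' continuous spectrum: it is the unique statistic linear in the observed
#' combined value `xAB` that equals 0 at the additive prediction
#' `x0 + dA + dB` and 1 at the multiplicative prediction
#' `x0 (1 + dA/x0)(1 + dB/x0)`:
#' \deqn{c = (x_{AB} - x_0 - \Delta_A - \Delta_B) \cdot
#'   \frac{x_0}{\Delta_A \Delta_B}.}
#' For upregulated features, c < 0 is sub-additive and c > 1
#' super-multiplicative.
#'
#' @param x0 Baseline (control) mean; must be positive for a defined value.
#' @param dA,dB Single-signal effects (treated mean minus baseline).
#' @param xAB Combined-treatment mean.
#' @return Numeric vector of c values; `NA` where `x0 <= 0` or
#'   `dA * dB == 0`.
#' @examples
#' computeC(100, 100, 200, 400)  # additive combined response: 0
#' computeC(100, 100, 200, 600)  # multiplicative: 1
#' @export
computeC <- function(x0, dA, dB, xAB) {
  out <- (xAB - x0 - dA - dB) * x0 / (dA * dB)
  out[!(is.finite(x0) & x0 > 0) | dA * dB == 0] <- NA_real_
  out
}

#' Accessibility deviation from additivity (d value)
#'
#' Fold-change difference between the observed combined-treatment peak
#' integral and the additive prediction: `d = observed/predicted - 1`, so
#' d = 0 is perfectly additive, d > 0 super-additive and d < 0
#' sub-additive.
#'
#' @param predAdd Additive prediction of the combined peak integral; must
#'   be positive.
#' @param xAB Observed combined-treatment peak integral (mean over
#'   replicates of the normalized fragment counts in the peak).
#' @return Numeric vector of d values; `NA` where `predAdd <= 0`.
#' @export
computeD <- function(predAdd, xAB) {
  out <- xAB / predAdd - 1
  out[!(is.finite(predAdd) & predAdd > 0)] <- NA_real_
  out
}

#' Select the master set of upregulated genes
#'
#' A gene enters the master set when it is significantly upregulated in at
#' least one dose of the combined treatment (log2 fold-change and adjusted
#' p-value thresholds) and both individual signals increased its expression
#' at every dose. Genes with a baseline of zero are excluded from c-value
#' analyses because their c value degenerates to 0 regardless of the
#' signals' effects.
#'
#' @param de data.frame of combined-treatment differential expression
#'   results with columns `gene_id`, `dose`, `log2fc`, `padj` (one row per
#'   gene per dose).
#' @param responses Output of [responseEstimates()] for the genes.
#' @param lfcMin Minimum log2 fold-change (default 0.5).
#' @param padjMax Maximum BH-adjusted p value (default 0.05).
#' @return List with `genes` (character vector of included gene ids) and
#'   `excluded` (data.frame `gene_id`, `reason`), reasons being one of
#'   `not_upregulated_combined`, `negative_individual_delta`,
#'   `zero_baseline`, `missing_response` (mutually exclusive, applied in
#'   that order).
#' @export
selectMasterSet <- function(de, responses, lfcMin = 0.5, padjMax = 0.05) {
  stopifnot(all(c("gene_id", "dose", "log2fc", "padj") %in% colnames(de)))
  sig <- de$log2fc >= lfcMin & de$padj <= padjMax
  upAny <- tapply(sig, de$gene_id, any)
  genes <- names(upAny)
  posAll <- tapply(seq_len(nrow(responses)), responses$feature_id,
                   function(i) all(responses$dA[i] > 0 & responses$dB[i] > 0))
  zeroBase <- tapply(responses$x0, responses$feature_id,
                     function(v) any(!is.finite(v) | v <= 0))
  reason <- rep(NA_character_, length(genes))
  names(reason) <- genes
  inResp <- genes %in% names(posAll)
  reason[!upAny[genes]] <- "not_upregulated_combined"
  need <- is.na(reason) & !inResp
  reason[need] <- "missing_response"
  need <- is.na(reason)
  reason[need & !posAll[genes]] <- "negative_individual_delta"
  need <- is.na(reason)
  reason[need & zeroBase[genes]] <- "zero_baseline"
  included <- genes[is.na(reason)]
  excluded <- data.frame(gene_id = genes[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         row.names = NULL, stringsAsFactors = FALSE)
  list(genes = included, excluded = excluded)
}

#' Reliability filter for c-value estimates
#'
#' The interaction scale `dA * dB / x0` is the gap between the
#' multiplicative and additive predictions; when it is small the c value is
#' dominated by technical noise. A (feature, dose) estimate is reliable
#' when `dA * dB / x0 >= minScale` (in measurement units, default 2 TPM)
#' and `dA * dB / x0 >= x0`. Boundaries are inclusive.
#'
#' @param responses Output of [responseEstimates()].
#' @param minScale Absolute floor for the interaction scale (default 2).
#' @return Logical vector along the rows of `responses` (`FALSE` where
#'   undefined).
#' @export
reliabilityFilter <- function(responses, minScale = 2) {
  scale <- responses$dA * responses$dB / responses$x0
  ok <- is.finite(scale) & scale >= minScale & scale >= responses$x0
  ok & !is.na(ok)
}

#' c values for a response table
#'
#' @param responses Output of [responseEstimates()].
#' @param masterGenes Optional character vector restricting to the master
#'   set.
#' @param minScale Passed to [reliabilityFilter()].
#' @return data.frame `feature_id`, `dose`, `c`, `interactionScale`,
#'   `reliable`.
#' @export
cValueTable <- function(responses, masterGenes = NULL, minScale = 2) {
  r <- responses
  if (!is.null(masterGenes)) r <- r[r$feature_id %in% masterGenes, ]
  data.frame(feature_id = r$feature_id, dose = r$dose,
             c = computeC(r$x0, r$dA, r$dB, r$xAB),
             interactionScale = r$dA * r$dB / r$x0,
             reliable = reliabilityFilter(r, minScale),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' d values for a peak response table
#'
#' @param responses Output of [responseEstimates()] on peak data.
#' @return data.frame `feature_id`, `dose`, `d`, `predAdd`.
#' @export
dValueTable <- function(responses) {
  data.frame(feature_id = responses$feature_id, dose = responses$dose,
             d = computeD(responses$predAdd, responses$xAB),
             predAdd = responses$predAdd,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dose trajectories of c values
#'
#' Tracks each gene's c value from low to medium to high dose, restricted
#' to reliable estimates. Genes lacking a reliable estimate at any dose are
#' dropped from the full-trajectory table but kept in the partial table.
#'
#' @param cRecords Output of [cValueTable()].
#' @param doses Dose order (default low, medium, high).
#' @return List of two data.frames: `full` (columns `gene_id`, one c column
#'   per dose, `slope` = high minus low) and `partial` (genes with at least
#'   one but not all doses reliable; unreliable doses `NA`).
#' @export
doseTrajectories <- function(cRecords, doses = c("low", "medium", "high")) {
  rel <- cRecords[cRecords$reliable & !is.na(cRecords$c), ]
  wide <- data.frame(gene_id = sort(unique(cRecords$feature_id)),
                     stringsAsFactors = FALSE)
  for (d in doses) {
    sub <- rel[rel$dose == d, ]
    wide[[paste0("c_", d)]] <-
      sub$c[match(wide$gene_id, sub$feature_id)]
  }
  cc <- as.matrix(wide[, paste0("c_", doses), drop = FALSE])
  nOk <- rowSums(!is.na(cc))
  full <- wide[nOk == length(doses), , drop = FALSE]
  if (nrow(full) > 0)
    full$slope <- full[[paste0("c_", doses[length(doses)])]] -
      full[[paste0("c_", doses[1])]]
  partial <- wide[nOk > 0 & nOk < length(doses), , drop = FALSE]
  rownames(full) <- rownames(partial) <- NULL
  list(full = full, partial = partial)
}
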