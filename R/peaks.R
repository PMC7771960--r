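## Differential ATAC-seq peak calling with an empirical-FDR grid.
##
## Consensus peaks are 150 bp nucleosome-sized windows centered on summits
## supported by a majority of replicates. Fragment counts are normalized by
## reads-in-peaks depth, and differential peaks are called on a lattice of
## fold-change x count thresholds whose per-cell FDR is estimated from extra
## control samples that differ from the reference only in starting cell
## density (so every differential call against them is a false positive).

geometricSteps <- function(from, to, n) {
  from * (to / from)^((seq_len(n) - 1) / (n - 1))
}

conditionLabel <- function(signal, dose) {
  ifelse(dose == "none", signal, paste(signal, dose, sep = "_"))
}

#' Consensus peaks from replicate summit sets
#'
#' Summits from different replicates whose `width`-bp windows overlap
#' (summit distance < `width`) are grouped by single-linkage; groups
#' supported by at least `minSupport` distinct replicates emit one peak of
#' `width` bp centered on the group's median summit position.
#'
#' @param summitsList List of [GenomicRanges::GRanges] (width-1 summit
#'   positions), one element per replicate.
#' @param width Peak width in bp (default 150, one nucleosome).
#' @param minSupport Minimum number of distinct replicates (default 2).
#' @return `GRanges` of consensus peaks with metadata columns `summit`
#'   (1-based position) and `support`. Output is independent of the order
#'   of `summitsList`.
#' @export
consensusPeaks <- function(summitsList, width = 150, minSupport = 2) {
  stopifnot(length(summitsList) >= minSupport)
  empty <- vapply(summitsList, length, integer(1)) == 0
  if (any(empty))
    warning(sum(empty), " replicate summit set(s) are empty")
  pooled <- do.call(c, lapply(seq_along(summitsList), function(i) {
    g <- granges(summitsList[[i]])
    if (length(g)) mcols(g)$replicate <- i
    g
  }))
  if (length(pooled) == 0)
    return(GRanges(summit = integer(), support = integer()))
  win <- suppressWarnings(resize(pooled, width, fix = "center"))
  grp <- reduce(win, min.gapwidth = 0L)
  hit <- findOverlaps(win, grp)
  grpIdx <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  pos <- start(pooled)
  reps <- mcols(pooled)$replicate
  support <- as.integer(tapply(reps, grpIdx, function(v) length(unique(v))))
  med <- as.integer(round(tapply(pos, grpIdx, median)))
  chrom <- as.character(tapply(as.character(seqnames(pooled)), grpIdx,
                               function(v) v[1]))
  keep <- support >= minSupport
  if (!any(keep))
    return(GRanges(summit = integer(), support = integer()))
  out <- GRanges(chrom[keep],
                 IRanges(start = med[keep] - floor(width / 2), width = width),
                 summit = med[keep], support = support[keep])
  sort(out)
}

#' Master consensus peak set across conditions
#'
#' Union of per-condition consensus peak sets with overlapping peaks
#' collapsed to a single peak, so the output is pairwise non-overlapping.
#'
#' @param peaksList List of `GRanges` peak sets (one per condition).
#' @return Non-overlapping `GRanges`, named `peak_00001`, ... in
#'   coordinate order.
#' @export
masterConsensus <- function(peaksList) {
  pooled <- do.call(c, lapply(peaksList, granges))
  out <- sort(reduce(pooled, min.gapwidth = 0L))
  names(out) <- sprintf("peak_%05d", seq_along(out))
  out
}

#' Depth-normalize a reads-in-peaks count matrix
#'
#' Each sample's counts are divided by
#' `total_s / mean_over_samples(total)`, so after normalization every
#' sample's reads-in-peaks total equals the grand mean and the grand total
#' is conserved.
#'
#' @param raw Numeric matrix, peaks x samples.
#' @return Normalized matrix of the same shape.
#' @export
normalizeCounts <- function(raw) {
  totals <- colSums(raw)
  if (any(totals <= 0)) stop("sample(s) with non-positive reads-in-peaks total")
  scale <- totals / mean(totals)
  sweep(raw, 2, scale, "/")
}

## per-(signal, dose) mean normalized counts, peaks x conditions
conditionMeanMatrix <- function(norm, sampleInfo) {
  lab <- conditionLabel(sampleInfo$signal, sampleInfo$dose)
  u <- unique(lab)
  m <- vapply(u, function(g)
    rowMeans(norm[, lab == g, drop = FALSE]), numeric(nrow(norm)))
  dimnames(m) <- list(rownames(norm), u)
  m
}

#' Empirical-FDR threshold grid for differential peak calling
#'
#' Lays a grid of 50 geometric minimum fold-change steps by 50 geometric
#' minimum count steps. Per cell, a peak is differential for a condition
#' versus the reference control when the (pseudocounted, two-sided) fold
#' change meets the fold-change threshold and the larger of the two
#' condition means meets the count threshold. The number of differential
#' calls in the extra density controls estimates the false positives per
#' condition, and the cell FDR is
#' `n_conditions * estimated_FP_per_condition / total experimental calls`.
#'
#' @param norm Normalized count matrix (peaks x samples).
#' @param sampleInfo data.frame with `signal` and `dose` per column of
#'   `norm` (see [signalLevels()]).
#' @param fcRange,countRange Grid end points, inclusive (defaults
#'   `c(1.1, 10)` and `c(10, 237)`).
#' @param nSteps Steps per axis (default 50).
#' @param pseudocount Added to both means before the fold change (default 1).
#' @return An [FdrGrid].
#' @export
fdrGrid <- function(norm, sampleInfo, fcRange = c(1.1, 10),
                    countRange = c(10, 237), nSteps = 50, pseudocount = 1) {
  stopifnot(nrow(sampleInfo) == ncol(norm))
  fcs <- geometricSteps(fcRange[1], fcRange[2], nSteps)
  cnts <- geometricSteps(countRange[1], countRange[2], nSteps)
  cm <- conditionMeanMatrix(norm, sampleInfo)
  if (!"control" %in% colnames(cm)) stop("no reference control samples")
  ref <- cm[, "control"]
  extras <- intersect(colnames(cm),
                      c("control_low_density", "control_high_density"))
  if (length(extras) == 0)
    stop("no extra control samples; the FDR cannot be estimated")
  expCond <- setdiff(colnames(cm), c("control", extras))
  if (length(expCond) == 0) stop("no experimental conditions")

  callsFor <- function(cond) {
    m <- cm[, cond]
    fc <- pmax((m + pseudocount) / (ref + pseudocount),
               (ref + pseudocount) / (m + pseudocount))
    mx <- pmax(m, ref)
    data.frame(peak_id = rownames(cm), condition = cond, fc = fc,
               maxCount = mx,
               fcBin = findInterval(fc, fcs),
               countBin = findInterval(mx, cnts),
               isControl = cond %in% extras,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, lapply(c(expCond, extras), callsFor))

  ## cumulative cell counts: a call lands in cell (i, j) iff fcBin >= i and
  ## countBin >= j
  cellCounts <- function(sub) {
    h <- matrix(0, nSteps, nSteps)
    ok <- sub$fcBin >= 1 & sub$countBin >= 1
    if (any(ok)) {
      tab <- table(factor(sub$fcBin[ok], levels = seq_len(nSteps)),
                   factor(sub$countBin[ok], levels = seq_len(nSteps)))
      h <- matrix(as.numeric(tab), nSteps, nSteps)
    }
    revCum <- function(m) apply(m, 2, function(v) rev(cumsum(rev(v))))
    t(revCum(t(revCum(h))))
  }
  nDiff <- cellCounts(calls[!calls$isControl, ])
  fpPer <- lapply(extras, function(e)
    cellCounts(calls[calls$condition == e, ]))
  nFP <- Reduce(`+`, fpPer) / length(fpPer)
  fdr <- length(expCond) * nFP / nDiff
  fdr[nDiff == 0] <- NA_real_
  new("FdrGrid", fcThresholds = fcs, countThresholds = cnts,
      nDiff = nDiff, nFalsePos = nFP, fdr = fdr, calls = calls,
      nConditions = length(expCond))
}

## logical matrix M[a, b] = any qualifying cell (i <= a, j <= b)
anyLooserCell <- function(q) {
  m <- apply(q, 2, cummax)
  m <- t(apply(m, 1, cummax))
  m > 0
}

#' Pool differential peaks from low-FDR grid cells
#'
#' Takes the union of the differential (peak, condition) calls of every
#' grid cell whose estimated FDR is below `cellFdrThreshold`, then
#' recomputes a pooled FDR on the union (false positives re-estimated from
#' the extra controls under the same union rule).
#'
#' @param grid An [FdrGrid].
#' @param cellFdrThreshold Per-cell FDR cut-off (default 0.0025, i.e.
#'   0.25%).
#' @return List: `calls` (experimental (peak, condition) calls,
#'   data.frame), `peaks` (unique peak ids), `pooledFdr`,
#'   `controlCalls` (calls in the extra controls under the union rule).
#' @export
callDifferentialPeaks <- function(grid, cellFdrThreshold = 0.0025) {
  q <- !is.na(grid@fdr) & grid@fdr < cellFdrThreshold
  calls <- grid@calls
  if (!any(q)) {
    warning("no grid cell passes the FDR threshold")
    empty <- calls[0, ]
    return(list(calls = empty, peaks = character(), pooledFdr = NA_real_,
                controlCalls = empty))
  }
  m <- anyLooserCell(q)
  inUnion <- calls$fcBin >= 1 & calls$countBin >= 1 &
    m[cbind(pmax(calls$fcBin, 1), pmax(calls$countBin, 1))]
  expCalls <- calls[inUnion & !calls$isControl, , drop = FALSE]
  ctlCalls <- calls[inUnion & calls$isControl, , drop = FALSE]
  nExtra <- length(unique(calls$condition[calls$isControl]))
  fpPerCond <- nrow(ctlCalls) / nExtra
  pooled <- if (nrow(expCalls) == 0) NA_real_ else
    grid@nConditions * fpPerCond / nrow(expCalls)
  rownames(expCalls) <- rownames(ctlCalls) <- NULL
  list(calls = expCalls, peaks = unique(expCalls$peak_id),
       pooledFdr = pooled, controlCalls = ctlCalls)
}

#' Merge round-1 peaks and re-call at fixed thresholds
#'
#' Nucleosome-sized peaks within `mergeDistance` bp of each other
#' (boundary inclusive) often form one larger element; they are merged,
#' counts are re-aggregated by summing member peaks, and a second
#' differential pass is run at fixed fold-change and count thresholds. The
#' pooled FDR of the final set is re-estimated from the extra controls.
#'
#' @param round1 Output of [callDifferentialPeaks()].
#' @param peaks Named `GRanges` of the master consensus peaks (names are
#'   peak ids).
#' @param norm Normalized count matrix (peaks x samples; rownames are peak
#'   ids).
#' @param sampleInfo data.frame with `signal` and `dose` per sample.
#' @param mergeDistance Maximum gap merged, inclusive (default 250 bp).
#' @param minFc Second-round minimum fold change (default 1.5).
#' @param minCount Second-round minimum normalized fragment count
#'   (default 30).
#' @param pseudocount Added before fold changes (default 1).
#' @return List: `peaks` (merged `GRanges` with `peak_id` names), `counts`
#'   (merged normalized counts), `calls` (second-round (peak, condition)
#'   calls), `differentialPeaks` (ids with at least one call),
#'   `pooledFdr`.
#' @export
mergeAndRecall <- function(round1, peaks, norm, sampleInfo,
                           mergeDistance = 250, minFc = 1.5, minCount = 30,
                           pseudocount = 1) {
  ids <- round1$peaks
  if (length(ids) == 0)
    return(list(peaks = GRanges(), counts = norm[0, , drop = FALSE],
                calls = round1$calls[0, ], differentialPeaks = character(),
                pooledFdr = NA_real_))
  sub <- peaks[ids]
  merged <- reduce(sub, min.gapwidth = mergeDistance + 1L)
  names(merged) <- sprintf("merged_%05d", seq_along(merged))
  hit <- findOverlaps(sub, merged)
  memb <- names(merged)[S4Vectors::subjectHits(hit)]
  mergedCounts <- rowsum(norm[ids, , drop = FALSE], memb)
  mergedCounts <- mergedCounts[names(merged), , drop = FALSE]

  cm <- conditionMeanMatrix(mergedCounts, sampleInfo)
  ref <- cm[, "control"]
  extras <- intersect(colnames(cm),
                      c("control_low_density", "control_high_density"))
  expCond <- setdiff(colnames(cm), c("control", extras))
  passFor <- function(cond) {
    m <- cm[, cond]
    fc <- pmax((m + pseudocount) / (ref + pseudocount),
               (ref + pseudocount) / (m + pseudocount))
    fc >= minFc & pmax(m, ref) >= minCount
  }
  calls <- do.call(rbind, lapply(expCond, function(cond) {
    ok <- passFor(cond)
    if (!any(ok)) return(NULL)
    data.frame(peak_id = rownames(cm)[ok], condition = cond,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(calls))
    calls <- data.frame(peak_id = character(), condition = character())
  nFPctl <- vapply(extras, function(e) sum(passFor(e)), numeric(1))
  fpPerCond <- if (length(extras)) mean(nFPctl) else NA_real_
  pooled <- if (nrow(calls) == 0) NA_real_ else
    length(expCond) * fpPerCond / nrow(calls)
  list(peaks = merged, counts = mergedCounts, calls = calls,
       differentialPeaks = unique(calls$peak_id), pooledFdr = pooled)
}
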