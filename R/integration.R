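## Relating peak behaviour and motif content to gene behaviour: proximity
## counting in TSS windows, signal-exclusive peaks, bootstrap confidence
## intervals, motif group densities, dual-motif shuffle nulls, and motif
## enrichment scores.

#' Transcription factor motif groups
#'
#' Motifs with near-identical position weight matrices are collapsed into
#' groups (e.g. AP-1 spans JUN/FOS/BACH/BATF family members); each group is
#' labelled by the signal whose response dominates the accessibility of
#' peaks carrying it (`RA_dominant`, `TGFB_dominant`, `neither`). The
#' default table ships with the package and can be replaced by any TSV with
#' columns `group`, `motif`, `dominance`.
#'
#' @param file Path to a group definition TSV.
#' @return data.frame with columns `group`, `motif`, `dominance`.
#' @export
motifGroups <- function(file = system.file("extdata", "motif_groups.tsv",
                                           package = "comboResponse")) {
  g <- read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "motif", "dominance") %in% colnames(g)))
  if (anyDuplicated(g$motif))
    stop("a motif may belong to only one group")
  g
}

#' Collapse a motif match matrix to group counts
#'
#' Per peak, the count for a group is the maximum match count over the
#' group's member motifs (taking the max rather than the sum avoids
#' over-counting motifs with similar position weight matrices that match
#' the same sequence).
#'
#' @param matches Numeric matrix, peaks x motifs (column names are motif
#'   names).
#' @param groups Group table from [motifGroups()]; motifs absent from the
#'   matrix are ignored, matrix motifs absent from the table are dropped.
#' @return Numeric matrix, peaks x groups.
#' @export
collapseMotifGroups <- function(matches, groups = motifGroups()) {
  gs <- unique(groups$group)
  cols <- lapply(gs, function(g) {
    member <- intersect(groups$motif[groups$group == g], colnames(matches))
    if (length(member) == 0) return(rep(0, nrow(matches)))
    apply(matches[, member, drop = FALSE], 1, max)
  })
  out <- matrix(unlist(cols), nrow = nrow(matches),
                dimnames = list(rownames(matches), gs))
  out
}

#' Link peaks to genes within a TSS window
#'
#' A peak is linked to a gene when the distance from the gene's canonical
#' TSS to the peak midpoint is at most `windowBp` (inclusive). The window
#' is symmetric around the TSS; strand is ignored.
#'
#' @param peaks Named `GRanges` of peaks.
#' @param genes data.frame with `gene_id`, `chrom`, `tss` (0-based
#'   coordinate) and optionally `strand`.
#' @param windowBp Window half-width in bp (default 100000).
#' @return data.frame `gene_id`, `peak_id`, `distance`, `withinWindow`
#'   (all `TRUE`), one row per link. A peak linking to several genes
#'   contributes one row per gene.
#' @export
linkPeaksToGenes <- function(peaks, genes, windowBp = 100000) {
  stopifnot(!is.null(names(peaks)))
  ok <- is.finite(genes$tss)
  if (any(!ok)) {
    message("skipping ", sum(!ok), " gene(s) without a TSS annotation")
    genes <- genes[ok, , drop = FALSE]
  }
  midPos <- start(peaks) + floor((width(peaks) - 1) / 2)
  midG <- GRanges(seqnames(peaks), IRanges(midPos, width = 1))
  tssPos <- genes$tss + 1L  # 0-based -> 1-based
  winG <- GRanges(genes$chrom,
                  IRanges(pmax(1L, tssPos - windowBp), tssPos + windowBp))
  hit <- findOverlaps(midG, winG)
  qi <- S4Vectors::queryHits(hit)
  si <- S4Vectors::subjectHits(hit)
  dist <- abs(midPos[qi] - tssPos[si])
  keep <- dist <= windowBp
  data.frame(gene_id = genes$gene_id[si][keep],
             peak_id = names(peaks)[qi][keep],
             distance = dist[keep],
             withinWindow = rep(TRUE, sum(keep)),
             row.names = NULL, stringsAsFactors = FALSE)
}

## percentile bootstrap of a statistic over resampled rows of `values`
bootStat <- function(values, statFun, nBoot, level) {
  n <- length(values)
  idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = nBoot)
  boots <- apply(idx, 1, function(i) statFun(values[i]))
  a <- (1 - level) / 2
  quantile(boots, c(a, 1 - a), names = FALSE, na.rm = TRUE)
}

#' Mean linked-peak counts per gene category with bootstrap CIs
#'
#' For every gene, counts the linked peaks of each accessibility class;
#' reports per (gene category, peak class) the mean count per gene with a
#' percentile-bootstrap confidence interval over resampled genes.
#'
#' @param links Output of [linkPeaksToGenes()].
#' @param peakCategories data.frame `feature_id`, `category` for peaks (one
#'   dose).
#' @param geneCategories data.frame `feature_id`, `category` for genes
#'   (same dose).
#' @param nBoot Bootstrap samples (default 10000).
#' @param level CI level (default 0.90).
#' @param seed Optional seed.
#' @return data.frame `gene_category`, `peak_category`, `meanCount`,
#'   `ciLo`, `ciHi`, `nGenes`. Empty gene categories are omitted.
#' @export
peakClassCountsByGeneCategory <- function(links, peakCategories,
                                          geneCategories, nBoot = 10000,
                                          level = 0.90, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pcls <- levels(factor(peakCategories$category))
  gcls <- levels(factor(geneCategories$category))
  pk <- setNames(as.character(peakCategories$category),
                 peakCategories$feature_id)
  rows <- list()
  for (gc in gcls) {
    gset <- geneCategories$feature_id[
      !is.na(geneCategories$category) & geneCategories$category == gc]
    if (length(gset) == 0) next
    sub <- links[links$gene_id %in% gset, , drop = FALSE]
    for (pc in pcls) {
      inClass <- sub[!is.na(pk[sub$peak_id]) & pk[sub$peak_id] == pc, ]
      counts <- table(factor(inClass$gene_id, levels = gset))
      vals <- as.numeric(counts)
      ci <- if (length(vals) > 1) {
        bootStat(vals, mean, nBoot, level)
      } else c(vals, vals)
      rows[[length(rows) + 1]] <-
        data.frame(gene_category = gc, peak_category = pc,
                   meanCount = mean(vals), ciLo = ci[1], ciHi = ci[2],
                   nGenes = length(gset), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Label signal-exclusive (dominant) peaks
#'
#' A peak responds exclusively to one signal when that signal's absolute
#' accessibility change is at least 90% of the summed absolute changes of
#' both signals (equivalently, at least 9x the minor effect). The boundary
#' is inclusive.
#'
#' @param responses Output of [responseEstimates()] on peak data.
#' @param threshold Major-fraction threshold (default 0.9).
#' @return data.frame `feature_id`, `dose`, `majorFraction`, `label`
#'   (factor A_dominant / B_dominant / shared; `NA` when both effects are
#'   zero).
#' @export
labelExclusivePeaks <- function(responses, threshold = 0.9) {
  aA <- abs(responses$dA)
  aB <- abs(responses$dB)
  tot <- aA + aB
  frac <- ifelse(tot > 0, pmax(aA, aB) / tot, NA_real_)
  lab <- rep(NA_character_, nrow(responses))
  lab[!is.na(frac) & frac < threshold] <- "shared"
  lab[!is.na(frac) & frac >= threshold & aA >= aB] <- "A_dominant"
  lab[!is.na(frac) & frac >= threshold & aB > aA] <- "B_dominant"
  data.frame(feature_id = responses$feature_id, dose = responses$dose,
             majorFraction = frac,
             label = factor(lab, levels = c("A_dominant", "B_dominant",
                                            "shared")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of genes with both an A-exclusive and a B-exclusive peak
#'
#' Per gene category, the fraction of genes whose linked peaks include at
#' least one A-dominant and at least one B-dominant peak, with a
#' percentile-bootstrap CI over resampled genes.
#'
#' @param links Output of [linkPeaksToGenes()].
#' @param labels Output of [labelExclusivePeaks()] restricted to one dose.
#' @param geneCategories data.frame `feature_id`, `category` for genes.
#' @inheritParams peakClassCountsByGeneCategory
#' @return data.frame `gene_category`, `fraction`, `ciLo`, `ciHi`,
#'   `nGenes`.
#' @export
dualDominantGeneFraction <- function(links, labels, geneCategories,
                                     nBoot = 10000, level = 0.90,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- setNames(as.character(labels$label), labels$feature_id)
  rows <- list()
  for (gc in levels(factor(geneCategories$category))) {
    gset <- geneCategories$feature_id[
      !is.na(geneCategories$category) & geneCategories$category == gc]
    if (length(gset) == 0) next
    sub <- links[links$gene_id %in% gset, , drop = FALSE]
    pl <- lab[sub$peak_id]
    hasA <- tapply(!is.na(pl) & pl == "A_dominant", sub$gene_id, any)
    hasB <- tapply(!is.na(pl) & pl == "B_dominant", sub$gene_id, any)
    dual <- rep(FALSE, length(gset))
    names(dual) <- gset
    both <- names(hasA)[hasA & hasB[names(hasA)]]
    dual[both] <- TRUE
    ci <- if (length(dual) > 1) bootStat(as.numeric(dual), mean, nBoot,
                                         level) else rep(mean(dual), 2)
    rows[[length(rows) + 1]] <-
      data.frame(gene_category = gc, fraction = mean(dual),
                 ciLo = ci[1], ciHi = ci[2], nGenes = length(gset),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Motif group densities per peak class
#'
#' Per peak, the collapsed group count divided by the peak width in units
#' of 150 bp; per (peak class, group), the mean density with a
#' percentile-bootstrap CI over resampled peaks.
#'
#' @param peaks Named `GRanges` (widths used).
#' @param matches Motif match matrix (peaks x motifs).
#' @param peakCategories data.frame `feature_id`, `category`.
#' @param groups Motif group table (default [motifGroups()]).
#' @param nBoot Bootstrap samples (default 1000).
#' @param level CI level (default 0.90).
#' @param seed Optional seed.
#' @return data.frame `peak_category`, `group`, `meanDensity`, `ciLo`,
#'   `ciHi`, `nPeaks`.
#' @export
motifDensity <- function(peaks, matches, peakCategories,
                         groups = motifGroups(), nBoot = 1000,
                         level = 0.90, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(width(peaks) <= 0)) stop("zero-width peak")
  gm <- collapseMotifGroups(matches, groups)
  wUnits <- setNames(width(peaks) / 150, names(peaks))
  dens <- gm / wUnits[rownames(gm)]
  rows <- list()
  for (pc in levels(factor(peakCategories$category))) {
    ids <- peakCategories$feature_id[
      !is.na(peakCategories$category) & peakCategories$category == pc]
    ids <- intersect(ids, rownames(dens))
    if (length(ids) == 0) next
    for (g in colnames(dens)) {
      vals <- dens[ids, g]
      ci <- if (length(vals) > 1) bootStat(vals, mean, nBoot, level) else
        rep(vals, 2)
      rows[[length(rows) + 1]] <-
        data.frame(peak_category = pc, group = g, meanDensity = mean(vals),
                   ciLo = ci[1], ciHi = ci[2], nPeaks = length(ids),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Shuffle null for dual-motif co-occurrence
#'
#' Within each peak class, the collapsed (grouped) motif matches are
#' redistributed uniformly at random among the class's peaks while every
#' peak keeps its original total number of grouped matches — a peak with
#' zero matches has zero matches after every shuffle. Per shuffle, the
#' fraction of peaks carrying at least one RA-dominant and at least one
#' TGFB-dominant group match is recorded.
#'
#' @param peakCategories data.frame `feature_id`, `category`.
#' @param matches Motif match matrix (peaks x motifs).
#' @param groups Motif group table with a `dominance` column.
#' @param nShuffles Number of shuffles (default 1000).
#' @param seed Optional seed.
#' @return data.frame per peak class: `peak_category`, `observed`,
#'   `nullMean`, `q05`, `q95`, `pLower` (P(null <= observed)), `pUpper`,
#'   `nPeaks`, `totalsConserved`.
#' @export
dualMotifShuffleNull <- function(peakCategories, matches,
                                 groups = motifGroups(), nShuffles = 1000,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gm <- collapseMotifGroups(matches, groups)
  dom <- setNames(groups$dominance[!duplicated(groups$group)],
                  groups$group[!duplicated(groups$group)])
  raGroups <- names(dom)[dom == "RA_dominant"]
  tgGroups <- names(dom)[dom == "TGFB_dominant"]
  rows <- list()
  for (pc in levels(factor(peakCategories$category))) {
    ids <- peakCategories$feature_id[
      !is.na(peakCategories$category) & peakCategories$category == pc]
    ids <- intersect(ids, rownames(gm))
    if (length(ids) < 2) {
      warning("peak class '", pc, "' has fewer than 2 peaks; null undefined")
      next
    }
    sub <- gm[ids, , drop = FALSE]
    totals <- rowSums(sub)
    dualFrac <- function(m) {
      mean(rowSums(m[, raGroups, drop = FALSE]) >= 1 &
             rowSums(m[, tgGroups, drop = FALSE]) >= 1)
    }
    obs <- dualFrac(sub)
    ## flatten grouped matches into a label pool, fixed per-peak slot counts
    pool <- rep(rep(colnames(sub), each = nrow(sub)), times = as.vector(sub))
    slotPeak <- rep(seq_along(ids), times = totals)
    conserved <- length(pool) == sum(totals)
    nullFrac <- vapply(seq_len(nShuffles), function(i) {
      lab <- sample(pool)
      isRA <- lab %in% raGroups
      isTG <- lab %in% tgGroups
      hasRA <- tapply(isRA, slotPeak, any)
      hasTG <- tapply(isTG, slotPeak, any)
      sum(hasRA & hasTG) / length(ids)
    }, numeric(1))
    q <- quantile(nullFrac, c(0.05, 0.95), names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      peak_category = pc, observed = obs, nullMean = mean(nullFrac),
      q05 = q[1], q95 = q[2],
      pLower = (1 + sum(nullFrac <= obs)) / (nShuffles + 1),
      pUpper = (1 + sum(nullFrac >= obs)) / (nShuffles + 1),
      nPeaks = length(ids), totalsConserved = conserved,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Per-motif accessibility enrichment score
#'
#' For each motif, the fractional change in mean normalized fragment
#' counts at motif-containing peaks between a condition and the reference
#' control, pooling the doses of the condition:
#' `(mean_condition - mean_reference) / mean_reference`.
#'
#' @param matches Motif match matrix (peaks x motifs).
#' @param norm Normalized count matrix (peaks x samples).
#' @param sampleInfo data.frame with `signal`, `dose` per sample.
#' @param condition Signal name (e.g. `"signalA"`); all its doses pooled.
#' @param reference Reference signal (default `"control"`).
#' @return data.frame `motif`, `score`, `nPeaks`; motifs contained in no
#'   peak get `NA` with a message.
#' @export
motifEnrichmentScore <- function(matches, norm, sampleInfo, condition,
                                 reference = "control") {
  condSel <- sampleInfo$signal == condition
  refSel <- sampleInfo$signal == reference
  stopifnot(any(condSel), any(refSel))
  common <- intersect(rownames(matches), rownames(norm))
  matches <- matches[common, , drop = FALSE]
  condMean <- rowMeans(norm[common, condSel, drop = FALSE])
  refMean <- rowMeans(norm[common, refSel, drop = FALSE])
  out <- lapply(colnames(matches), function(m) {
    has <- matches[, m] >= 1
    if (!any(has)) {
      message("motif ", m, " matches no peak; score undefined")
      return(data.frame(motif = m, score = NA_real_, nPeaks = 0L))
    }
    r <- mean(refMean[has])
    data.frame(motif = m, score = (mean(condMean[has]) - r) / r,
               nPeaks = sum(has), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Median d value of peaks containing a motif
#'
#' @param matches Motif match matrix (peaks x motifs).
#' @param dRecords data.frame `feature_id`, `d` (one dose).
#' @param motif Motif (or collapsed group) column name.
#' @param nBoot Bootstrap samples for the CI (default 1000).
#' @param level CI level (default 0.90).
#' @param seed Optional seed.
#' @return List: `median`, `ciLo`, `ciHi`, `nPeaks`; `NA`s when no peak
#'   contains the motif.
#' @export
motifConditionalD <- function(matches, dRecords, motif, nBoot = 1000,
                              level = 0.90, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  has <- rownames(matches)[matches[, motif] >= 1]
  vals <- dRecords$d[dRecords$feature_id %in% has]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0)
    return(list(median = NA_real_, ciLo = NA_real_, ciHi = NA_real_,
                nPeaks = 0L))
  ci <- if (length(vals) > 1) bootStat(vals, median, nBoot, level) else
    rep(vals, 2)
  list(median = median(vals), ciLo = ci[1], ciHi = ci[2],
       nPeaks = length(vals))
}

#' Welch's unequal-variances t-test
#'
#' Two-sided p value from Welch's t statistic with Satterthwaite degrees
#' of freedom; no multiple-comparison correction is applied. Degenerate
#' pairs of constant groups return p = 1 when the means agree and p = 0
#' when they differ.
#'
#' @param group1,group2 Numeric vectors (each of length >= 2).
#' @return Two-sided p value.
#' @export
welchTest <- function(group1, group2) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs at least 2 values")
  if (sd(group1) == 0 && sd(group2) == 0)
    return(if (mean(group1) == mean(group2)) 1 else 0)
  t.test(group1, group2, var.equal = FALSE)$p.value
}
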