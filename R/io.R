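## Reading and writing the pipeline's file formats, configuration, and the
## end-to-end driver.
##
## Formats: long-format TSV for expression (gene_id, sample_id, tpm) with a
## separate sample annotation TSV; BED3 for summits; BED-like TSV with
## count columns for peaks; TSV for DE results and motif matrices; BED6 for
## gene TSS annotations. All genomic coordinates on disk are 0-based
## half-open (BED convention); in-memory GRanges are 1-based.

checkFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  path
}

#' Read a sample annotation table
#'
#' TSV with columns `sample_id`, `signal`, `dose`, `replicate`.
#'
#' @param path File path.
#' @return data.frame, validated against [signalLevels()]/[doseLevels()].
#' @export
readSampleAnnotation <- function(path) {
  d <- read.delim(checkFile(path), stringsAsFactors = FALSE)
  need <- c("sample_id", "signal", "dose", "replicate")
  stopifnot(all(need %in% colnames(d)))
  key <- paste(d$signal, d$dose, d$replicate)
  if (anyDuplicated(key))
    stop("duplicated (signal, dose, replicate) at row ",
         which(duplicated(key))[1], " of ", path)
  d
}

#' Read a long-format expression table into a SignalExperiment
#'
#' @param path TSV with header `gene_id`, `sample_id`, `tpm`.
#' @param samples Sample annotation from [readSampleAnnotation()].
#' @return A [SignalExperiment].
#' @export
readExpressionTable <- function(path, samples) {
  d <- read.delim(checkFile(path), stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "sample_id", "tpm") %in% colnames(d)))
  key <- paste(d$gene_id, d$sample_id)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop("duplicated (gene, sample) pair at data row ", bad, " of ", path,
         ": ", key[bad])
  }
  genes <- sort(unique(d$gene_id))
  m <- matrix(NA_real_, length(genes), nrow(samples),
              dimnames = list(genes, samples$sample_id))
  m[cbind(match(d$gene_id, genes), match(d$sample_id, samples$sample_id))] <-
    d$tpm
  if (anyNA(m)) stop("expression table is not complete over genes x samples")
  SignalExperiment(m, samples$signal, samples$dose, samples$replicate)
}

#' Write a SignalExperiment as a long expression table + sample annotation
#'
#' @param se A [SignalExperiment].
#' @param exprPath,samplesPath Output TSV paths.
#' @export
writeExpressionTable <- function(se, exprPath, samplesPath) {
  cd <- colData(se)
  samples <- data.frame(sample_id = rownames(cd), signal = cd$signal,
                        dose = cd$dose, replicate = cd$replicate,
                        stringsAsFactors = FALSE)
  m <- assay(se)
  long <- data.frame(gene_id = rep(rownames(m), ncol(m)),
                     sample_id = rep(colnames(m), each = nrow(m)),
                     tpm = as.vector(m), stringsAsFactors = FALSE)
  writeTsv(long, exprPath)
  writeTsv(samples, samplesPath)
  invisible(c(exprPath, samplesPath))
}

#' Read a BED-like peak count table into a SignalExperiment
#'
#' TSV with header `chrom`, `start` (0-based), `end`, `peak_id`, then one
#' column per sample.
#'
#' @param path File path.
#' @param samples Sample annotation; sample ids must match the count
#'   columns.
#' @return A [SignalExperiment] with peak `rowRanges`.
#' @export
readPeakCounts <- function(path, samples) {
  d <- read.delim(checkFile(path), stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "peak_id") %in% colnames(d)))
  if (anyDuplicated(d$peak_id))
    stop("duplicated peak_id at row ", which(duplicated(d$peak_id))[1],
         " of ", path)
  miss <- setdiff(samples$sample_id, colnames(d))
  if (length(miss) > 0)
    stop("count columns missing for sample(s): ", paste(miss, collapse = ", "))
  gr <- GRanges(d$chrom, IRanges(start = d$start + 1L, end = d$end))
  names(gr) <- d$peak_id
  m <- as.matrix(d[, samples$sample_id, drop = FALSE])
  rownames(m) <- d$peak_id
  SignalExperiment(m, samples$signal, samples$dose, samples$replicate,
                   rowRanges = gr)
}

#' @rdname readPeakCounts
#' @param se A [SignalExperiment] with `rowRanges`.
#' @export
writePeakCounts <- function(se, path) {
  gr <- rowRanges(se)
  d <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                  end = end(gr), peak_id = names(gr),
                  stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(assay(se), check.names = FALSE))
  writeTsv(d, path)
}

#' Read per-replicate summit BED files
#'
#' @param paths Character vector of BED3(+) files, one per replicate.
#' @return List of width-1 `GRanges`.
#' @export
readSummits <- function(paths) {
  lapply(paths, function(p) {
    gr <- rtracklayer::import(checkFile(p), format = "BED")
    granges(gr)
  })
}

#' @rdname readSummits
#' @param summits List of `GRanges`.
#' @param dir Directory for `summits_rep<i>.bed`.
#' @export
writeSummits <- function(summits, dir) {
  vapply(seq_along(summits), function(i) {
    p <- file.path(dir, sprintf("summits_rep%d.bed", i))
    rtracklayer::export(summits[[i]], p, format = "BED")
    p
  }, character(1))
}

#' Read a gene TSS annotation (BED6-like TSV)
#'
#' Columns `chrom`, `start` (0-based TSS), `end`, `gene_id`, `score`,
#' `strand`; one canonical TSS per gene.
#'
#' @param path File path.
#' @return data.frame `gene_id`, `chrom`, `tss`, `strand`.
#' @export
readGeneAnnotation <- function(path) {
  d <- read.delim(checkFile(path), header = FALSE,
                  col.names = c("chrom", "start", "end", "gene_id", "score",
                                "strand"), stringsAsFactors = FALSE)
  if (anyDuplicated(d$gene_id))
    stop("gene with more than one TSS at row ",
         which(duplicated(d$gene_id))[1], " of ", path)
  data.frame(gene_id = d$gene_id, chrom = d$chrom, tss = d$start,
             strand = d$strand, stringsAsFactors = FALSE)
}

#' @rdname readGeneAnnotation
#' @param genes data.frame `gene_id`, `chrom`, `tss`, `strand`.
#' @export
writeGeneAnnotation <- function(genes, path) {
  d <- data.frame(genes$chrom, genes$tss, genes$tss + 1L, genes$gene_id, 0L,
                  if (is.null(genes$strand)) "+" else genes$strand)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression result table
#'
#' TSV with `gene_id`, `dose`, `log2fc`, `padj` for the combined
#' treatment.
#'
#' @param path File path.
#' @return data.frame.
#' @export
readDETable <- function(path) {
  d <- read.delim(checkFile(path), stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "dose", "log2fc", "padj") %in% colnames(d)))
  key <- paste(d$gene_id, d$dose)
  if (anyDuplicated(key))
    stop("duplicated (gene, dose) at row ", which(duplicated(key))[1],
         " of ", path)
  d
}

#' Read a motif match matrix
#'
#' TSV with a `peak_id` column followed by one column per motif.
#'
#' @param path File path.
#' @return Integer matrix, peaks x motifs.
#' @export
readMotifMatrix <- function(path) {
  d <- read.delim(checkFile(path), check.names = FALSE,
                  stringsAsFactors = FALSE)
  stopifnot("peak_id" %in% colnames(d))
  m <- as.matrix(d[, setdiff(colnames(d), "peak_id"), drop = FALSE])
  rownames(m) <- d$peak_id
  m
}

#' @rdname readMotifMatrix
#' @param matches Matrix with peak rownames.
#' @export
writeMotifMatrix <- function(matches, path) {
  d <- data.frame(peak_id = rownames(matches),
                  as.data.frame(matches, check.names = FALSE),
                  check.names = FALSE)
  writeTsv(d, path)
}

writeTsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Every tunable of the analysis with its default. Values are validated on
#' construction; [runPipeline()] refuses an invalid configuration before
#' any stage runs.
#'
#' @param ciLevel Confidence level of the classifier interval (0.80).
#' @param windowBp Peak-gene window (100000 bp).
#' @param fdrCellThreshold Per-cell FDR cut-off of the grid (0.0025).
#' @param mergeDistanceBp Peak merge distance (250 bp, inclusive).
#' @param minFc2,minCount2 Second-round thresholds (1.5, 30).
#' @param lfcMin,padjMax Master-set DE thresholds (0.5, 0.05).
#' @param reliabilityMinScale Reliability filter floor (2).
#' @param nSimsC,nSimsD Null simulations per gene (250) and per peak (10).
#' @param binWidth,histStep Histogram geometry (0.25, 0.125).
#' @param nPoissonReps Runs for the Poisson bin p values (1000).
#' @param nShuffles Dual-motif shuffles (1000).
#' @param nBootGenes,nBootPeaks Bootstrap samples for gene-level (10000)
#'   and peak-level (1000) CIs.
#' @param exclusivityThreshold Major-fraction threshold (0.9).
#' @param seed Integer seed for all stochastic stages.
#' @return Validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(ciLevel = 0.80, windowBp = 100000,
                           fdrCellThreshold = 0.0025, mergeDistanceBp = 250,
                           minFc2 = 1.5, minCount2 = 30, lfcMin = 0.5,
                           padjMax = 0.05, reliabilityMinScale = 2,
                           nSimsC = 250, nSimsD = 10, binWidth = 0.25,
                           histStep = 0.125, nPoissonReps = 1000,
                           nShuffles = 1000, nBootGenes = 10000,
                           nBootPeaks = 1000, exclusivityThreshold = 0.9,
                           seed = 1) {
  cfg <- as.list(environment())
  if (!is.numeric(ciLevel) || ciLevel <= 0 || ciLevel >= 1)
    stop("ciLevel must be a fraction in (0, 1)")
  if (windowBp < 0 || mergeDistanceBp < 0)
    stop("window and merge distances must be non-negative")
  if (fdrCellThreshold <= 0 || fdrCellThreshold >= 1)
    stop("fdrCellThreshold must be a fraction in (0, 1)")
  if (histStep > binWidth) stop("histStep must not exceed binWidth")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; unknown keys are an
#' error.
#'
#' @param path YAML file.
#' @return Validated `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(checkFile(path))
  unknown <- setdiff(names(vals), names(formals(pipelineConfig)))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' Load a dataset bundle from files
#'
#' Reads all inputs and verifies cross-references: peak ids in the motif
#' matrix must exist in the peak count table, and DE genes must carry a
#' TSS annotation; violations are dropped with a warning and recorded.
#'
#' @param paths Named list/vector with entries `expression`, `samples`
#'   (expression sample annotation), `peak_counts`, `peak_samples`,
#'   `summits` (vector of BED paths), `de`, `genes`, `motifs`.
#' @return List: `se`, `peakSe`, `summits`, `de`, `genes`, `motifs`,
#'   `excluded` (data.frame of dropped cross-references).
#' @export
loadDataset <- function(paths) {
  samples <- readSampleAnnotation(paths$samples)
  se <- readExpressionTable(paths$expression, samples)
  peakSamples <- readSampleAnnotation(paths$peak_samples)
  peakSe <- readPeakCounts(paths$peak_counts, peakSamples)
  summits <- readSummits(paths$summits)
  de <- readDETable(paths$de)
  genes <- readGeneAnnotation(paths$genes)
  motifs <- readMotifMatrix(paths$motifs)
  excluded <- data.frame(id = character(), table = character(),
                         reason = character(), stringsAsFactors = FALSE)
  orphanPeaks <- setdiff(rownames(motifs), rownames(peakSe))
  if (length(orphanPeaks) > 0) {
    warning(length(orphanPeaks),
            " motif-matrix peak(s) missing from the count table; excluded")
    excluded <- rbind(excluded, data.frame(
      id = orphanPeaks, table = "motifs", reason = "unknown_peak_id"))
    motifs <- motifs[setdiff(rownames(motifs), orphanPeaks), , drop = FALSE]
  }
  orphanGenes <- setdiff(unique(de$gene_id), genes$gene_id)
  if (length(orphanGenes) > 0) {
    warning(length(orphanGenes), " DE gene(s) lack a TSS annotation; flagged")
    excluded <- rbind(excluded, data.frame(
      id = orphanGenes, table = "de", reason = "missing_annotation"))
  }
  list(se = se, peakSe = peakSe, summits = summits, de = de, genes = genes,
       motifs = motifs, excluded = excluded)
}

#' Write a synthetic dataset bundle in the pipeline's file formats
#'
#' @param exprData Output of [generateExpressionData()].
#' @param peakData Output of [generatePeakData()].
#' @param motifs Motif match matrix.
#' @param genes Gene annotation data.frame.
#' @param dir Output directory (created).
#' @return Named list of written paths, usable with [loadDataset()].
#' @export
writeDataset <- function(exprData, peakData, motifs, genes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(expression = file.path(dir, "expression.tsv"),
            samples = file.path(dir, "samples.tsv"),
            peak_counts = file.path(dir, "peak_counts.tsv"),
            peak_samples = file.path(dir, "peak_samples.tsv"),
            de = file.path(dir, "de_combined.tsv"),
            genes = file.path(dir, "genes.bed"),
            motifs = file.path(dir, "motif_matrix.tsv"))
  writeExpressionTable(exprData$se, p$expression, p$samples)
  cd <- colData(peakData$se)
  writeTsv(data.frame(sample_id = rownames(cd), signal = cd$signal,
                      dose = cd$dose, replicate = cd$replicate),
           p$peak_samples)
  writePeakCounts(peakData$se, p$peak_counts)
  p$summits <- writeSummits(peakData$summits, dir)
  writeTsv(exprData$de, p$de)
  writeGeneAnnotation(genes, p$genes)
  writeMotifMatrix(motifs, p$motifs)
  writeTsv(exprData$truth, file.path(dir, "truth_genes.tsv"))
  writeTsv(peakData$truth, file.path(dir, "truth_peaks.tsv"))
  p
}

#' Write result tables and a manifest
#'
#' Writes every table as TSV with its column order preserved and returns a
#' manifest listing each file with its row count; the manifest itself is
#' written as `manifest.tsv`.
#'
#' @param tables Named list of data.frames.
#' @param outDir Output directory (created if possible).
#' @return data.frame manifest (`file`, `rows`), invisibly.
#' @export
writeResults <- function(tables, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  files <- character(0); rows <- integer(0)
  for (nm in names(tables)) {
    f <- paste0(nm, ".tsv")
    writeTsv(as.data.frame(tables[[nm]]), file.path(outDir, f))
    files <- c(files, f); rows <- c(rows, nrow(tables[[nm]]))
  }
  manifest <- data.frame(file = files, rows = rows, stringsAsFactors = FALSE)
  writeTsv(manifest, file.path(outDir, "manifest.tsv"))
  invisible(manifest)
}

stageMsg <- function(...) message("[comboResponse] ", ...)

#' Run the full analysis pipeline
#'
#' Executes the stages in order — noise model, response estimates,
#' categorical classification, c/d values, null simulations, differential
#' peak calling, regulatory integration — on a dataset bundle (from
#' [loadDataset()] or assembled in memory), writing every result table
#' plus a manifest to `outDir`. All stochastic stages derive their seeds
#' from `config$seed`, so outputs are a pure function of (inputs, config,
#' seed).
#'
#' @param config A [pipelineConfig()].
#' @param data Dataset bundle: list with `se`, `peakSe`, `summits`, `de`,
#'   `genes`, `motifs` (see [loadDataset()]).
#' @param outDir Output directory.
#' @param dose Dose at which single-dose integration analyses are run
#'   (default `"medium"`).
#' @return Invisibly, a list with `status` (0 on success), the `manifest`,
#'   and the in-memory `tables`.
#' @export
runPipeline <- function(config, data, outDir, dose = "medium") {
  stopifnot(inherits(config, "PipelineConfig"))
  set.seed(config$seed)
  tables <- list()

  stageMsg("stage 1/6: noise model (seed ", config$seed, ")")
  noise <- estimateNoise(data$se)
  resp <- responseEstimates(data$se, noise, ciLevel = config$ciLevel)
  tables$gene_responses <- resp

  stageMsg("stage 2/6: categorical classification")
  geneClass <- classifyGeneResponses(resp)
  tables$gene_classification <- geneClass

  stageMsg("stage 3/6: master set, c values, dose trajectories")
  master <- selectMasterSet(data$de, resp, config$lfcMin, config$padjMax)
  tables$master_set_exclusions <- master$excluded
  cTab <- cValueTable(resp, master$genes, config$reliabilityMinScale)
  tables$c_values <- cTab
  traj <- doseTrajectories(cTab)
  tables$c_trajectories <- traj$full

  stageMsg("stage 4/6: null simulations (seed ", config$seed + 1, ")")
  masterResp <- resp[resp$feature_id %in% master$genes, , drop = FALSE]
  addSim <- simulateNull(masterResp, "additive", "c", config$nSimsC,
                         seed = config$seed + 1)
  w <- mixtureWeights(geneClass)
  w[is.na(w)] <- 0.5
  mixSim <- simulateNull(masterResp, "mixture", "c", config$nSimsC,
                         mixtureProbAdd = w, seed = config$seed + 2)
  obsC <- cTab$c[cTab$dose == dose & is.finite(cTab$c)]
  rng <- c(-5, 6)
  obsH <- slidingHistogram(pmax(pmin(obsC, rng[2] - 0.01), rng[1]),
                           config$binWidth, config$binWidth, rng)
  simMix <- mixSim$value[mixSim$dose == dose & is.finite(mixSim$value)]
  mixH <- slidingHistogram(pmax(pmin(simMix, rng[2] - 0.01), rng[1]),
                           config$binWidth, config$binWidth, rng)
  sc <- fitMixtureScale(obsH, mixH)
  addPart <- mixSim$value[mixSim$dose == dose & is.finite(mixSim$value) &
                            mixSim$assigned_mode == "additive"]
  addH <- slidingHistogram(pmax(pmin(addPart, rng[2] - 0.01), rng[1]),
                           config$binWidth, config$binWidth, rng)
  fit <- residualSecondaryPeak(obsH, addH, sc)
  tables$residual_fit <- data.frame(mu = fit$mu, sigma = fit$sigma,
                                    amplitude = fit$amplitude,
                                    converged = fit$converged,
                                    degenerate = fit$degenerate)
  pv <- poissonBinPvalues(obsC, masterResp[masterResp$dose == dose, ],
                          config$binWidth, config$histStep,
                          config$nPoissonReps, seed = config$seed + 3)
  tables$c_bin_pvalues <- pv

  stageMsg("stage 5/6: differential peak calling")
  cons <- consensusPeaks(data$summits)
  tables$consensus_peaks <- as.data.frame(cons)
  norm <- normalizeCounts(assay(data$peakSe))
  cd <- colData(data$peakSe)
  sampleInfo <- data.frame(signal = cd$signal, dose = cd$dose,
                           stringsAsFactors = FALSE)
  grid <- fdrGrid(norm, sampleInfo)
  r1 <- callDifferentialPeaks(grid, config$fdrCellThreshold)
  r2 <- mergeAndRecall(r1, rowRanges(data$peakSe), norm, sampleInfo,
                       config$mergeDistanceBp, config$minFc2,
                       config$minCount2)
  tables$differential_peaks <- data.frame(
    peak_id = r2$differentialPeaks, stringsAsFactors = FALSE)
  tables$peak_fdr <- data.frame(round = c(1, 2),
                                pooledFdr = c(r1$pooledFdr, r2$pooledFdr),
                                nPeaks = c(length(r1$peaks),
                                           length(r2$differentialPeaks)))

  normSe <- SignalExperiment(norm, cd$signal, cd$dose, cd$replicate,
                             rowRanges = rowRanges(data$peakSe))
  peakResp <- responseEstimates(normSe, ciLevel = config$ciLevel)
  peakClass <- classifyPeakResponses(peakResp)
  tables$peak_classification <- peakClass
  dTab <- dValueTable(peakResp)
  tables$d_values <- dTab

  stageMsg("stage 6/6: regulatory integration (seed ", config$seed + 4, ")")
  links <- linkPeaksToGenes(rowRanges(data$peakSe), data$genes,
                            config$windowBp)
  tables$peak_gene_links <- links
  gc1 <- geneClass[geneClass$dose == dose & !is.na(geneClass$category),
                   c("feature_id", "category")]
  pc1 <- peakClass[peakClass$dose == dose & !is.na(peakClass$category),
                   c("feature_id", "category")]
  tables$peak_counts_by_gene_category <- peakClassCountsByGeneCategory(
    links, pc1, gc1, config$nBootGenes, seed = config$seed + 4)
  excl <- labelExclusivePeaks(peakResp, config$exclusivityThreshold)
  tables$peak_exclusivity <- excl
  tables$dual_dominant_fraction <- dualDominantGeneFraction(
    links, excl[excl$dose == dose, ], gc1, config$nBootGenes,
    seed = config$seed + 5)
  groups <- motifGroups()
  tables$motif_density <- motifDensity(
    rowRanges(data$peakSe), data$motifs, pc1, groups, config$nBootPeaks,
    seed = config$seed + 6)
  tables$dual_motif_null <- dualMotifShuffleNull(
    pc1, data$motifs, groups, config$nShuffles, seed = config$seed + 7)
  tables$motif_enrichment <- motifEnrichmentScore(
    data$motifs, norm, sampleInfo, "both")

  manifest <- writeResults(tables, outDir)
  stageMsg("done: ", nrow(manifest), " tables written to ", outDir)
  invisible(list(status = 0L, manifest = manifest, tables = tables))
}
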