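# comboResponse

When two signals (for example retinoic acid and TGF-β) each upregulate a
gene, does the combination add the two effects, multiply the two fold
changes, or something in between? `comboResponse` implements a statistical
pipeline for answering that question jointly from bulk RNA-seq (TPM) and
ATAC-seq (fragment counts) dosing experiments, aimed at computational
biologists analysing factorial signal-response designs.

At its core are two statistics. For a gene with baseline $x_0$ and
individual effects $\Delta_A = \bar{x}_A - x_0$, $\Delta_B = \bar{x}_B - x_0$,
the **combined response factor**

$$c = (x_{AB} - x_0 - \Delta_A - \Delta_B)\cdot\frac{x_0}{\Delta_A\Delta_B}$$

is 0 when the combined expression $x_{AB}$ equals the additive prediction
$x_0+\Delta_A+\Delta_B$ and 1 when it equals the multiplicative one
$x_0\frac{\bar{x}_A}{x_0}\frac{\bar{x}_B}{x_0}$. For an ATAC-seq peak, the
**d value** $d = x_{AB}/\mathrm{pred}_{add} - 1$ measures the fold-change
deviation of the combined accessibility from additivity.

Around these, the package provides:

* a shared-CV Gaussian noise model (one coefficient of variation per
  feature and signal, pooled across doses with the small-sample corrected
  estimator $(1+\frac{1}{4n})s/\bar x$) and an 80%-interval classifier of
  responses as sub-additive / additive / multiplicative /
  super-multiplicative / ambiguous;
* Monte Carlo nulls (folded-Gaussian resimulation with the combined mean
  pinned to either prediction), mixture fitting, residual secondary-peak
  Gaussian fits, and sliding-bin Poisson p values;
* a differential ATAC-seq peak caller: consensus 150 bp summit peaks
  (majority rule), reads-in-peaks normalization, a 50×50 empirical-FDR
  threshold grid calibrated on extra cell-density controls, and two-round
  merging;
* regulatory integration: peak–gene linking in 100 kb TSS windows,
  signal-exclusive peak labels, motif-group densities and enrichment
  scores, a total-preserving dual-motif shuffle null, bootstrap CIs, and
  Welch tests;
* a synthetic-data generator with known ground truth (and writers/readers
  for every file format), so the entire pipeline is testable end to end.

## Worked example

A single gene at ~100 TPM rises to ~200 under signal A and ~300 under
signal B; the additive and multiplicative anchors are therefore 400 and
600 TPM. Suppose the combined treatment lands around 580:

```r
library(comboResponse)
computeC(100, 100, 200, 400)  # combined equals the additive prediction
#> [1] 0
computeC(100, 100, 200, 600)  # equals the multiplicative prediction
#> [1] 1

set.seed(1)
vals <- rbind(
  control = abs(rnorm(3, 100, 8)),
  signalA = abs(rnorm(3, 200, 16)),
  signalB = abs(rnorm(3, 300, 24)),
  both    = abs(rnorm(3, 580, 46)))
m <- matrix(as.vector(t(vals)), nrow = 1, dimnames = list("geneX", NULL))
se <- SignalExperiment(m,
  signal    = rep(c("control", "signalA", "signalB", "both"), each = 3),
  dose      = rep(c("none", "medium", "medium", "medium"), each = 3),
  replicate = rep(1:3, 4))
r <- classifyGeneResponses(responseEstimates(se))
round(r[, c("x0", "dA", "dB", "xAB", "ciLo", "ciHi", "predAdd", "predMult")], 1)
#>     x0    dA    dB   xAB  ciLo ciHi predAdd predMult
#> 1 96.6 109.3 217.8 604.5 545.9  663   423.7    670.2
as.character(r$category)
#> [1] "between_add_mult"
round(computeC(r$x0, r$dA, r$dB, r$xAB), 2)
#> [1] 0.73
```

The additive prediction (423.7) falls below the 80% interval of the
combined treatment while the multiplicative one (670.2) falls above it, so
the response is classified between addition and multiplication; the
continuous c value of 0.73 places it 73% of the way from the additive to
the multiplicative anchor.

On a synthetic cohort the machinery recovers planted ground truth — here
300 genes generated with a true c of 0.5 everywhere:

```r
cfg <- synthConfig(nGenes = 300, cTrue = 0.5, seed = 42)
g    <- generateExpressionData(cfg)
resp <- responseEstimates(g$se)
ct   <- cValueTable(resp, masterGenes = g$truth$gene_id)
rel  <- ct$reliable & ct$dose == "medium"
round(mean(ct$c[rel]), 3)
#> [1] 0.465
```

`runPipeline()` ties all stages together on a dataset bundle (see
`loadDataset()` for the file formats, or `inst/scripts/combosig.R` for a
small command-line wrapper with `simulate` and `all` subcommands).

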