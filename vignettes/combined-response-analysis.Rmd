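---
title: "Quantifying how two signals combine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying how two signals combine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboResponse)
```

## The question

When a cell receives two signals at once — here signal A (retinoic acid) and
signal B (TGF-β) in the dosing design the package models — how does a gene
that responds to each signal individually respond to both together? Two
simple phenomenological anchors exist. If the effects act on independent
steps, the *changes* add: a gene at baseline $x_0$ with individual effects
$\Delta_A$ and $\Delta_B$ reaches $x_0 + \Delta_A + \Delta_B$. If the
effects act multiplicatively (say, on independent probabilities of
transcriptional bursting), the *fold changes* multiply:
$x_0 \cdot \frac{x_0+\Delta_A}{x_0} \cdot \frac{x_0+\Delta_B}{x_0}$. For a
gene going from 100 to 200 copies under A and to 300 under B, the two
anchors predict 400 and 600 copies.

The package turns this comparison into a tested pipeline: a noise model and
categorical classifier, a continuous statistic (the c value) locating each
gene between the anchors, its chromatin analogue (the d value) for ATAC-seq
peaks, Monte Carlo nulls, an empirical-FDR differential peak caller, and
peak/motif integration analyses — all exercisable on synthetic data with
known ground truth.

## Noise model

Each replicate observation (TPM for genes, normalized fragment counts for
peaks) is modelled as a draw from
$\mathrm{Gaussian}(\bar{x},\ (\bar{x}\cdot\mathrm{CV})^2)$, with a single
coefficient of variation shared by all doses of a signal. Per dose the CV
uses the small-sample corrected estimator
$(1 + \tfrac{1}{4n})\, s/\bar{x}$ and the shared value is the arithmetic
mean over the $m$ doses. With three replicates and three doses this moves
the variance estimate from three to nine samples' worth of information. A
dose with non-positive mean contributes no CV term; a feature whose
baseline is non-positive is flagged invalid rather than classified.

The classifier's interval is the central 80% (default `ciLevel = 0.80`) of
the estimated Gaussian of *single observations* of the combined treatment:
$\bar{x}_{AB} \pm z_{0.9}\,\bar{x}_{AB}\widehat{\mathrm{CV}}_{both}$.
Normal ($z$) rather than $t$ quantiles are used, because the interval
describes the modelled observation noise with its plug-in CV, not the
sampling distribution of a mean with estimated variance. Interval
endpoints are inclusive, so a prediction exactly at a bound counts as
inside; this avoids measure-zero flip-flops in tests and can only affect
results on ties.

Genes are classified by where the two anchor predictions fall relative to
the interval (sub-additive, additive, between, multiplicative,
super-multiplicative, ambiguous); peaks use the additive anchor only
(sub-additive / additive / super-additive, with "prediction above the
interval" meaning the observed accessibility fell short of additivity).

## The c and d values

$$c = \left(x_{AB} - x_0 - \Delta_A - \Delta_B\right)
      \cdot \frac{x_0}{\Delta_A \Delta_B}$$

is the unique statistic linear in $x_{AB}$ with $c = 0$ at the additive and
$c = 1$ at the multiplicative prediction; the interaction scale
$\Delta_A\Delta_B/x_0$ is exactly the gap between the two predictions. The
estimate is undefined for $x_0 \le 0$ or $\Delta_A\Delta_B = 0$, and its
noise scales with the reciprocal of the interaction scale — hence the
reliability filter $\Delta_A\Delta_B/x_0 \ge 2$ (measurement units) and
$\ge x_0$, both boundaries inclusive. For peaks the package reports
$d = x_{AB}/\mathrm{pred}_{add} - 1$, a plain ratio-minus-one rather than a
log2 ratio: a distribution of additive peaks then centers at 0 and the
statistic stays linear in the observation. The combined observation for a
peak is the mean over replicates of the peak integral (summed normalized
fragment counts in the interval).

Only upregulated genes are analysed for c (the master set): significantly
upregulated in at least one dose of the combined treatment (defaults
log2FC ≥ 0.5, BH-adjusted p ≤ 0.05, both configurable) with positive
individual effects at every dose; zero-baseline genes are excluded because
their c degenerates to 0 identically.

## Null simulations

New replicate sets are drawn from folded Gaussians — the absolute value of
a Gaussian draw, which avoids negative expression while changing means
negligibly at the CVs considered (folding mass is $<10^{-3}$ for
$\mathrm{CV} \le 0.3$) — with the fitted per-condition parameters, except
that the combined mean is replaced by the additive or multiplicative
prediction. Means of the simulated replicates feed the same c/d
computation. Defaults are 250 simulations per gene per dose and 10 per
peak. Mixture mode assigns each feature additive behaviour with the
observed per-dose frequency of additive classifications renormalized over
the additive and multiplicative categories only.

Histograms use 0.25-wide bins; overlapping (sliding) bins advance by half
a bin width (0.125), a symmetric tiling that places bin edges exactly at 0
and 1. The mixture histogram is scaled to the observed one by the closed
form least-squares factor over the four bars directly abutting c = 0 and
c = 1. The residual after subtracting the scaled additive component is fit
with a Gaussian density by nonlinear least squares (`nls`, port algorithm,
with an `nlsLM` fallback), locally in $c \in [-4, 5]$; a residual with no
positive mass is flagged degenerate instead of fitted. Per-bin Poisson
p values use 1000 re-simulated additive cohorts (one observation per
gene), scale the observed histogram to the simulated peak height at c = 0
(defined as the summed counts of the two bars abutting 0), and report the
upper tail $P(\mathrm{Poisson}(\lambda) \ge k)$; bins whose *center* lies
inside the open exclusion zone $(-0.3, 0.3)$ are omitted because there the
additive peak itself dominates.

## Differential peak calling

Summits from different replicates group when their 150 bp nucleosome-sized
windows overlap (summit distance < 150 bp, single linkage); groups backed
by at least two distinct replicates emit one 150 bp peak at the median
summit. Per-condition peak sets merge into a non-overlapping master
consensus. Counts are normalized by each sample's reads-in-peaks total
over the cross-sample mean, which conserves the grand total.

The caller lays a 50 × 50 grid of geometric thresholds — minimum fold
change 1.1 to 10, minimum count 10 to 237, endpoints inclusive — and in
each cell calls a peak differential for a condition when the two-sided
pseudocounted fold change versus the reference control meets the
fold-change threshold and the larger of the two means meets the count
threshold. The extra density controls (50% and 150% seeding, biologically
null versus the reference) provide the false-positive estimate: cell FDR =
(number of experimental conditions × mean differential calls in the extra
controls) / total experimental calls. Calls from every cell with FDR below
0.25% are pooled, the pooled FDR is re-estimated on that union, peaks
within 250 bp (inclusive) are merged with counts summed, and a second pass
applies fixed thresholds (fold change ≥ 1.5, count ≥ 30) per condition
versus the reference. The pseudocount of 1, the two-sided fold change, and
per-condition-vs-reference semantics in round two are the package's
choices where the procedure description is silent. Note an intrinsic
property of the empirical estimate: on *pure-null* data the union rule
preferentially collects cells whose control-call count happens to be zero,
so the pooled estimate can understate the (trivially 100%) realized FDR of
a tiny fluke set; calibration is therefore tested on spike-in cohorts
where true positives dominate the calls.

## Regulatory integration

Peak–gene links use the distance from the canonical TSS to the peak
midpoint, linked when ≤ 100 kb (inclusive); the window is symmetric and
strand-agnostic, and a peak linking to several genes counts once per gene.
A peak is signal-exclusive when one signal's absolute effect is at least
90% of the summed absolute effects (≥ 9× the minor effect), boundary
inclusive. Motifs collapse to groups by the maximum member count per peak
(so three JUN + two FOS + two JDP2 + one BACH1 count as three AP-1
matches); densities are per 150 bp of peak width. The dual-motif null
redistributes the collapsed group labels uniformly within each peak class
while fixing every peak's total match count — a zero-match peak stays at
zero through every shuffle. The RA-dominant set includes the retinoic acid
receptor group alongside FOX and ETS by default; the shipped
`motif_groups.tsv` resource makes the grouping editable because the
narrative and methods descriptions of the source analysis differ on RAR's
membership. Bootstrap intervals are percentile intervals at 90%,
resampling the analysis unit (genes for per-gene-category tables, peaks
for per-peak-class tables; 10000 and 1000 resamples by default). Group
comparisons use Welch's unequal-variances t-test with no
multiple-comparison correction.

## What the synthetic generator does and does not emulate

The generator draws per-feature baselines log-uniformly (1–500 TPM for
genes, 20–500 normalized counts for peaks), per-signal fold changes
log-uniformly (1.5–4 for genes, 1.25–3 for peaks — spanning the modest
accessibility responses and larger transcriptional responses typical of
these treatments), per-feature per-signal CVs uniformly in 0.05–0.3, and
scales effects across doses by 0.5/1/1.5. Combined means follow the c (or
d) construction exactly, replicates are folded-Gaussian draws, extra
density controls are drawn from the identical control distribution (so
every differential call against them is false by construction), summits
are jittered per replicate with configurable dropout, and motif matches
are Poisson or, with clustering, negative-binomial across peaks.

This emulates exactly the statistical structure the estimators assume.
Passing tests therefore demonstrate correctness of the *procedures* —
identities, calibration, parameter recovery, FDR behaviour — not
robustness to the ways real data violate the model: count overdispersion
beyond a shared CV, correlated replicates, batch effects, mappability and
GC artefacts, peak-width variation, or sequence-driven motif co-occurrence
are all outside the generator.

## Numerical and scale choices

Undefined quantities are `NA` with recorded reasons, never silent zeros.
Geometric grids use $r_i = a (b/a)^{(i-1)/49}$, endpoints exact. The
pipeline derives every stage seed from one configured seed, so outputs are
a pure function of inputs, configuration and seed. Simulation-heavy checks
in the test suite run on cohorts of 150–500 genes and up to 2000 peaks
with 20–250 simulations per feature; these sizes give Monte Carlo error
comfortably below the asserted tolerances (for example, the pooled median
of 125 000 simulated c values has a standard error well under 0.01) while
the whole suite stays quick on a laptop. One calibration note: the
realized coverage of the 80% classifier interval on truly additive
synthetic peaks runs a few points below nominal (about 75–78%), because
the interval plugs in a CV estimated from nine samples and compares a
prediction that is itself built from three estimated means; the
acceptance checks state their tolerance around this behaviour rather than
pretending the plug-in interval is exact.

## Known limitations

Downregulated and mixed-sign responses are out of scope, as in the
analysis the package models. The noise model is Gaussian with a shared CV,
not a count model; no shrinkage or empirical-Bayes variance moderation is
applied. The mixture model considers only two components. Read alignment,
fragment counting, peak summit calling and DE model fitting are upstream:
the package consumes their outputs (summit BED files, count tables, a DE
table) and the synthetic generator provides surrogates for testing.
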