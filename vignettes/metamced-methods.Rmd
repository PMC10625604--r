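---
title: "Two-tier serum metabolomics cancer detection: models and methods"
author: "metamced"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier serum metabolomics cancer detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multi-cancer early detection (MCED) from serum asks two questions of a
single blood draw: *is there a cancer signal at all*, and if so, *which
tissue did it come from*. `metamced` implements a two-tier answer built on
untargeted LC-MS metabolomics. Tier 1 (the cancer-detection model, CDAI)
is a binary linear scorer over aligned metabolite intensities; tier 2 (the
tissue-of-origin model, TOOAI) is a 15-class one-vs-rest scorer applied
only to samples tier 1 calls cancer-positive, judged by both its best
guess (top-1) and its best two guesses (double-class, top-2). Everything
upstream of the models — peak alignment, normalization, imputation,
feature reduction — is part of the method and is implemented and tested
here.

## Virtual lock-mass alignment

Across runs the same metabolite is observed at slightly different m/z;
the error is multiplicative, so it grows with mass and is naturally
expressed in parts per million. The package aligns peak lists by *virtual
lock-mass* (VLM) windows anchored on a metabolite reference table: one
window per reference mass $M$, spanning $M(1 \pm \tau \cdot 10^{-6})$ with
$\tau$ the tolerance in ppm. The default $\tau = 5$ matches the
instrument-level mass accuracy. A peak inside several windows goes to the
window with the smallest absolute ppm deviation from center, ties broken
toward the lower mass (a total order, so assignment is reproducible and
independent of peak order). Several peaks in one window for one sample
keep the maximum intensity. Retention time is deliberately *not* used for
matching: the window definition is mass-only, and the packaged peak lists
carry retention time for bookkeeping only.

Windows inherit the reference's mass spacing: reference masses closer
than about $2\tau$ ppm yield overlapping windows, which `buildBoxes()`
reports rather than merges. After assembly, features flagged drug- or
plant-derived in the reference are removed (`trimMatrix()`), leaving the
endogenous feature matrix, held as an `MCEDExperiment`
(a `SummarizedExperiment`: features in rows, samples in columns, `NA`
marking cells with no assigned peak).

## Preprocessing recipes

Two recipes are implemented, one per tier, each fit strictly on training
samples and frozen for application to held-out samples — no fit step ever
sees a test row or a test label.

**Detection (CDAI) recipe:** prevalence filter → quantile normalization →
uniform k-nearest-neighbour imputation.

**Tissue-of-origin (TOOAI) recipe:** prevalence filter → log10 transform →
quantile normalization → standard-scaler standardization → *selective*
KNN imputation of the training set only, within each class; test samples
are left non-imputed.

Parameter choices, with rationale:

* `minPrevalence = 0.1`: features observed in under 10% of samples are
  noise-dominated; the threshold is a package default (the filtering step
  itself is prescribed, its threshold is not).
* Quantile normalization is implemented *reference-based* so that a single
  new sample can be normalized against the training distribution: the
  reference is the mean of each sorted-intensity position over training
  samples; application substitutes the reference quantile at each
  observed value's within-sample rank. Ties receive the mean of the
  reference values their positions span; samples with missing cells use
  linear rank interpolation over their observed positions. On a complete,
  tie-free training sample this reproduces classic pooled quantile
  normalization exactly, and the operation is idempotent. The reference
  pools all training rows (cancers and normals alike).
* `pseudocount` for the log10 transform defaults to half the smallest
  nonzero training intensity — standard practice for zero-inflated
  intensity data.
* KNN imputation uses `k = 5` neighbours by Euclidean distance over
  mutually observed features (scaled by the fraction observed), mean of
  the neighbours' values; observed cells are never altered. The selective
  policy confines each training row's neighbour pool to its own class, so
  class signatures are not smeared across classes; test rows stay
  non-imputed and their missing cells enter the linear scores as 0 —
  which, after standardization, is the training mean, the least
  informative value.

## Tier 1: the detection score

The detection model is an L2-regularized (ridge) logistic regression
exposing the affine score

$$y_\mathrm{score} = x_0 + \sum_{i=1}^{n} x_i I_i$$

over the processed intensities $I_i$. A score at or above the threshold
(default 0, the logistic decision boundary) is called cancer; the exact
tie goes to cancer, since a screening context prefers sensitivity and the
event has measure zero. Class balancing (inverse-frequency sample
weights) is on by default to counter the cancer:normal imbalance.

The ridge penalty $\lambda$ defaults to 1, applied to internally
standardized features (the penalty must be scale-aware: quantile-normalized
raw intensities span several decades, and an unstandardized penalty is
effectively zero). $\lambda = 1$ is a conventional default that keeps
small-cohort fits stable; it is exposed as `regularization` everywhere.

Performance is summarized by repeated stratified random train/test splits
(`crossValidateCDAI()`; half-and-half by default, 1000 splits at study
scale) with the *full preprocessing refit on each training half*, and
percentile 95% confidence intervals — metric distributions near 100% are
skewed, so normal-approximation intervals would be wrong.

## Feature reduction and ranking

PLS-DA (partial least squares against one-hot class indicators, via
`mixOmics`) supplies supervised feature reduction: per-feature importance
is the sum over components of squared loading weights, `plsdaReduce()`
keeps the top-$n$ features. $R^2$ is the fraction of indicator variance
explained on the training set; $Q^2$ its 5-fold cross-validated analogue
(fold count is a package default; the precise importance statistic and
component count are not pinned down by the method description, and the
VIP-like sum of squared loading weights is the package's choice).

Feature *ranking* uses recursive feature elimination: refit a linear
trainer, drop the feature with the smallest absolute weight (ties broken
toward the lexicographically first feature id), repeat; the last survivor
has rank 1. One-at-a-time elimination is $O(n^2)$ fits; `stepSize`
trades fidelity for speed at large $n$ but defaults to 1.

## Tier 2: tissue of origin with double-class accuracy

One linear scorer per cancer class, one-vs-rest; class $k$ emits

$$P(k) = \frac{1}{1 + e^{-(a_k + \mathbf{w}_k \cdot \mathbf{I})}},$$

a sigmoid-mapped linear score with one intercept per class. The published
formulas write the sigmoid with the opposite sign convention and mix two
intercept symbol families; the package stores one intercept and one
weight vector per class, oriented so that a larger linear score means
"more likely class $k$". Scores are *not* renormalized across classes
(they need not sum to 1); a per-class sigmoid score is what the decision
rules consume. Top-1 and top-2 decisions take the largest and two largest
scores, ties broken lexicographically by label.

The default family is a linear support-vector machine per class (with
inverse-frequency class weights); ridge logistic one-vs-rest is the
alternative. A small hyperparameter grid (SVM cost) is selected by
held-out top-1 accuracy on an internal stratified 75/25 split, then the
model is refit on all training rows.

Double-class accuracy is the percentage of samples whose true class lies
in the top two predictions — never below top-1 accuracy, with equality
exactly when no sample is rescued by its second guess. The double-class
confusion matrix credits a top-2 hit to the diagonal; a full miss is
counted at (truth, top-1), which keeps row sums equal to per-class sample
counts (the off-diagonal target for a miss is otherwise ambiguous; top-1
is the package's convention).

The tiered contract is strict: tier 2 sees exactly the set of samples
tier 1 called cancer-positive. `runPipeline()` enforces and audits this.

## The synthetic cohort generator

No public spectra accompany the study design this pipeline targets, so
the generator is a first-class, tested module that emulates the
statistical structure the analysis assumes:

* **Reference**: unique metabolite ids with masses uniform over the
  instrument scan range (66.7–1000 Da), ~10% flagged drug-derived and
  ~10% plant-derived so origin trimming is exercised.
* **Intensity model**: per-metabolite log10-normal baseline, uniform over
  4.5–7 (typical LC-MS dynamic range); class effects add a fixed log10
  shift to each cancer class's signature metabolites (the normal class is
  all-zero by convention); a per-batch log10 shift models batch drift; iid
  per-observation log10 noise completes the model. The log-additive form
  matches the log10 transform the tissue-of-origin recipe applies.
* **Mass error**: multiplicative Gaussian in ppm — relative errors are
  what the instrument bounds, and absolute errors grow with mass.
  `ppmErrorSd` defaults to 5 (the instrument accuracy figure read as a
  standard deviation). For end-to-end study cohorts the package instead
  reads "5 ppm accuracy" as a 3-sigma bound and simulates
  `ppmErrorSd = 5/3`: with 5 ppm windows, a 5 ppm *standard deviation*
  would place roughly a third of all peaks outside their own window,
  which no working assay tolerates.
* **Dropout**: independent per (sample, metabolite) with probability
  `dropoutRate` (default 0.1), optionally weighted toward low intensities
  through a logistic term (`dropoutDependence`), emulating
  intensity-dependent missingness.
* Perturbed m/z values are clipped to the scan range, keeping peak counts
  deterministic; a fixed seed makes the whole cohort bit-exact, and the
  batch shifts can be redrawn alone (`batchSeed`) for repeated-run
  studies.

What the generator does **not** emulate: chromatographic peak shapes,
isotope/adduct envelopes (one peak per metabolite per sample), correlated
metabolite panels, retention-time drift, and real serum biology. Passing
tests on these cohorts therefore demonstrate that the *pipeline machinery*
is correct and self-consistent under the stated statistical structure —
not that any particular clinical accuracy would be attained on real sera.

## Robustness harness

`robustnessHarness()` freezes a trained detection pipeline, regenerates
the same cohort repeatedly with fresh batch-level shifts only, and
reports per-run per-class sensitivity plus the coefficient of variation
of the pooled (net) sensitivity across runs. Net sensitivity is pooled
counts (total correct over total tested), not the mean of per-class
values; both conventions appear in practice and the per-class table is
returned so either can be recomputed. With zero batch noise every run is
identical and the CV is exactly 0.

## Numerical choices and degenerate inputs

* Percentages are computed in exact rational form and rendered at one
  decimal with round-half-even (`formatPct()`).
* ROC-AUC is the tie-corrected rank statistic (Mann–Whitney over
  positive–negative pairs), invariant under monotone score transforms.
* Zero-variance features: the standard scaler centers them, treats their
  sd as 1, and flags them; PLS-DA drops constant features with a warning
  and refuses an all-constant matrix.
* A sample with no observed features is an error everywhere (it cannot be
  ranked, normalized or imputed); all-missing test cells that no
  neighbour can fill remain missing and score as 0.
* Deterministic tie-breaks throughout: lower-mass box on ppm ties,
  lexicographic feature id in RFE, lexicographic label in top-k decisions.
* All simulation and split randomness flows from explicit integer seeds;
  refitting with the same seed reproduces models bit-exactly.

## Problem sizes used in the packaged analyses

The packaged test-suite and the acceptance analysis run a scaled-down
cohort: a 300-metabolite reference, 16 classes (15 cancers + normal) at
40 samples per class, 30-metabolite class signatures at +0.5 log10,
observation noise 0.2 log10, 10% dropout, 3 batches; 20 random splits for
the detection tier, 10 for the tissue-of-origin tier, and a 10-run
robustness study on the per-class batch template
(25/25/23/25/24/24/15/12/15/12/10/12/15/15/15). These sizes keep a full
desk run in the order of a minute while exercising every stage at
realistic dimensionality ratios.

## Known limitations

* With 40 samples per class, a half split leaves only 20 normal controls
  to estimate the normal centroid against 300 cancers in a ~255-feature
  space; the detection tier's specificity is then estimation-limited, and
  materially below its sensitivity, at the packaged cohort size. The
  study design this emulates used 300 normal controls — the largest
  single group in its cohort — and the limitation vanishes as the normal
  arm grows. The packaged analyses report what the stated cohort size
  actually achieves rather than tuning the generator around it.
* Reference-based quantile normalization forces every sample onto one
  value multiset; when class signatures cover a large fraction of the
  feature space (unavoidable when 15 × 30 signature metabolites are drawn
  from a few hundred), rank displacement partially cancels along
  signature directions. At study-scale feature counts (thousands of
  features, signatures a small minority) the distortion is small.
* The exact mechanics of upstream gap filling are not modelled: all
  filling is deferred to the imputation stage so it is not applied twice.
* The alternative normalizations evaluated and rejected in the source
  method (variance stabilization, probabilistic quotient, L1/L2 norms)
  are not implemented.
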