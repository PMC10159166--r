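---
title: "Methods: unbalanced chemical-stimulus classification from plant electrical signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unbalanced chemical-stimulus classification from plant electrical signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `plantstim`, the
choices made where the design was genuinely open, and what the synthetic
benchmark can and cannot say about real recordings.

## The analysis problem

The pipeline addresses a three-class recognition problem: given a
1024-sample window (at 10 Hz) of the high-pass-filtered electrical
potential of a plant stem, decide which chemical stimulus — NaCl, H₂SO₄
or O₃ — the plant was exposed to. Class counts are extremely unbalanced
(ozone experiments run far longer, contributing ~94% of windows), so the
evaluation machinery, not only the classifier, must be imbalance-aware.
The package's contribution is the benchmarking methodology: windowed
higher-order feature extraction, IQR outlier filtering, PCA reduction,
Monte Carlo under-sampling evaluation of ten classifier configurations,
imbalance-robust multiclass metrics, and MANOVA comparison of the full
versus reduced feature space.

## Preprocessing

**Drift removal.** Raw plant potentials carry large, slow baseline
drifts. `highpass_filter()` applies a zero-phase (forward–backward)
Butterworth high-pass, default order 2, cutoff 0.05 Hz. The cutoff sits
well below the window's fundamental (10 Hz / 1024 ≈ 0.01 Hz resolution
over a 102 s window) so the stochastic content of interest is untouched
while multi-minute drifts are suppressed. Published analyses of such
data use an optimally designed IIR filter whose search procedure is a
separate contribution; a documented, configurable standard filter is the
honest substitute. Because plain forward–backward filtering has edge
transients comparable in length to the filter's impulse response
(~`fs/cutoff` samples at these cutoffs), the implementation mean-centres
and odd-reflects the signal at both ends (pad length `3·fs/cutoff`,
capped at the signal length) before filtering; a constant offset is then
removed to machine precision. A consequence worth knowing: the mean of
a filtered white-noise window is not exactly zero — the filter passes
some near-cutoff noise power — which is why the Fano factor below is
numerically delicate.

**Windowing.** `segment_signal()` cuts non-overlapping consecutive
blocks of `block_len` samples (default 1024) and discards the trailing
remainder (floor rule).

**Outlier filtering.** `remove_outliers()` implements the literal
published rule: per feature, keep values with
`Q1 − n·IQR < x < Q1 + n·IQR` (note `Q1`, not `Q3`, in the upper bound),
default `n = 6`; the conventional `Q3 + n·IQR` upper bound is available
as `rule = "conventional"`. A row is dropped if *any* feature violates
its band — the published description ("a uniform criterion on the
samples") does not resolve per-feature versus per-row dropping, and
row-wise dropping is the reading that keeps the table rectangular.
Rows containing non-finite feature values (degenerate blocks, unstable
Fano factors) are dropped here as well. Quartiles use linear
interpolation between order statistics (R's type 7), fixed so that the
IQR feature and the outlier bounds are reproducible. A zero-IQR feature
degenerates to an equality band and raises a warning rather than
silently keeping or dropping everything.

**Pipeline order.** Features are extracted, then outlier-filtered, then
min–max normalized. The source description is ambiguous about whether
normalization preceded outlier removal; normalizing last prevents
extreme rows from compressing the [0, 1] scale of the retained data, and
the `n = 6` retention fraction is computed on the raw feature scale.
`minmax_normalize()` refuses constant features by name rather than
emitting NaNs.

## The fifteen features

All features are computed per block, on the filtered signal.

* **Moments** (`moments()`): population variance (divide by N);
  skewness, kurtosis, superskewness and superflatness as
  σ-standardized central moments `E[(x−μ)^k]/σ^k`, k = 3…6 (Gaussian
  reference values 0, 3, 0, 15). The source calls these "central
  moments" without resolving standardization; raw central 5th/6th
  moments are scale-dependent and would be dominated by the variance
  after min–max normalization, so the standardized convention — also the
  common toolkit convention — is used, and kurtosis is reported raw (not
  excess) since the definition carries no "−3". The IQR uses the same
  type-7 quartiles as the outlier filter. The Fano factor is the literal
  σ²/μ on the near-zero-mean filtered block; when |μ| < 1e−12 it is
  flagged NaN. Both the NaN flag and the heavy tail this ratio produces
  are deliberately left to the outlier stage to absorb.
* **Hjorth parameters** (`hjorth()`): mobility
  `sqrt(var(Δx)/var(x))` and complexity `mobility(Δx)/mobility(x)`.
  For iid noise the expected values are √2 and √3/√2; for a sinusoid of
  frequency f, mobility is exactly `2 sin(πf/fs)`. Constant inputs are
  an error at this level (and a NaN flag at the table level).
* **DFA** (`dfa_alpha()`): integrate the mean-removed series, compute
  RMS fluctuations around per-box linear fits over ≥10 log-spaced box
  sizes in [4, N/4], and report the log–log slope. Calibration anchors:
  α = 0.5 (white noise), 1.5 (random walk), α = H for fGn.
* **Hurst exponent** (`hurst_rs()`): classical rescaled-range over
  log-spaced window sizes in [16, N/4]; windows with zero standard
  deviation are skipped. R/S carries a known small-sample upward bias
  for white noise (≈0.55–0.60 at N = 1024); the tests encode that bias
  rather than pretending it away.
* **Wavelet-packet entropy** (`wavelet_packet_entropy()`): full
  wavelet-packet decomposition with the db4 filter (8 taps), level 3 → 8
  leaf bands, implemented as a periodized orthogonal filter bank (no
  wavelet package exists in the dependency set; the filter bank is ~30
  lines and exactly energy-conserving, which the tests assert). Entropy
  is the Shannon entropy of normalized leaf energies, in nats, bounded
  by ln 8; white signals approach the bound, narrowband tones
  concentrate in one leaf.
* **Spectral power** (`spectral_power()`): mean squared value, equal by
  Parseval to the mean periodogram energy; A²/2 for a sinusoid of
  amplitude A over whole periods.
* **Correlation dimension** (`correlation_dimension()`):
  Grassberger–Procaccia with delay embedding m = 5, τ = 1; correlation
  sums over a log radius grid spanning 1–50% of the attractor diameter,
  slope read from the middle third of the grid. For the pair-sum budget
  at most 400 evenly spaced embedded points are used (the correlation
  sum is a U-statistic; even subsampling preserves the slope while
  making the cost independent of block length). No Theiler window is
  applied — at τ = 1 with stochastic signals temporal correlation is
  short, and the limit-cycle and noise calibration cases behave
  correctly without it. A constant block returns 0 by convention.

The source defers all of these definitions to an external toolkit whose
parameterization it does not print; every default above is therefore an
explicit, config-overridable gap-fill (`feature_config()`), not a
reconstruction.

`extract_features()` assembles the fifteen values and converts
component-level errors on degenerate input into NaN flags so that one
bad block cannot abort a 38,000-block table; the flags are removed by
the outlier stage.

## PCA reduction

`fit_pca()` eigendecomposes the sample covariance of the centered
(min–max normalized, *not* z-scored — the stated 0–1 normalization is
the input scale) features, with the sign convention that each loading's
largest-magnitude element is positive. `select_components()` picks the
smallest k whose cumulative explained-variance ratio reaches the
threshold (default 0.90). Whether the original analysis fitted the PCA
once globally or per draw is not stated; the default here refits on each
draw's training half only (no information leaks from test to train), and
`run_benchmark(pca_global = )` reproduces the global-fit variant. The
reduced space is labeled "7d" after the component count the original
data yielded at the 90% threshold; on synthetic data the threshold picks
whatever the scree curve implies (typically 4–6 at the default
generator settings), unless `pca_k` pins it.

## The classifier registry

Ten configurations behind one `fit_predict()` contract, hyperparameters
pinned to the benchmarked values (`make_classifier()` allows overrides):

| name | implementation | pinned settings |
|---|---|---|
| `adaboost` | in-package SAMME.R boosting on depth-5 CART trees | 600 estimators, learning rate 50 |
| `decision_tree` | `rpart`, gini, unpruned (cp = 0, minsplit = 2) | — |
| `gnb` | `e1071::naiveBayes` (Gaussian conditionals) | — |
| `knn` | `class::knn` | k = 5, Euclidean |
| `mlp` | `nnet::nnet`, one hidden layer, softmax | 100 units, decay 2 |
| `qda` | `MASS::qda` | — |
| `rf_entropy` | in-package bagged-CART forest | 100 depth-5 trees, information split, balanced weights |
| `rf_gini` | in-package bagged-CART forest | 100 depth-5 trees, gini split |
| `svm_linear` | `e1071::svm`, no internal rescaling | C = 1 (gamma pinned but inert) |
| `svm_rbf` | `e1071::svm` | C = 1, gamma = 1.5 |

Three design notes. First, the AdaBoost learning rate of 50 is far
outside the usual (0, 1] range but is kept as benchmarked; the weight
update runs in log space with renormalization so it remains finite, and
the practical effect is an extreme reweighting toward currently
misclassified points. Second, no available forest implementation
exposes an entropy/information split criterion, so both forest variants
are built on the same in-package bagged-CART path (bootstrap rows,
`mtry = max(2, ⌊√p⌋)` features per tree, majority vote); using one code
path keeps the gini-versus-entropy pair a pure criterion contrast. The
feature subsample is drawn per tree rather than per node — a random
subspace approximation to per-node sampling, which CART in R does not
expose. Third, the MLP is the R-idiomatic single-hidden-layer network
(BFGS-trained, logistic hidden units) with matching width and weight
decay; relu/adam specifics of other ecosystems are not reproduced.
Every stochastic model receives a per-draw seed derived from the master
seed, so a fit is bit-reproducible. A single-class training set returns
constant predictions rather than erroring, keeping degenerate draws
well-defined.

## Monte Carlo under-sampling evaluation

Each draw of `run_benchmark()`:

1. `balanced_undersample()` — sample, uniformly without replacement,
   `n_min` rows from every class (`n_min` = minority count; the minority
   class enters in full). At the study's counts this yields
   628 × 3 = 1884 rows.
2. `split_half()` — stratified 50:50 split (⌊n/2⌋ per class to train),
   314 per class per half at study scale. Stratification is a choice:
   the published description says only "equally", and the stratified
   split preserves the balanced design inside both halves.
3. Optional per-draw PCA (above), then every classifier fits and
   predicts; the 3×3 test confusion matrix is stored.

Draw indices are generated once per draw and shared by all classifiers
and both feature spaces (common random numbers), which is what makes the
per-draw paired comparison and the "repeated-measures" analysis below
valid. `average_confusion()` row-normalizes each matrix (per-class
rates) before the element-wise ensemble mean, so rows of the average sum
to 1. The default draw count of 1000 matches the study design;
scaled-down runs (the examples use 10–50) only widen the Monte Carlo
error of the metric means.

## Metrics

From each confusion matrix, `metric_set()` computes:

* `accuracy()` — mean per-class recall (the trace-based multiclass
  accuracy; equals trace/total on balanced test sets). Its chance level
  is 1/K = 1/3.
* `balanced_accuracy()` — mean over classes of one-vs-rest
  (sensitivity + specificity)/2. Note its chance level is 1/2, not 1/3
  — a random or constant predictor scores 0.5 because specificity
  compensates. The two "balanced" notions are easy to conflate; the
  package computes both, and the chance-level tests pin each to its own
  baseline.
* `f_beta()` — macro-averaged F score with the standard
  `(1+β²)·Pre·Rec/(β²·Pre + Rec)` form (a printed variant with a product
  in the denominator is a typographical slip; the accompanying
  description is the harmonic mean). Conventions: precision of a
  never-predicted class is 0; F is 0 when Pre + Rec = 0.
* `mcc()` — Gorodkin's multiclass Matthews correlation, 0/0 → 0.

Macro (unweighted) averaging is used throughout: under the balanced
design every class has equal test weight, so weighting is moot, and
macro is the standard reading of per-class aggregation.
`metric_distributions()` attaches normal-fit summaries (sample mean and
sd) per metric over the ensemble.

## MANOVA comparison of feature spaces

`oneway_manova()` decomposes scatter into within (W) and between (B)
matrices, takes the s = min(p, g−1) leading eigenvalues of W⁻¹B
(negatives below 1e−10 clipped to zero), and reports Pillai's trace
`V = Σ λ/(1+λ)`, Wilks `Λ = Π 1/(1+λ)`, Hotelling–Lawley `U = Σ λ` and
Roy's greatest root `Θ = max λ`, each with its standard F approximation
(Rao's for Wilks; the moment approximations for Pillai and
Hotelling–Lawley; the upper-bound F for Roy). For two groups all four
reduce to the identical exact two-sample Hotelling T² F on
(p, n−p−1) degrees of freedom — the tests verify this against the
closed form, and against `stats::summary.manova` for three groups. For
a single variate the printed identities `V = U/(1+U)`, `Λ = 1 − V`,
`Θ = U` hold exactly; these identities are what the acceptance script
recomputes from the published eigenvalues. The `R²` column reports the
Pillai-type effect size `V/s`. Published tables of this analysis print
df1 = 2 with three dependent variables, consistent with a rank drop in
the authors' software; this package reports degrees of freedom from the
dimension actually used and leaves the discrepancy documented rather
than imitated.

The "repeated-measures" comparison of the 15-D and reduced spaces is
described only loosely in the source, so `compare_spaces()` provides
both defensible readings, labeled: (a) per-group one-sample location
tests (`group_location_test()`, Hotelling's one-sample T² expressed
through the single eigenvalue λ = T²/(n−1)) — the "constant/intercept"
rows of a repeated-measures table — and (b) the paired per-draw
difference test (`paired_location_test()`), which is the statistically
sharper reading given common random numbers. A singular within-scatter
(e.g. duplicated metrics) is an error advising de-duplication, not a
silent pseudo-inverse.

## The synthetic generator

`generate_dataset()` emulates the study conditions: three stimulus
classes at a 10 : 24 : 571 imbalance (default 60/144/3426 blocks,
preserving the 628 : 1488 : 35718 ratio at desk scale), 1024-sample
blocks at 10 Hz, and two species labels drawn independently of class
(the species histograms of real data largely overlap, and independence
guarantees species cannot confound stimulus).

Each block is AR(1) plus fractional Gaussian noise (Davies–Harte
circulant embedding) with class-mean parameters

| class | φ | σ | H | skew |
|---|---|---|---|---|
| NaCl | 0.2 | 1.0 | 0.55 | 0 |
| H₂SO₄ | 0.5 | 1.4 | 0.70 | 0.12 |
| O₃ | 0.7 | 2.0 | 0.85 | 0 |

followed by the quadratic skew transform `x + skew·x²` — so the classes
differ in variance, spectral slope, long-range dependence and asymmetry,
the four feature families the pipeline measures. Crucially, every block
jitters its parameters around the class means (Gaussian sd 0.12 on φ,
0.10 on H, 0.06 on skew; lognormal sd 0.30 on σ). The jitter models
plant-to-plant and session-to-session heterogeneity and is what gives
the univariate feature histograms their realistic between-class overlap;
without it, within-class spread is so small relative to separation that
the IQR filter — whose quartiles the 94% majority class dominates —
discards the minority classes wholesale. The real recordings'
distributions are uncharacterized in print, so these values are design
choices calibrated to qualitative structure (overlapping histograms,
above-chance but imperfect classification), not estimates of real data.

One master seed spawns a per-block substream, so generation is
bit-reproducible and independent of evaluation order; the species and
per-block seeds are drawn from the master stream up front.

**What passing tests do and do not show.** The synthetic process is
stationary within a block, Gaussian up to the skew transform, and free
of action/variation-potential waveforms, stimulus-onset transients,
electrode artifacts and inter-block dependence (real consecutive windows
of one experiment are correlated; synthetic blocks are iid given their
class). Green end-to-end tests therefore demonstrate that the machinery
is correct and calibrated — balanced draws, paired comparisons, metrics
at their chance levels under label permutation, MANOVA at nominal type-I
error — not that any particular accuracy is attainable on real plants.

## Problem sizes and numerical choices

The test suite exercises the full default synthetic conditions (3630
blocks of 1024 samples) once end-to-end with k-NN at R = 50 draws, and
uses smaller configurations (block length 512, tens of blocks, R ≤ 20)
elsewhere; estimator-calibration checks use 200 Monte Carlo replicates.
These sizes make the suite complete in a couple of minutes while keeping
every statistical tolerance meaningful at its stated width.

Numerical conventions collected in one place: type-7 quantiles
everywhere; population (divide-by-N) variance in moments and Hjorth
ratios; NaN flags, not errors, for degenerate blocks at the table level;
MCC and F conventions as above; eigenvalue clipping at −1e−10;
forest/boosting ties broken by first class index; min–max normalization
errors on constant features; `fit_pca()` requires more rows than
features (no pseudo-rank fits).

## Known limitations

* The high-pass filter is a standard Butterworth stand-in, not the
  optimized IIR design used on the original recordings.
* Per-tree (not per-node) feature subsampling in the forests, and a
  logistic-activation BFGS-trained MLP, are R-ecosystem approximations
  of the benchmarked configurations.
* The correlation-dimension estimator uses a fixed radius window and no
  Theiler correction; it is a comparative feature here, not a rigorous
  invariant estimate.
* Synthetic realism gaps listed above; in particular, no claim is made
  that real plant data would reproduce the synthetic accuracy levels.
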