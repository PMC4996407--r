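---
title: "Self-normalizing gene-pair signatures from whole blood: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-normalizing gene-pair signatures from whole blood: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodPairs)
```

# The measurement model and what the method assumes

`bloodPairs` works on MAS5-style probe-set summaries of whole-blood
microarrays: a nonnegative signal value and a Present/Marginal/Absent
detection call per probe set per array, held in a `BloodExpressionSet`
(a `SummarizedExperiment` with `signal` and `calls` assays and sample
annotations — disease group, collection tube, source, RIN, 28S:18S —
in `colData`).

The working model of a log2 signal is

$$\log_2 x_{ps} = \mu_p + b_p\,[\text{tube}_s=\text{PAXgene}]
  + \delta_p\,[\text{s diseased}] + \lambda_p c_s + \varepsilon_{ps},$$

where $\mu_p$ is the probe baseline, $b_p$ a probe-specific collection
tube bias, $\delta_p$ a disease effect, $c_s$ a latent per-sample
confounder (diurnal state, cell-count composition) with probe loadings
$\lambda_p$, and $\varepsilon$ measurement noise. Three structural
assumptions drive every design choice:

* tube and scale artefacts act *multiplicatively* on signals (additive
  on log2), so within-sample ratios cancel them;
* confounders are *shared* across probes, so a ratio of two probes with
  matched loadings cancels them too, and a near-uninformative pair that
  tracks the confounder can subtract it from an informative but
  contaminated pair (the suppressor idea, borrowed from the
  differential amplifier);
* only probes with demonstrated replicate stability are worth pairing —
  reliability is established *before* any disease information is used.

# Pipeline stages and their tunables

**Sample QC** (`qcFilterSamples`): keep iff RIN ≥ 7.0 and 28S:18S ≥ 1.0,
both inclusive. Missing metrics reject the sample — a clinical QC gate
should fail closed.

**Probe filter** (`filterProbes`, `buildStabilityList`): the retained
universe is the conjunction of six rules — Present in all samples;
all signals in [100, 10000] (both ends inclusive: below 100 MAS5
signals are noise-dominated, above 10000 saturated); membership of the
MAQC reproducibility list and of EDTA (±10%) and PAXgene (±15%)
replicate-stability lists; and no outlier, operationalized per probe as
any signal more than 2-fold outside the probe's own central 95% signal
range. The stability metric is the maximum relative deviation from the
replicate *median*, robust to a single bad hybridization; probes with a
zero median cannot be scored and are excluded. Because the chain is a
pure conjunction it is idempotent and order-free. Inside
cross-validation the filter is recomputed on each training fold only.

**Pair screening** (`evaluatePairs`): all unordered pairs of retained
probes, as log2 ratios and log2 sums, scored by AUROC in its
Mann–Whitney form (ties counted half), computed by midrank arithmetic.
Pairs are oriented (feature negated; for a ratio that is exactly
swapping numerator and denominator) so the recorded AUROC is ≥ 0.5.
Significance threshold 0.7 — a screening compromise between losing
usable pairs and admitting unreliable ones. Sum pairs must additionally
beat their best member's single-probe AUROC by ≥ 0.05 (default),
since a sum only helps when the two probes' noise partially cancels.
Log2 scale is used throughout: it makes ratio features symmetric in
the two probes and well-scaled for a logistic model.

**Suppressor detection** (`findSuppressors`): a pair is a suppressor
when its own AUROC is within `delta = 0.05` of 0.5 *and* the magnitude
of its Pearson correlation (over all samples) with at least one
significant pair's feature reaches `rho_min = 0.6`. Both defaults are
configurable; 0.05 is the resolution at which a screening AUROC is
distinguishable from chance at realistic cohort sizes, and 0.6 demands
that the pair share most of its variance with the signal it is meant to
clean. Pearson correlation (not rank) is used because the suppressor
enters a *linear* logistic score.

**Balancing by replication** (`replicationPlan`,
`replicateWithNoise`): in one-against-all training the unconfirmed
"Other" pool dwarfs the pathology-confirmed strata, so confirmed
samples are replicated — r extra copies each, i.e. n(r+1) effective —
until strata contribute comparably. Copies get i.i.d. N(0, σ²) log2
noise, σ = 0.05 by default (≈3.5% CV), small enough to act as
measurement uncertainty rather than new biology; with σ = 0 the
operator is pure duplication. `hccTrainingDesign()` carries the worked
reference design: 26×16 = 416, 20×21 = 420, 28×15 = 420, 7×57 = 399,
totalling 2513 effective training columns. Replication is applied after
filtering and before pair screening, inside the training fold only —
re-weighting confirmed samples is meant to shape the screening
statistics as well as the fit, and test folds must never be replicated.

**Monte-Carlo panel search** (`mcSearch`): systematic evaluation of all
size-k pair subsets is combinatorially out of reach, and any panel that
predicts well enough is useful, so random subsets are drawn (at most
`max_suppressors` suppressor pairs each, default 2), fitted by
maximum-likelihood logistic regression, and scored. The default
objective is AUROC on an internal 70/30 stratified validation split
rather than training AUROC, which resists overfitting during subset
selection; when a class is too small to split, the search falls back to
the training objective. Ties break to fewer distinct probes, then the
lexicographically smallest probe-id set — fully deterministic under a
fixed seed, and with a shared random stream the best objective is
non-decreasing in the iteration budget. The default panel size is 6
pairs. `estimatePi` ships as the self-contained demonstrator of why
random beats systematic search: at 100,000 random points the π estimate
is reliably within 5% (usually far closer), while a lattice of equal
cost converges more slowly per point in higher-dimensional analogues.

**Fitting and scoring** (`fitPanel`, `panelScore`): the panel score is
the logistic linear predictor; the decision threshold is fixed at 0
(probability one half). Replication-balanced training data are often
perfectly separable, so separation triggers a ridge-stabilized IRLS
refit with λ = 1e-6 on the coefficients (intercept unpenalized) instead
of an error; the panel records this in its `ridged` flag. The penalty
is small enough to leave non-separable fits indistinguishable from
maximum likelihood and exists only to pin down the separating
direction's scale.

**Evaluation** (`oneAgainstAll`, `crossValidate`): the target disease
is positive, controls plus every other disease negative. Iterated
stratified 2-fold cross-validation re-runs the entire pipeline inside
each training fold; out-of-fold scores are pooled across folds and
iterations, and the metric set — sensitivity, control specificity,
others-specificity (all at threshold 0), AUROC — is computed on the
pool. Pooling rather than averaging per-iteration metrics is the stabler
choice when positive groups are as small as 8–12 samples; a fold that by
chance lacks a class is resampled and counted, never dropped.

# The synthetic generator: what it emulates, and what it does not

`simulationConfig()`/`simulateCohort()` draw cohorts directly from the
working model above, with deterministic planted structure: cancelable
marker pairs (shared bias and loading, disease shift on one member),
suppressor pairs (loading on one member, no disease effect), globin-trap
probes (disease shift plus PAXgene-only extra noise — globin carryover
is a PAXgene-chemistry problem), tube-bias-only probes, and stable
background. Defaults: 0.5 log2 tube bias on ~30% of probes, 1.2 log2
disease shift, confounder SD 0.8 with unit loadings, measurement noise
0.15 log2, globin extra noise 2.0 log2, baselines placed so planted
probes stay inside the [100, 10000] filter window. Detection calls use
the same 100-signal threshold as the filter, keeping fixture and filter
consistent. `simulateReplicates()` emulates the pooled-sample replicate
hybridizations from which the stability lists are built (replicate
scatter 0.03 log2, ≈2% CV).

`tubeBiasChallenge()` assembles the full benchmark: an EDTA-dominated
training cohort (5 PAXgene + 25 EDTA per class — the realistic
situation in which a lab transitions tube chemistry), an independent
balanced test cohort of 50 per stratum (sized so a per-tube AUROC is
estimated to ±0.04 and the 0.1/0.2 verdict thresholds are resolvable),
replicate-derived stability lists, PAXgene replication balancing, and a
3-pair search at 150 iterations. The naive comparator is a logistic
model on the single best training-AUROC probe of the *unfiltered*
matrix. The verdict passes when the pipeline's per-tube AUROC gap stays
below 0.1 while the naive model's exceeds 0.2; with no tube-dependent
structure planted the comparison is meaningless and is reported
"inapplicable" rather than pass or fail.

What passing these benchmarks does **not** show: the generator is
log-normal with additive-on-log2 artefacts — exactly the structure
ratios cancel. Real blood data add cell-composition drift,
probe-specific saturation, non-multiplicative batch effects and
RNA-degradation gradients that ratios only partially absorb, and the
original study cohorts are not publicly deposited, so the published
per-disease sensitivities/specificities are not reproduced here.
Passing establishes internal correctness and the *mechanism* of bias
suppression, not clinical performance.

# Numerical and degenerate-input choices

* AUROC is exact midrank arithmetic; tests hold it to exhaustive
  pair counting (identical doubles, not approximate equality).
* Percentiles in the outlier rule use R's default quantile
  (type 7); the rule is a conjunction member, so its placement in the
  chain does not affect the outcome.
* Features are required finite; a non-positive signal reaching the log
  transform is an error instructing that the 100-minimum filter must
  run first, rather than a silent NaN.
* If screening yields fewer candidates than the panel size (typical
  under permuted labels), the candidate set is padded with the
  top-AUROC remaining pairs so a panel can always be fitted; null
  behaviour is then checked by permutation tests rather than by
  refusing to fit.
* All randomness (balancing noise, search subsets, validation splits,
  fold assignment, simulation) is seed-controlled; identical seeds give
  bit-identical results.
* Sample and probe identifiers are opaque case-sensitive strings; no
  platform-specific parsing is attempted.

# Problem sizes used in the shipped tests

The test suite and benchmarks run at deliberately small scale, chosen
as the smallest sizes at which each asserted property is statistically
resolvable: screening nulls use 200–400 samples (the in-sample AUROC
bias of a fitted single feature is ≈ $E|U-0.5|\approx 0.4/\sqrt{n}$ and
must sit well inside the ±0.05 band); the cross-validated permutation
null averages over fresh label permutations, because out-of-fold AUROC
at 2-fold/n = 40 carries a known pessimistic bias of a few points;
exhaustive-search oracles cap at 12 candidates (C(12,3) = 220
enumerable fits); the tube-bias challenge repeats over 5 seeds and the
noise-monotonicity check over 6. The Monte-Carlo demonstrator uses
100,000 points.

# Known limitations

* Pair enumeration is quadratic in the retained probe count; the
  exhaustive screen is intended for post-filter universes (hundreds of
  probes). Larger universes should be pre-reduced or the search budget
  spent directly on random pair subsets.
* Class-weighted fitting as an alternative to replication balancing is
  deliberately not offered: replication with noise is the method's own
  mechanism and also regularizes single influential samples.
* Suppressor detection considers pairwise correlation with one
  significant pair at a time; a confounder only visible as a linear
  combination of several features will be missed at screening (though
  the logistic fit can still exploit it if the pair is drawn).
* The threshold-0 decision rule presumes the logistic intercept is
  calibrated by the (balanced) training prevalence; under strong class
  rebalancing the score is a risk index, not a calibrated probability.
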