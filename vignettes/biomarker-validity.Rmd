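---
title: "Valid biomarkers from point-mass mixture intensity data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valid biomarkers from point-mass mixture intensity data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmarker)
```

# The data model

A clinical peptidomics run reports, for each peptide (characterized by its
molecular mass in Da and normalized CE migration time in min) and each
sample, a nonnegative amplitude, with 0 meaning *not detected*. Because a
peptide can be genuinely absent or merely below the limit of detection
(LOD), the per-feature distribution is a left-censored point-mass mixture:

\[ X = B \cdot \exp(Z), \qquad B \sim \mathrm{Bernoulli}(\pi_d), \quad
   Z \sim N(\mu, \sigma^2), \]

optionally followed by censoring of amplitudes below the LOD. All
continuous-component summaries in this package (means, SDs, effect sizes)
are computed on the **natural log of the nonzero values only**; zeros are
censored observations and are never imputed into the continuous component.
The standardized effect size is
\(\delta = (\mu_1 - \mu_2)/\sigma_{\text{pooled}}\) with group 1 the
reference (first factor level, lexicographic unless declared), so the sign
convention is group 1 minus group 2.

Group differences decompose into a *zero-proportion* part and a
*continuous* part. When the group with the (strictly) higher zero
proportion has the smaller continuous mean the difference is **consonant**
— the typical LOD mechanism, since less abundant peptides are also less
detectable; the opposite pattern is **dissonant**; features with no zeros
at all are **no-point-mass**. Two tie rules are fixed: equal zero
proportions classify as consonant (the conservative choice — the dominant
class in real data), and a group with no nonzero values (continuous mean
undefined) is classified by zero proportions alone, with the feature
flagged degenerate.

The detection-frequency filter keeps a feature iff its nonzero frequency
reaches the threshold (default 0.30) in **either** group: a marker may
legitimately be present in only one condition. The filter is idempotent
and order-preserving, and it is applied once, on the full training set —
not re-applied inside resamples.

# The five differential tests

All tests are two-sided; defaults are \(\alpha = 0.05\) and FDR level
\(q = 0.05\).

* **t**: Welch two-sample t on the log nonzero amplitudes (pooled-variance
  variant behind `pooledVar = TRUE`). The Welch default was chosen for
  robustness since equal variances are not guaranteed across groups.
  Requires ≥ 2 nonzero values per group.
* **wilcoxon**: rank-sum on *all* values. Zeros are genuine observations
  tied at the common minimum; mass ties at zero only make the test
  conservative. Small samples use exact p-values: `stats::wilcox.test`'s
  exact distribution when there are no ties and both groups have ≤ 25
  samples, and full enumeration of the permutation distribution of the
  midrank sum when ties are present and the total sample size is ≤ 16
  (the deviation-based two-sided p, valid because the midrank multiset is
  reflection-symmetric). Larger samples use the tie-corrected normal
  approximation *without* continuity correction, so that the squared
  statistic is exactly the chi-square component used by the two-part test.
* **two_part_t / two_part_wilcoxon**: \(X^2 = Z_B^2 + Z_C^2\), where
  \(Z_B\) is the pooled two-proportion z on the zero proportions and
  \(Z_C\) the continuous-part statistic (Welch t, or tie-corrected
  rank-sum z) on the nonzero values; \(X^2\) is referred to a chi-square
  with df = number of *defined* parts. A part is dropped when its data are
  degenerate: the proportion part when there are no zeros anywhere (or
  everything is zero), the continuous part when a group has fewer than two
  nonzero values. Both parts degenerate ⇒ the feature is flagged
  untestable and excluded from the adjustment family. With no zeros the
  two-part statistics collapse exactly to the squared single-part
  statistics with df 1. Continuity corrections are off throughout.
* **elrt**: a two-sample empirical likelihood ratio test of equal mixture
  means, zeros included as observations on the amplitude scale. For a
  candidate common mean \(\mu\), each group's one-sample log EL ratio
  \(2\sum\log(1+\lambda(x_i-\mu))\) is profiled by solving
  \(\sum (x_i-\mu)/(1+\lambda(x_i-\mu)) = 0\) for \(\lambda\) by bracketed
  root finding (tolerance 1e-10); the combined statistic is minimized over
  \(\mu\) in the closed interval between the two sample means (each
  group's EL ratio is convex in \(\mu\) with minimum at its own mean, so
  the minimizer of the sum lies between them; `optimize` tolerance 1e-8).
  When the data hulls do not overlap the statistic is effectively infinite
  and the p-value 0.

## Calibration of the ELRT

The chi-square df 1 asymptotics of the ELRT are **unreliable for skewed
amplitude data at realistic sample sizes**: on simulated null mixtures
with a lognormal continuous component (log-SD 1) and 67 samples per group,
the chi-square calibration gives empirical type-I error around 0.06–0.075
at the nominal 0.05 (on pure normal data it is 0.05, so this is the
well-known skewness-driven undercoverage of empirical likelihood, not an
implementation artifact; the pseudo-observation-adjusted EL was evaluated
and still gave ≈ 0.066). `testAll` therefore calibrates the ELRT by
**permutation of the group labels, pooling the permuted statistics across
features** — legitimate because the statistic is asymptotically pivotal —
with `B = 60` permutations by default (so the reference distribution has
`60 × m` draws) and an internally fixed seed for reproducibility. The
asymptotic calibration remains available (`calibrate = "chisq"`) and is
what the single-feature `runTest` reports. Pooling assumes the null
distribution of the statistic is exchangeable across features; for highly
heterogeneous real panels this is an approximation, which is the price of
making the calibration affordable.

## Multiplicity and validation

`bhAdjust` is the Benjamini–Hochberg step-up procedure (delegated to
`stats::p.adjust`), applied within the family of testable features of one
`testAll` call. `validateMarkers` re-tests training-significant candidates
on an independent matrix; because the phrase "tested alone" is ambiguous,
both conventions are provided: BH within the candidate subset (default) or
raw per-marker testing (`testAdjust = "none"`). Candidates missing from
the test matrix count as unconfirmed and are reported.

# Stability selection

`stabilitySelect` draws, per resample, a stratified (per-group) subsample
of \(1 - h\) of the samples without replacement (default holdout
\(h = 0.30\); stratification avoids degenerate unbalanced resamples),
re-runs the test + BH at the FDR level, and records per-feature selection
frequencies with denominator \(N\). Tiers at thresholds 1.0 / 0.8 / 0.5
are nested by construction; \(N = 0\) means the single full-data analysis
and all tiers equal the full-data significant set. The default inner test
is the Wilcoxon, the workflow's baseline.

# Differential sample size

The p-value distribution of a marker panel is modelled as the
beta-uniform mixture \(f(p) = \pi_0 + (1-\pi_0)\, a\, p^{a-1}\) with
\(0 < a < 1\) (a decreasing alternative density — the standard shape).
The mixture weight is **unidentifiable at the null boundary**: as
\(a \to 1\) the likelihood is flat along a ridge of \((\pi_0, a)\) pairs.
`estimatePi0` therefore profiles the likelihood over a \(\pi_0\) grid
(150 points on \([0.001, 0.999]\), inner `optimize` over \(a\)) and
reports the **largest** \(\pi_0\) within 0.5 log-likelihood units of the
optimum. Away from the ridge this is the MLE; on pure-null data it
resolves the plateau conservatively (\(\hat\pi_0 \approx 1\)), which
over- rather than under-estimates \(\pi_0\) — the safe direction, since
the downstream per-test level shrinks with \(\pi_0\). P-values are clamped
to \(10^{-12}\) below to keep the Beta density finite; all-identical
p-values are a degenerate-input error.

The FDR-equivalent average per-test level is evaluated literally as
\[ \alpha_{\mathrm{ave}} = (1-\beta)_{\mathrm{ave}}\; q\;
   \Big[1 + (1-q)\,\frac{\pi_0}{1-\pi_0}\Big]^{-1}, \]
with limits \(\alpha_{\mathrm{ave}} = (1-\beta)_{\mathrm{ave}} q\) at
\(\pi_0 = 0\) and \(0\) at \(\pi_0 = 1\) (e.g. 0.020131 at
\(\pi_0 = 0.5652831\), \(q = 0.05\), \((1-\beta)_{\mathrm{ave}} = 0.9\)).
Because published values for this quantity are not always consistent with
the formula, every consumer of \(\alpha\) (notably `bootstrapPower`) takes
it as an explicit argument rather than deriving it silently.

`bootstrapPower` resamples **whole pilot columns** with replacement within
group — preserving the within-sample correlation of the peptide panel —
at each per-group size on the grid (default 10–120 step 5, B = 2000),
tests each feature at the per-test level, and reports the rejection
fraction, discounted by the factor 0.95 by default (treating 5% of
rejections as false positives; `discount = FALSE` gives the raw rate).
`ndiff` then reads off the smallest grid size reaching the target power
(default 0.9), with an explicit `unattained` flag. Bootstrap power is only
as representative as the pilot; a 2 × 7 pilot is the workflow's canonical
minimum, and the box-plot summaries of repeated pilot cohorts (default 30)
are the honest way to display its sampling variability.

# Discriminative sample size

`learningCurve` subsamples the training set at each per-group size
(default 20 repetitions), re-runs feature selection (unadjusted Wilcoxon,
\(\alpha = 0.05\)) *inside* the subsample, trains the classifier, and
evaluates AAC = 1 − AUC and MER = 1 − accuracy on the fixed independent
test set. Failed subsamples (empty selection, classifier failure) are
recorded as missing points. `fitPowerLaw` fits
\(E(Y) = \Gamma + \beta N^{-\gamma}\) (\(\Gamma, \beta, \gamma \ge 0\):
\(\Gamma\) is the Bayes-error asymptote, \(\gamma\) the learning rate) by
constrained Levenberg–Marquardt least squares on the per-size means
(`onMeans = FALSE` fits raw points), with a multistart grid over
\(\gamma \in \{0.2, 0.5, 0.7, 1, 1.5\}\) and floor candidates
\(\Gamma_0 \in \{0, 0.5, 0.9\} \times \min \bar y\); essentially flat
curves (\(\beta\) or \(\gamma \approx 0\)) are flagged degenerate.
`ndisc` inverts the fitted curve,
\(N = ((\text{target} - \Gamma)/\beta)^{-1/\gamma}\), rounding to the
nearest integer by default (ceiling available); targets at or below
\(\Gamma\) are unattainable by definition.

# Classification and the LOOCV trap

Classifier inputs are natural-log amplitudes with zeros mapped to the log
of a pseudo-amplitude equal to **half the smallest nonzero value of the
training submatrix** (recorded in the evaluation object); the choice is a
documented assumption — indicator-feature encodings are a reasonable
alternative not taken here. Adapters with fixed default hyperparameters
wrap e1071 (SVM, RBF kernel, cost 1), randomForest (500 trees), rpart, a
binomial GLM, an AdaBoost.M1 implemented over depth-1 rpart stumps (100
rounds), and — for the pluggable "hierarchical Bayes" slot — MAP Bayesian
logistic regression under a shared Gaussian shrinkage prior (ridge
penalty, \(\lambda = 1\)), explicitly non-canonical. Any classifier can be
plugged in as a `fit(X, y)` / `predictScore(model, X)` pair with scores
oriented toward the second group level.

ROC curves sweep the decision score with tied scores grouped, always
running from (0,0) to (1,1); AUC is the trapezoid rule (equal to the
rank statistic, hence invariant under strictly monotone score
transformations) and AAC = 1 − AUC, MER = 1 − accuracy hold exactly.
Training and test sample identifiers must be disjoint; an overlap aborts
as leakage.

`loocv` defaults to *complete* LOOCV — feature selection re-run inside
every fold. The `reselect = FALSE` variant (selection once, on the full
training set) is retained deliberately: on null data with 7 samples per
group it produces apparent accuracies near 1.0 while the holdout accuracy
stays at chance, the selection-bias optimism that makes training-set
validation meaningless for small panels. Folds whose selection comes up
empty count as errors.

# The synthetic-data generator

`makeNullSpec`/`makeEffectSpec` encode the study conditions the analyses
assume. Defaults, chosen once: detection probability 0.7 (a ≈ 30% point
mass, the regime the 30% frequency filter addresses), log-mean 5 and
log-SD 1 on the natural-log amplitude scale (a mid-range peptide with the
typical near-Gaussian log hump), 67 samples per group, null proportion
\(\pi_0 = 0.565\) mirroring the canonical urinary-peptidome estimate, a
consonant/dissonant/no-point-mass mix of 0.961/0.031/0.008 mirroring the
observed composition of real data, \(|\delta|\) uniform on \([0.2, 2]\)
with random sign, and a detection-probability shift of 0.15 realizing the
point-mass difference (consonant features give the lower-mean group the
lower detection probability; dissonant the higher; no-point-mass features
are detected everywhere). Ground truth (intended class and \(\delta\)) is
stored in the spec. Optional equicorrelated latent blocks
(`blockSize`, `rho`) stress multiplicity behaviour under dependence.

What the generator does **not** emulate: migration-time drift and
normalization artifacts, amplitude-dependent censoring beyond a sharp LOD,
heteroscedastic continuous components, and realistic long-range
correlation structure. Tests passing on this generator therefore validate
the statistical machinery under the stated model, not the wet-lab
pipeline; the two suite blocks that target the original CE-MS cohorts
require the (non-redistributable) supplementary matrices to run.

# Problem sizes and numerical conventions used by the test suite

The suite audits: BH against the literal step-up definition exhaustively
over grid multisets up to length 8; Wilcoxon against full enumeration on
all two-group splits of value vectors up to length 8; type-I calibration
of all five tests on a 1000-feature null at 67 samples per group (±3
Monte-Carlo SDs around 0.05); bootstrap power against
`stats::power.t.test` within ±0.05 on a deterministic no-zero Gaussian
pilot (quantile-constructed, 200 per group, B = 500); exact recovery of
inverse power-law coefficients from noiseless curves (1e-6) and of the
learning rate within ±0.15 under Gaussian noise (SD 0.02, 20 reps);
LOOCV-minus-holdout optimism > 0.2 on 400-feature nulls at 7 per group
over 20 seeds; generator round trips at n = 10000 (±0.05 on \(\delta\),
±0.015 on zero proportions, 3-SD multinomial bands on the class mix); and
the monotone growth of BH-significant counts over per-group sizes 7 → 67
on a fixed 300-feature effect spec, 10 seeds. These sizes are the
package's chosen audit scale: large enough for the stated tolerances,
small enough to run routinely.

# Known limitations

- The two-part chi-square treats its components as independent; under
  strong LOD coupling between detection and abundance this is an
  approximation.
- Pooled permutation calibration of the ELRT assumes cross-feature
  exchangeability of the null statistic.
- The power-ordering of two-part versus single-part tests is
  regime-dependent: with consonant signal concentrated in one component
  the plain Wilcoxon can be the more powerful test, which is precisely why
  the workflow's baseline is the Wilcoxon.
- Bootstrap power from very small pilots inherits the pilot's sampling
  error in \(\delta\); repeated pilot cohorts are the only honest display
  of that uncertainty.
- `fitPowerLaw` extrapolates; `ndisc` solutions far beyond the largest
  observed training size should be treated as planning guidance, not
  guarantees.
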