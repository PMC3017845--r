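# pepmarker

Statistical validation of proteomic biomarkers and classifiers from
left-censored peptide intensity matrices.

Clinical peptidomics platforms such as CE-MS report, for every peptide and
every urine sample, a nonnegative amplitude where 0 means *not detected* —
the peptide is either absent or below the limit of detection (LOD). The
per-feature distribution is therefore a **point-mass mixture**: a spike at
zero plus a continuous component that is roughly Gaussian on the natural-log
scale. Naive reuse of standard tests and of training-set error estimates on
such data produces biomarker lists and classifiers that collapse on
independent samples. `pepmarker` implements the statistical workflow that
addresses this, end to end, for two-group studies (case/control):

- **Data model**: `PeptideSet`, a `SummarizedExperiment` of amplitudes with
  feature metadata (mass in Da, CE migration time in min) and a group label
  per sample; delimited-text I/O; detection-frequency filtering (keep a
  feature iff nonzero in ≥ 30% of either group); consonant / dissonant /
  no-point-mass classification of group differences; standardized log
  effect sizes δ = (μ₁ − μ₂)/σ_pooled.
- **Differential tests** (`testAll`): Welch t on log nonzero amplitudes;
  Wilcoxon rank-sum with zeros as ties at the minimum (exact for small
  samples, including tie-aware exact enumeration); the two-part tests
  X² = Z_B² + Z_C² combining a two-proportion z on the zero proportions
  with a continuous-part t or rank-sum z (df = number of defined parts);
  and a two-sample empirical likelihood ratio test of equal mixture means.
  Benjamini–Hochberg adjustment and independent-test-set validation
  (`validateMarkers`).
- **Stability selection** (`stabilitySelect`): repeated stratified 30%
  holdout, selection frequencies, nested tiers f(100%) ⊇-nested into
  f(80%), f(50%), and their test-set concordance.
- **Sample-size estimation**: π₀ from the beta-uniform mixture of p-values
  (`estimatePi0`); the FDR-equivalent average per-test level
  α_ave = (1−β)_ave · q / (1 + (1−q)·π₀/(1−π₀)) (`alphaAve`); bootstrap
  power curves from pilot columns (`bootstrapPower`) and the differential
  sample size N_diff (`ndiff`); classifier learning curves fitted with the
  inverse power law E(Y) = Γ + β·N^(−γ) (`learningCurve`, `fitPowerLaw`)
  and the discriminative sample size N_disc = ((target − Γ)/β)^(−1/γ)
  (`ndisc`).
- **Classification** (`selectFeatures`, `trainAndEval`, `loocv`): Wilcoxon
  feature selection, SVM / random forest / AdaBoost / tree / logistic GLM /
  shrinkage-logistic adapters plus a pluggable slot, holdout accuracy, ROC
  by score sweeping, trapezoid AUC, and complete leave-one-out
  cross-validation — including the leaky variant that demonstrates why
  LOOCV after full-data feature selection is not a validation.
- **Synthetic data** (`makeNullSpec`, `makeEffectSpec`, `simulateMatrix`):
  a generator of two-group point-mass mixture matrices with known ground
  truth (per-feature δ, difference class, detection probabilities), so the
  whole pipeline is auditable without any external data.
- **Pipeline** (`runPipeline`, `inst/scripts/pepmarker.R`): a configurable,
  seed-deterministic filter → test → (stability | N_diff | N_disc |
  classify) chain with TSV/JSON outputs and a structured log.

## Worked example

```r
library(pepmarker)

## a synthetic two-group study with known ground truth:
## 500 peptides, 56.5% null, moderate effects, 67 samples per group
spec  <- makeEffectSpec(500, pi0 = 0.565, deltaRange = c(0.2, 0.8),
                        nPerGroup = 67, seed = 42)
train <- simulateMatrix(spec)
test  <- simulateMatrix(reseed(spec, 43))   # same truth, independent draw
colnames(test) <- paste0("T", colnames(test))

train <- frequencyFilter(train, 0.30)
test  <- test[rownames(train), ]
train
#> PeptideSet: 500 features x 134 samples
#> groups: A (n=67), B (n=67)
#> zero fraction: 0.330

res <- testAll(train, "wilcoxon")
sum(res$p_raw < 0.05)                  #> 165   unadjusted "markers"
sum(res$p_adj < 0.05, na.rm = TRUE)    #> 123   BH-adjusted markers

validateMarkers(res, test)[c("n_candidates", "n_confirmed", "fraction")]
#> 123 candidates, 83 confirmed on the independent set (67.5%)

(pi0 <- estimatePi0(res$p_raw))
#> Pi0Model: pi0 = 0.4029, Beta shape a = 0.2526 (m = 500, logLik = 392.5)
alphaAve(pi0)                          #> 0.0274  per-test level for FDR 0.05

ev <- trainAndEval(train, test, "svm", selectFeatures(train, 0.05), seed = 1)
ev
#> ClassifierEval: svm on 165 features (train n = 67+67)
#>   holdout accuracy 0.993 (MER 0.007), AUC 1.000 (AAC 0.000)
```

The numbers mean: of 165 nominally significant peptides only 123 survive
FDR control, and only 67.5% of those are confirmed when re-tested alone on
an independent cohort — multiplicity adjustment and external validation are
not optional. With all 67+67 training samples the SVM generalizes almost
perfectly; with 7 per group the same code gives LOOCV accuracy 1.00 against
a holdout accuracy of 0.76, the classic selection-bias optimism:

```r
sub <- train[, c(1:7, 68:74)]
feats <- selectFeatures(sub, 0.05)
loocv(sub, "svm", reselect = FALSE, features = feats)  #> 1.00
trainAndEval(sub, test, "svm", feats, seed = 1)$accuracy  #> 0.76
```

Discriminative sample size from a fitted learning curve:

```r
fit <- powerLawFit(gammaFloor = 0.03, scale = 1.39, rate = 0.716)
ndisc(fit, 0.10)   #> 65 samples per group for a 10% area above the curve
```

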