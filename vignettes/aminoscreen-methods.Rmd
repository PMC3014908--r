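---
title: "Methods: aminogram screening classifiers under a matched design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aminogram screening classifiers under a matched design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aminoscreen)
```

## The problem and the design

Plasma free amino-acid concentrations ("aminograms", 21 analytes in µM) are
systematically perturbed in lung-cancer patients. A screening index built
from them must respect the case-control design under which such data are
collected: controls are selected to match each patient on age, gender and
smoking status, so the analysis has to condition on those matching factors
rather than adjust for them. `aminoscreen` implements the complete
analysis: matching, univariate and principal-component profiling, subset
selection by cross-validated information criterion, conditional logistic
estimation, and ROC evaluation — together with a calibrated synthetic
cohort generator that makes every stage testable end to end.

## The synthetic-cohort generator

No patient-level data accompany the published study, so the generator is
calibrated to its printed summary tables and is itself a first-class,
tested component.

**Joint distribution.** Aminograms are multivariate normal on the raw µM
scale, with the group's published marginal means and SDs as exact
population parameters, and draws containing a non-positive coordinate
rejected and redrawn. A log-normal model would guarantee positivity
without rejection but would make the printed moments only approximate
targets; the normal-with-rejection model keeps them exact up to a small,
quantifiable truncation effect (below).

**Correlation.** Within-cohort correlations are not published. The default
uses biologically motivated equicorrelated blocks — branched-chain amino
acids (Val, Ile, Leu) at ρ = 0.7, aromatic amino acids (Tyr, Phe, Trp) at
ρ = 0.5, urea-cycle intermediates (Cit, Orn, Arg) at ρ = 0.4 — over a
baseline ρ = 0.2 for all other pairs, shared by both groups. These values
are typical of published plasma amino-acid correlation matrices and,
importantly, reproduce the *suppressor* behaviour visible in the reported
six-analyte model: Val and Trp have essentially null marginal group
differences yet carry significant negative coefficients multivariately,
which requires strong positive correlation with the elevated analytes
(Ile; and the aromatic block). Because the true correlation structure is
an assumption, the published PCA eigenvalues and loadings cannot be — and
are not — reproduced numerically; the PCA machinery is instead verified
against its own spectral invariants and the closed-form spectrum of the
configured correlation matrix.

**Demographics.** Gender and smoking margins, age mean/SD/range and BMI
mean/SD per group follow the published cohort characteristics; the small
"unknown smoking" counts are renormalized away. Age is truncated to the
published ranges by resampling. Stage (I/II/III/IV = 69/8/39/25 of 141)
and histology (adenocarcinoma/squamous/other = 100/36/4 of 140) are sampled
for cases only. Aminograms are independent of demographics and stage by
default, consistent with the reported stage-independent discrimination;
this also means the generator cannot emulate confounding of the aminogram
by age or smoking, which is precisely what the matched design guards
against in real data. Passing tests on synthetic cohorts therefore
demonstrate the correctness of the machinery, not the clinical performance
of the index on new populations.

**Truncation bias.** The positivity rejection step truncates the
multivariate normal to the positive orthant. With the default calibration
the only analyte whose mean sits closer than 2.8 SD to zero is Glu
(control mean/SD = 45.7/19.5 = 2.34 SD), so about 1% of control rows are
rejected, lifting the kept Glu mean by ≈ 0.026 SD and, through the
baseline correlation, other means by ≈ 0.005 SD. The package computes a
first-order analytic bound for this shift (inverse-Mills ratio of each
coordinate's negative tail, propagated through the correlation matrix),
and the calibration tests use *k*·SE + bound as their tolerance — the
bound is derived, not fitted, and matters only for Glu.

## Matching

Greedy 1:*m* nearest-age matching without replacement within exact
gender × smoking cells, processing cases in seeded random order with
seeded tie-breaks. The age caliper defaults to ±5 years — the study
reports near-identical group age means but no caliper, and ±5 y is the
conventional epidemiologic choice; it is a plain argument. Cases without
*m* eligible controls abort the match by default (`allow_partial = TRUE`
drops and reports them). Optimal (network-flow) and propensity matching
are out of scope.

## Profiling

The Mann–Whitney statistic counts case-control pairs with half credit for
ties. The two-sided p-value is exact by complete enumeration of labelings
when the smaller sample has ≤ 8 observations and the enumeration is
tractable (≤ 2×10⁵ labelings — with one tiny and one huge sample the exact
null is astronomically wide and the normal approximation is used instead);
otherwise it is the tie-corrected normal approximation without continuity
correction.

Standardization divides by the *population* (divide-by-n) SD, matching the
transformation printed with the published PCA; the column means and scales
are retained so new subjects can be projected. PCA eigen-decomposes the
correlation matrix of the pooled standardized cases and controls, so the
eigenvalues sum to 21 exactly; each loading column is oriented so its
largest-magnitude entry is positive (published loading signs are
recoverable only up to column sign). Components are retained by the Kaiser
rule (eigenvalue > 1), tested for a case-control score difference
(α = 0.05 by default; the study's retained components tested far below
that), and a variable contributes to a component when its squared loading
exceeds 0.05.

## Subset selection

The search enumerates every subset of 1–6 of the candidate analytes
("below seven" variables; 82,159 subsets from the full panel) in (size,
lexicographic) order. Each candidate is fitted by unconditional logistic
IRLS (tolerance 1e-8 on the coefficient change, 100 iterations, monotone
step-halving; separation surfaces as a non-convergence flag), its
leave-one-out out-of-fold probabilities are computed by literal refit —
n fits per candidate, warm-started at the full-data solution — and scored
by

AIC_cv = −2 Σᵢ [yᵢ ln p̂₍₋ᵢ₎ + (1−yᵢ) ln(1−p̂₍₋ᵢ₎)] + 2(k+1).

Whether the original analysis kept the 2(k+1) penalty on top of the
cross-validated deviance is not documented; the penalty is kept by default
(the criterion is, after all, called an AIC) and `penalty = FALSE` ranks by
pure cross-validated deviance. Probabilities are clipped to
[1e-12, 1−1e-12] before the logarithms so one separated fold cannot
produce an infinite deviance; a non-convergent fold marks the whole
candidate non-convergent (criterion +∞, ranked last) rather than being
skipped — conservative and deterministic. Ties in the criterion break
toward the smaller, then lexicographically earlier subset, making the
ranking independent of evaluation order and worker count. Selection uses
the unconditional likelihood; the matched structure enters only at the
final conditional fit.

## Conditional logistic regression and the discriminant score

With one case per stratum the conditional likelihood is
Π exp(x'_case β) / Σ_j exp(x'_j β) over stratum members; log-sum-exp terms
are computed with max-subtraction. Newton–Raphson with monotone
step-halving converges on a gradient norm below 1e-8 (100 iterations max);
standard errors come from the inverse observed information, and
per-variable p-values are Wald — (β/se)² against χ²₁ — matching the style
of the published per-analyte p-values (a likelihood-ratio alternative
would differ only in the third decimal at these sample sizes). There is no
intercept, and the matching covariates are deliberately *not* regressors:
both are absorbed by the conditioning. A covariate constant within every
stratum carries no conditional information and is rejected by name.

The discriminant score of any subject is the linear predictor x'β — the
logit of the conditional-logistic function value. The conditional model
identifies no intercept, so the score is defined up to a constant shift;
this is immaterial for ROC evaluation, which is rank-based, and it is the
only construction that applies unchanged to unmatched test-set subjects
and to other patient groups.

## Evaluation

AUC is the rank statistic (ties at half credit), identical to the
Mann–Whitney functional, with the full ROC polygon available. Subgroup
analysis computes each patient subgroup's scores against *all* controls of
the data set (the study does not describe sub-matching within subgroups);
subgroups under 3 patients are flagged. The analytic benchmark for the
six-analyte panel under the generator is the linear-discriminant AUC
Φ(√(Δ'Σ⁻¹Δ/2)) with the pooled covariance, ≈ 0.826 under the default
calibration — consistent with the published "> 0.8" headline, which is the
level at which the unreproducible cohort-specific AUCs (0.817 study /
0.812 test) are emulated.

## Problem sizes and reproducibility

All randomness flows from explicit seeds through named substreams
(generation, matching order, tie-breaks), and generation restores the
caller's RNG state. The test suite exercises study-scale configurations
throughout: calibration and correlation recovery at n = 10⁵; headline
discrimination as the mean AUC of ten independent 141-case/423-control
matched runs; selection on a 10-analyte pool with k_max = 3 (175
candidates) at study scale, with the 82,159-candidate full search counted
exactly and supported but not run routinely; conditional-logistic recovery
and coverage over 200 replicates of 500 simulated strata; and subgroup
exchangeability on 800-patient cohorts averaged over two seeds (at 141
cases a ~8-patient stage-II subgroup has an AUC standard error near 0.09,
too wide to support a pointwise check). Oracles are independent routes:
exhaustive permutation for the rank tests, pair enumeration for AUC,
per-fold `glm` refits for LOOCV, grid search and the survival package for
the conditional likelihood.

## Limitations

The generator emulates printed marginal summaries with an assumed
correlation structure; it does not model measurement error of the
chromatography-mass-spectrometry assay, fasting or diurnal variation,
cachexia-related drift, or aminogram-demographic dependence. Conclusions
from synthetic runs concern the correctness and stability of the
statistical machinery, not clinical screening performance, which requires
prospective cohorts.
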