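# aminoscreen

Plasma free amino-acid ("aminogram") profiles shift in cancer patients
because tumour metabolism perturbs the inter-organ amino-acid balance.
`aminoscreen` implements the statistical machinery for turning a 21-analyte
plasma aminogram into a screening index for non-small-cell lung cancer under
a matched case-control design, and for evaluating how well that index
separates patients from controls. It is aimed at statisticians and
metabolomics analysts who want a reproducible, fully testable version of
this analysis — including a calibrated synthetic-cohort generator, so the
whole pipeline runs without access to any patient-level data.

## What it computes

Given cases and a pool of candidate controls, the pipeline

1. **matches** each case to *m* controls sharing gender and smoking
   category, with |Δage| ≤ caliper (greedy nearest-age, without
   replacement), forming the strata for conditional inference;
2. **profiles** the 21 analytes: group means/SDs, Mann–Whitney U tests,
   per-analyte ROC areas, and PCA of the standardized concentrations
   z<sub>ij</sub> = (x<sub>ij</sub> − x̄<sub>j</sub>) / s<sub>j</sub>
   (population SD), with Kaiser retention (eigenvalue > 1), per-component
   group tests, and contributor extraction (squared loading > 0.05);
3. **selects** an amino-acid subset by exhaustive search over all subsets of
   at most 6 of the 21 analytes (82,159 candidates), each scored by an
   unconditional logistic fit whose Bernoulli log-likelihood is replaced by
   its leave-one-out cross-validated counterpart:
   AIC<sub>cv</sub> = −2 Σᵢ [yᵢ ln p̂₍₋ᵢ₎ + (1−yᵢ) ln(1−p̂₍₋ᵢ₎)] + 2(k+1);
4. **fits** conditional logistic regression on the matched strata for the
   selected subset — the likelihood Π exp(x'<sub>case</sub>β) / Σ<sub>j∈stratum</sub> exp(x'<sub>j</sub>β)
   conditions out the matching factors — and defines each subject's
   **discriminant score** as the logit of the fitted conditional-logistic
   function value, i.e. the linear predictor x'β;
5. **evaluates** the score by ROC AUC (rank statistic, ties at half credit),
   overall and within stage and histology subgroups.

The synthetic generator draws aminograms from a multivariate normal whose
marginal means/SDs equal the published group summaries of the study cohorts
(141 NSCLC patients, 423 matched controls), with biologically motivated
correlation blocks (BCAA 0.7, aromatic 0.5, urea-cycle 0.4, baseline 0.2)
and rejection of non-positive draws.

## Worked example

```r
library(aminoscreen)
cfg     <- default_generator_config()
cases   <- generate_cohort(cfg, "case", 141, seed = 1)
pool    <- generate_cohort(cfg, "control", 4000, seed = 2)
matched <- match_controls(cases, pool, ratio = 3, caliper = 5, seed = 3)
matched
#> Matched case-control strata: 141 strata, 1:3 ratio, age caliper 5 y
#>   cases: 141  controls: 423  age SMD: 0.001

fit <- fit_conditional(matched, c("Ala", "Val", "Ile", "His", "Trp", "Orn"))
summary(fit)
#> Conditional logistic regression (141 strata)
#>       Estimate Std. Error       z  Pr(>|z|)
#> Ala  0.0041784  0.0014590  2.8639 0.0041852 **
#> Val -0.0204265  0.0037613 -5.4308 5.612e-08 ***
#> Ile  0.0657750  0.0095757  6.8689 6.469e-12 ***
#> His -0.0371999  0.0106292 -3.4998 0.0004656 ***
#> Trp -0.0081892  0.0125493 -0.6526 0.5140422
#> Orn  0.0465224  0.0090719  5.1282 2.926e-07 ***
#> Conditional log-likelihood: -116.273 (null -195.468)

controls <- matched[matched$group == "control", ]
auc(discriminant_score(fit, cases), discriminant_score(fit, controls))
#> [1] 0.832
```

The coefficients are log-odds per µM. Ile, Orn and Ala (raised in patients)
enter positively; His (lowered) negatively; Val acts as a classic suppressor
— its marginal group difference is negligible, but its strong correlation
with Ile makes its negative coefficient sharpen the contrast. The AUC of
0.832 sits near the analytic population value of the panel under the
generator, Φ(√(Δ'Σ⁻¹Δ/2)) ≈ 0.826.

`exhaustive_search()` runs the subset selection (use the `variables`
argument to restrict the pool for desk-scale runs), and `run_pipeline()`
drives generation → matching → profiling → selection → conditional fit →
scoring → reporting from a single seeded configuration, writing all
artifacts plus `summary.json`.

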