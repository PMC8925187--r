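---
title: "Methods: symptom clustering and past-mercury exposure modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symptom clustering and past-mercury exposure modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgclust)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the defaults and why they were chosen, and
the limits of what the test suite demonstrates.

## 1. The analysis problem

A community health survey scores many neurological and mood symptoms on
5-point Likert scales. Mercury biomarkers — umbilical-cord blood at birth,
and hair or blood samples collected opportunistically across roughly three
decades — exist for only part of the cohort, with most people measured a
handful of times and a small minority measured in ten or more years.
The pipeline answers four questions in sequence:

1. Which symptoms co-occur, and how reliably can they be summarised by a
   few composite dimensions?
2. What was each person's prenatal and childhood mercury exposure, given
   that most have no direct measurement for those windows?
3. Do the reconstructed exposures relate to the symptom dimensions, and
   through which pathways?
4. In the subset with dense longitudinal hair data, do people above the
   median of a composite score carry higher hair mercury over the
   sampling period?

## 2. Variable clustering

For a set `C` of standardized variables the homogeneity `H(C)` is the
leading eigenvalue of their correlation matrix; it equals the sum of
squared correlations of the members with the cluster's first principal
component, ranging from 1 (orthogonal members) to `|C|` (collinear
members). Agglomeration starts from singletons and merges the pair
minimizing `d(A, B) = H(A) + H(B) − H(A ∪ B)`; `d` is non-negative
because the leading eigenvalue of a block matrix cannot exceed the sum of
the blocks' leading eigenvalues, and the package asserts this on every
merge. Likert scores are treated as numeric 1–5 values: with
all-quantitative input, the mixed-data principal-component machinery
reduces to PCA of standardized variables, and the composite the analysis
interprets is exactly a weighted linear combination of symptom scores.
A polychoric variant of the criterion is deliberately out of scope.

The number of clusters is selected by bootstrap stability: resample
participants with replacement (`B = 60` by default), rebuild the tree, cut
at each candidate `K`, and compare to the full-data partition at the same
`K` by the Hubert–Arabie adjusted Rand index. `select_k()` maximizes the
mean ARI and breaks ties toward the largest gap in the merge-cost path,
but always returns the full diagnostic table — on real data the choice of
`K` deserves a human look at aggregation levels and the ARI spread, and
the automatic rule is only a reproducible default.

Pruning applies two published-practice thresholds: a symptom must have
squared correlation ≥ 0.6 with its own composite, and a retained cluster
must explain ≥ 50% of its members' variance. Pruning iterates to a
fixpoint, never removes a cluster's last member (a collapsing cluster is
flagged degenerate instead of vanishing silently), and recomputes
composites after every removal. Missing Likert cells use
pairwise-complete correlations; a participant's composite score uses
available-item mean imputation when at least half the cluster's items are
observed and is missing otherwise. The per-cluster "driving symptom"
reported by `varclust()` is simply the member with the highest squared
loading — an interpretive convenience, not a test.

## 3. Exposure reconstruction

`build_yearly_hair()` converts blood to equivalent hair at 0.25 µg/g per
µg/L — a conventional 250:1 hair-to-blood concentration ratio, exposed as
a parameter because monitoring programmes differ — and keeps the highest
equivalent value per person-year, reflecting that a year's worst exposure
is the toxicologically relevant summary when segments of a single year
are sampled repeatedly.

Reconstruction is measurement-first and era-aware. Childhood exposure is
the arithmetic mean of yearly values at ages 5–15 when any exist.
Otherwise the cascade attributes, in order: the cohort's mean
equivalent-hair value in the year the person turned 10; the era constant
0.1 µg/g for people already 10 or older in 1962 (before the discharge);
0.81 µg/g for people turning 10 after 1990 (the late-period plateau).
Prenatal exposure is the measured cord value when present; otherwise the
mean measured cord value of the birth year (when at least 3 measured
births exist — below that the within-period regression of log10 cord Hg
on birth year predicts instead, and both paths are recorded in the
provenance column); the era constants 1.0 µg/L (born before 1962),
65.7 µg/L (born 1962–1969, the 1970 mean), 4.48 µg/L (born after 1992,
the 1992 mean); and 1.0 µg/L regardless of year when the mother spent the
pregnancy elsewhere. Era boundaries follow the half-open reading
consistent with the 1970 and 1992 constants being those years' means:
"before 1962" is birth year ≤ 1961, "between 1962 and 1970" is
1962–1969, "after 1992" is ≥ 1993, "≥ 10 years old in 1962" is birth
year ≤ 1952, and "10 after 1990" is turning 10 in 1991 or later.

Estimates (never measurements) are adjusted multiplicatively by the
ratio of the geometric-mean measured childhood value in the person's
childhood-fish-consumption × residential-school stratum to the overall
geometric mean, computed within childhood eras when enough measured data
exist and globally otherwise. This reproduces the direction of the
stratum contrasts seen in measured data — frequent fish eaters higher,
residential-school attendees lower — without inventing regression
coefficients; the exact adjustment used in the motivating analysis is
not published, and this multiplicative-stratum scheme is one admissible
reading, recorded as such. A childhood estimate is undefined when the
fish-consumption answer is missing and no measurement exists. Mercury
values are log10-transformed wherever they enter regressions or SEMs,
following the skewness rule applied throughout.

## 4. Structural equation models

Ordinal symptom indicators (and the binary ever ≥ 5 µg/g and diagnosed
nervous-system-disorder variables) enter through polychoric, polyserial
and Pearson correlations with thresholds estimated from the margins
(two-step maximum likelihood). The bivariate-normal rectangle
probabilities behind the polychoric likelihood are computed in C++ by
Gauss–Legendre quadrature of the angular representation for |r| < 0.925
and by direct quadrature of the conditional-probability integral above
that, accurate to ~1e-15 and ~1e-6 respectively against an independent
numerical-integration oracle.

Estimation minimizes the diagonally weighted least-squares discrepancy —
weights are inverse asymptotic variances of the correlation estimates,
obtained from per-observation influence functions — by Levenberg–
Marquardt iteration on the numeric moment Jacobian. Because DWLS weights
are not the inverse of the full asymptotic covariance, the package never
reports the naive statistic: the chi-square is mean-scaled by
`trace(U Γ)/df` with `Γ` the full influence-function covariance of the
moments, parameter standard errors are sandwich estimates under the same
`Γ`, and modification indices are robust score tests in which the freed
parameter's direction is residualized against the free parameters (by QR
projection, which keeps the test stable when a candidate is nearly
collinear with the fitted model; genuinely collinear candidates return
`NA` and are flagged). Fit indices are recomputed from the scaled
chi-square, its degrees of freedom and `N − 1` — `RMSEA =
sqrt(max(χ²−df, 0)/(df(N−1)))` with a 90% CI by noncentrality inversion,
CFI/TLI against the zero-covariance independence baseline, SRMR as the
root-mean-square correlation residual — rather than trusted from any
internal state. AIC/BIC are the quasi versions `χ² + 2q` and
`χ² + q log N`, meaningful only for comparing models on the same data.

Latent scales are identified by fixing each latent's (residual) variance
to 1 with all loadings free. The more common first-loading-fixed
convention is available (`identification = "loading"`), but it is fragile
exactly where this pipeline needs stability: in the latent past-Hg
construct the natural first indicator (log cord Hg) can correlate weakly
with the other exposure indicators — reconstructed cord values are
non-monotone in birth year because people born before the discharge
combine floor-level prenatal exposure with high childhood exposure — and
scaling the latent by a weak indicator sends the optimizer along a flat
ridge. The standardized solution, which is what the analysis reports and
compares, is identical under either identification.

Two model families are built per retained cluster.
`sem_spec_latent_hg()` measures a latent past-mercury construct by log10
cord, log10 childhood and the exceedance indicator, regresses the
symptom-cluster latent on it together with covariates, and routes a
mediated path through the diagnosed nervous-system disorder.
`sem_spec_separate()` keeps the exposures observed, with childhood
mediating prenatal exposure and the disorder mediating childhood
exposure. `decompose_effects()` enumerates all directed paths from an
exposure to the cluster in the fitted standardized graph; each indirect
effect is the product of standardized coefficients along one path, the
total is direct plus the sum of indirect, and delta-method standard
errors come from the sandwich covariance. Moderation by sex is a
two-group comparison: the Wald test of the group difference in the
target path (sandwich SEs) alongside a scaled chi-square difference
whose 1-df correction factor is the trace of the projection difference
against the stacked moment covariance. Power analyses follow the
noncentral-chi-square RMSEA framework (`λ = (N−1)·df·ε²`; when the null
and alternative RMSEA coincide the power is α by construction) and a
Monte-Carlo rejection rate for a target standardized path.

Missing survey covariates are completed by chained equations
(`mice_impute()`: predictive mean matching for continuous, logistic
draws for binary, proportional-odds draws for ordered variables; m = 5
by default with Rubin-rule pooling helpers). The number of imputations
is a convention; the motivating analysis states the method but not m.

## 5. Longitudinal mixed models

Participants with at least 10 yearly hair values are median-split on
each retained cluster's composite score (ties at the median go below —
the conservative side). REML fits log10 hair mercury on score group, age
at sampling, sex and mean-centred calendar year with a person-level
random intercept; the published footnote "age of sampling nested in year
of sampling" is ambiguous, so that structure (random intercepts for
sampling year with an age slope, simplified automatically when singular)
is offered behind `random = "year_nested"` rather than silently chosen.
The group coefficient is reported both in log10 units and back-
transformed as a multiplicative ratio, because the original scale
handling is unstated and an additive µg/g difference is not stable under
the log-normal error model. Model support is reported by AIC/BIC and a
boundary-corrected likelihood-ratio test against the fixed-effects-only
model; residual normality by a q-q table and Shapiro–Wilk statistic.

The sample-size module implements the compound-symmetry two-group
formula `N/group = 2(z₁₋α/₂ + z₁₋β)²(1 + (n−1)ρ)/(nΔ²)` with defaults
α = 0.05, power 0.80, 10 time points, ρ ∈ {0.1, 0.2} and effect 0.25.
Whether 0.25 was meant as Cohen's d or Cohen's f in the original
calculation is unknowable from the text, so both are computed and
labelled (f doubles into d); across that grid the minimum total N spans
24–142, which brackets the 29–42 range the motivating study reported
without claiming to reproduce its exact software configuration. The
Monte-Carlo check exploits that under compound symmetry with balanced
data the mixed-model group contrast equals the two-sample t-test on
person means; `long_power_analytic()` evaluates the exact noncentral-t
power at a given N, which is the fair comparison at small N where the
z-approximation in the closed-form N overshoots by a few points.

## 6. The synthetic cohort generator

`generate_cohort()` is first-class, tested code that defines the study
conditions for every recovery claim in the test suite. Its defaults: 391
participants born 1950–1992 and surveyed in 2016; 59 symptom columns of
which 37 load on 6 latent factors (sizes 9, 7, 6, 6, 5, 4) and 22 are
noise; factor loadings U(0.85, 0.95); discretization at cut-points
(−1.5, −0.5, 0.5, 1.5); cord mercury log10-piecewise-linear through
geometric means 65.7 (1970), 18 (1977), 6.5 (1988) and 4.48 µg/L (1992)
with 0.25 log10 scatter and half the in-window births measured; hair
mercury declining through 8, 3, 1, 0.8 µg/g (1970–1997) with 0.3 log10
between-person and 0.2 log10 within-person SD and AR(1) ρ = 0.3;
person-years sampled with Beta-heterogeneous propensities of mean 0.2 so
that a minority of people accumulate ≥ 10 measurements, as in
opportunistic monitoring; a nervous-system-disorder mediator with
baseline prevalence 24% and log-odds 0.6 per SD of log childhood
exposure; standardized exposure effect 0.3 on each factor; 5% MCAR
missingness on Likert cells and 3% on covariates.

Two defaults deserve their rationale spelled out. The **loading range
0.85–0.95** is derived from the pruning rule the pipeline itself
applies: after 5-level discretization (categorical attenuation ≈ 0.9 on
the correlation scale), an item's squared correlation with its composite
clears the 0.6 retention threshold reliably only when the continuous
loading is about 0.85 or higher; a generator claiming to emulate
batteries whose retained clusters show reliability above 0.8 should
plant items that survive its own retention rule. The **AR(1) within-
person correlation 0.3** is a modelling convenience: the within-person
autocorrelation of yearly hair mercury is not reported anywhere we can
cite, so the generator exposes it as a parameter without claiming
fidelity.

What the generator does **not** emulate: informative missingness
(holes are MCAR), seasonality of fish consumption and hair growth,
measurement error correlated with exposure level, cohort attrition, and
the full 266-question survey instrument. Passing recovery tests
therefore show that the pipeline's estimators are consistent and
calibrated under the generative model they assume — not that the
motivating study's effect estimates are correct, and not that the
pipeline is robust to violations the generator cannot produce.

## 7. Numerical choices and degenerate inputs

* Merge ties in the clustering tree break toward the lexicographically
  smallest symptom label; bootstrap replicates that produce a constant
  column are dropped and counted with a warning.
* The unit diagonal of the correlation matrix enters the SEM moment
  vector with a large fixed weight (20× the largest off-diagonal
  weight), letting residual variances absorb it; degrees of freedom
  count those moments and parameters consistently with the standard
  ordinal-SEM bookkeeping.
* Variance parameters may go mildly negative during optimization so
  that Heywood cases are flagged (`heywood = TRUE`) rather than masked
  by a bound; non-convergence is reported, never silently replaced by a
  fallback.
* `N − 1` (not N) multiplies the discrepancy in the chi-square and the
  RMSEA noncentrality; conventions differ and this one is stated.
* Zero-variance columns, all-identical scores in a median split,
  constant residuals in diagnostics, empty hair series, ties-only
  Spearman input and cyclic structural graphs all raise errors naming
  the offending object; an empty exceedance series yields `NA`
  ("not computable"), not `FALSE`.
* All randomized stages take explicit seeds; the pipeline derives named
  sub-seeds deterministically from one master seed (kept below 2³¹) and
  two runs with the same configuration produce byte-identical output
  tables.

## 8. Problem sizes used by the tests

The test suite exercises recovery at the generator's study conditions:
100 cohorts of 391 × 59 for clustering recovery; 100 fits at n = 250 and
500 null fits for the SEM path estimate and its type-I rate; 100
planted and 400 null longitudinal fits at 40 persons × 12 years; a 3 × 3
(ρ × effect) grid with 1000-replicate Monte-Carlo power per cell; and a
double end-to-end run of the 391-participant demo pipeline compared file
by file. The acceptance script reports the same quantities at reduced
replicate counts (25 recovery seeds, 200 null replicates) so that the
whole recomputation stays under a minute; replicate counts are part of
each reported value's `n` field.

## 9. Known limitations

* The polychoric layer estimates thresholds per margin and ignores
  threshold uncertainty in the influence functions (the usual two-step
  simplification); at the cohort sizes involved this is visible in
  nothing the test suite measures, but very small samples would deserve
  full-information estimation the package does not provide.
* The DWLS engine handles the model classes the pipeline needs —
  measurement models, recursive structural graphs, residual covariances,
  two-group equality constraints. It is not a general SEM system: no
  nonlinear constraints, no multi-level models, no missing-data FIML.
* Mediation inference uses delta-method standard errors on standardized
  products; product distributions are skewed at small n and a
  bootstrap would be preferable when a single indirect path is the
  headline estimate.
* The exposure adjustment scheme is one admissible reading of an
  under-specified published procedure; its provenance column exists so
  that sensitivity analyses can drop or replace adjusted values.
* Automatic K selection follows stability alone; the motivating
  analysis combined stability with visual inspection, and so should any
  real application of this package.
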