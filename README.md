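# hgclust

Tools for linking **reconstructed past mercury exposure** to **clusters of
co-occurring neurological symptoms** in community health survey data.

The package grew out of the analysis problem faced by long-running
freshwater-contamination studies: a recent survey records dozens of
self-reported symptoms on 5-point Likert scales, while mercury biomarkers
(umbilical-cord blood, yearly hair samples, blood samples converted to
equivalent hair concentrations) were collected opportunistically decades
earlier, so most participants have sparse or missing measurements. The
analysis must (i) reduce the symptom battery to a small number of reliable
composite dimensions, (ii) reconstruct each person's prenatal and
childhood exposure by rules when measurements are absent, (iii) relate
exposure to the symptom dimensions with models that respect the ordinal
outcome scale and allow mediation, and (iv) check the longitudinal signal
directly in the people with enough repeated hair measurements. `hgclust`
implements that pipeline end to end, plus a synthetic-cohort generator
with planted ground truth, because the motivating datasets are not
publicly distributable.

## The methods at the core

**Variable clustering.** Symptoms are clustered by hierarchically
maximizing a homogeneity criterion: for a cluster *C* of standardized
variables, *H(C)* is the leading eigenvalue of their correlation matrix,
equal to the sum of squared correlations of the members with the
cluster's first principal component. Merging the pair minimizing
*d(A,B) = H(A) + H(B) − H(A∪B)* (which is provably ≥ 0) yields a tree;
the number of clusters is chosen from aggregation levels and the mean
adjusted Rand index over bootstrap resamples of participants. Each
cluster produces a **composite variable** (first-PC score, oriented so
that higher = more frequent symptoms); symptoms with squared correlation
< 0.6 with their composite are pruned, and clusters explaining < 50% of
their members' variance are not retained. Cronbach's alpha reports scale
reliability.

**Exposure reconstruction.** Yearly equivalent-hair series keep the
highest measurement per person-year (blood converted at 0.25 µg/g per
µg/L). Childhood exposure is the mean of values at ages 5–15;
prenatal exposure is the measured cord value. When measurements are
missing, a measurement-first rule cascade attributes year means,
period-regression predictions (log10 cord Hg on birth year within
1970–1976, 1977–1987, 1988–1992), or era constants: 1.0 µg/L before the
1962 discharge and for pregnancies spent elsewhere, 65.7 µg/L for births
1962–1969, 4.48 µg/L after 1992; childhood hair 0.1 µg/g for people aged
≥ 10 in 1962 and 0.81 µg/g for those turning 10 after 1990. Estimates
(never measurements) are adjusted multiplicatively by the childhood
fish-consumption × residential-school stratum.

**Structural equation models.** Ordinal indicators enter through
polychoric/polyserial correlations; estimation is diagonally weighted
least squares with a mean-scaled test statistic and sandwich standard
errors computed from influence functions. Two model families per symptom
cluster: a **latent past-Hg** construct measured by prenatal, childhood
and ever ≥ 5 µg/g indicators, and a **separate-exposures** model where
childhood mediates prenatal exposure and a diagnosed nervous-system
disorder mediates childhood exposure. Standardized path coefficients,
direct/indirect/total effect decomposition, modification indices,
sex-moderation tests and RMSEA-based power analyses are provided.

**Longitudinal mixed models.** For participants with ≥ 10 yearly hair
values, log10 hair Hg is regressed on the median-split composite score
group, age at sampling, sex and calendar year with a person-level random
intercept (REML, via `lme4`); the group coefficient is the difference in
hair mercury between score groups over the sampling period.

**Power.** The compound-symmetry sample-size formula
*N/group = 2(z₁₋α/₂+z₁₋β)²(1+(n−1)ρ)/(nΔ²)* for the longitudinal
two-group design, evaluated over ρ ∈ {0.1, 0.2} and both Cohen-d and
Cohen-f readings of the effect size, with a Monte-Carlo oracle.

## Worked example

```r
library(hgclust)

co  <- generate_cohort(synthetic_params(seed = 17))   # 391 participants
rep <- run_pipeline(co$survey, co$cord_table, co$biomarker_table,
                    pipeline_config(seed = 17))

rep$selection$K                       # stability-selected cut
#> [1] 8
table(rep$clusters$cluster[rep$clusters$retained])
#> 1 2 3 4 5 6
#> 6 4 6 5 9 7
round(rep$cronbach, 2)
#> [1] 0.95 0.93 0.95 0.93 0.97 0.95   NA   NA
rep$subset_sizes
#> clustering        sem       lmem
#>        391        356         51
print(rep$lmem[1, c("estimate_log10", "ratio", "p")], digits = 2)
#>          estimate_log10 ratio     p
#> cluster1           0.25   1.8 0.015
```

The cohort plants six symptom clusters (37 informative symptoms among
59 columns) and a standardized exposure effect on each cluster. The
bootstrap cut at K = 8 leaves the noise columns in two catch-all groups
that fail the retention rules (their reliability is the two `NA`s);
pruning keeps exactly the 37 informative symptoms in 6 retained
clusters with internal consistency above 0.9. The longitudinal model
estimates hair mercury about 1.8× higher in participants above the
median of the first composite score (p = 0.015 in this cohort).
`rep$sem` holds the fitted path models with fit indices and effect
decompositions per cluster and exposure mode.

A thin command-line wrapper ships in `exec/`:

```sh
hgclust simulate --out demo --n 391 --seed 17
hgclust run --dir demo --out results
hgclust power --rho 0.1,0.2 --effect 0.25
```

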