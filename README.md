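# riskburden

Most common diseases — coronary artery disease (CAD), type 2 diabetes,
breast and prostate cancer — are shaped by hundreds of common risk alleles,
each with a small effect (per-allele odds ratios mostly between 1.02 and
1.25). Every person carries a large number of them: for a panel of ~200 CAD
loci, around 190 on average, approximately normally distributed across a
population. `riskburden` is an R toolkit for studying how such alleles
combine — with each other and with modifiable exposures such as smoking,
obesity or diabetes — to determine disease prevalence.

The package implements, as tested tidyverse-style functions over plain
tibbles and matrices:

- **Scoring** — unweighted allele-count genetic risk scores (GRS) and
  log-odds-weighted scores (wGRS = Σⱼ ln(ORⱼ)·xᵢⱼ) from GWAS summary
  statistics and genotype dosages (VCF or matrix), with risk-allele
  orientation and expectation imputation of missing genotypes (2·RAF).
- **Stratification** — balanced score deciles/percentiles; per-stratum
  prevalence, mean allele count, and *prevalence per risk allele*
  (prevalence ÷ mean count, the statistic that reveals whether a given
  allele's absolute effect depends on its carrier's total burden); fold
  changes top vs bottom stratum; width-2 count histograms and a
  Kolmogorov–Smirnov normality check; linear trend tests.
- **Link-function comparison** — individuals grouped by exact allele count
  (groups with > 200 subjects retained), binomial GLMs of status on count
  fitted by IRLS under the identity, logit, probit and log links, each
  scored by the Pearson correlation R (with Fisher-z 95% CI) between
  observed and predicted group prevalence. A multiplicative (log-odds
  additive) disease architecture makes the three non-linear links fit
  near-identically and beat the identity link.
- **Panel exchangeability** — random sub-panel resampling and greedy
  odds-ratio matching of annotated vs unannotated variants, with
  cross-classification of one sub-score inside a fixed stratum of another.
- **Gene–environment amplification** — exposure-stratified prevalence
  across genetic strata, absolute-difference amplification folds, and
  linear/quadratic fits to the difference curve.
- **A synthetic-cohort simulator** — Hardy–Weinberg genotypes at
  independent loci, binary exposures, and case status under either a
  multiplicative (logistic) model or an additive absolute-risk null, with
  the intercept calibrated by bisection to a target prevalence. Every
  analysis in the package runs end to end on simulated data; no
  access-controlled biobank data are required.

## Worked example

Simulate a CAD-like cohort (100,000 individuals, 198 loci, ~4.75%
prevalence, smoking/obesity/diabetes exposures), score it, and stratify:

```r
library(riskburden)

cohort  <- simulate_cohort(sim_config(n_individuals = 100000, seed = 42))
scores  <- compute_scores(cohort$dosage, cohort$panel)
deciles <- assign_quantile_strata(scores$count_score, k = 10, seed = 42)
tab     <- stratum_summary(deciles, cohort$phenotypes$case, scores$count_score)
tab[c(1, 10), ]
#>   stratum n_cases n_controls prevalence mean_count per_allele_prevalence
#> 1       1     202       9798     0.0202       185.              0.000109
#> 2      10     893       9107     0.0893       216.              0.000414
fold_summary(tab)
#>   reference comparison allele_fold risk_fold per_allele_fold
#> 1         1         10        1.17      4.42            3.79
```

The top decile carries only 17% more risk alleles than the bottom decile,
yet is 4.4-fold more often diseased, and each single allele it carries is
associated with a 3.8-fold larger per-allele prevalence — the signature of
risk alleles multiplying rather than adding.

Compare the four link functions on the allele-count prevalence curve:

```r
compare_links(round_counts(scores$count_score), cohort$phenotypes$case,
              min_group_size = 200)
#>   link   intercept   slope     r ci_low ci_high converged
#> 1 logit    -13.2   0.0506  0.970  0.945   0.983 TRUE
#> 2 log      -12.7   0.0477  0.970  0.945   0.983 TRUE
#> 3 probit    -6.38  0.0233  0.969  0.944   0.983 TRUE
#> 4 linear   -0.307  0.00177 0.940  0.893   0.967 TRUE
```

The three non-linear links are indistinguishable (ΔR < 0.001) and all beat
the identity link. Finally, stratify prevalence by an exposure:

```r
gxe <- stratified_prevalence(deciles, cohort$phenotypes$case,
                             cohort$phenotypes$smoking)
amplification_summary(gxe, low = 1, high = 10)
#> [1] 5.12
```

The absolute prevalence difference attributable to smoking is ~5-fold
larger in the top genetic decile than in the bottom one: a high allele
burden amplifies the absolute effect of the exposure.

`run_pipeline()` (or `inst/scripts/run_pipeline.R` from a shell) chains the
stages from a YAML configuration, writing versioned, hash-stamped TSV
outputs plus a checksum manifest.

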