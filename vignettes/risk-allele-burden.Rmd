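---
title: "Modelling cumulative risk-allele burden and disease prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cumulative risk-allele burden and disease prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskburden)
```

## The scientific question

A person's genetic liability to a common disease is spread over hundreds of
loci, each contributing a per-allele odds ratio barely above 1. Two views of
how those contributions combine make sharply different predictions:

* **Additive (absolute-risk) combination.** Each risk allele adds a fixed
  absolute increment to disease probability. Prevalence is then linear in
  the allele count, and the prevalence *per allele carried* is the same for
  everyone.
* **Multiplicative (odds-scale) combination.** Each allele multiplies the
  odds, i.e. effects add on the log-odds scale. Absolute risk then grows
  faster than linearly with the count, and the same allele conveys a larger
  absolute effect in a heavily burdened carrier than in a lightly burdened
  one. Binary exposures that multiply odds are amplified in exactly the
  same way.

`riskburden` operationalises the comparison: stratify a cohort by
risk-allele count, trace prevalence and per-allele prevalence across
strata, fit binomial regressions under identity/logit/probit/log link
functions and score them by observed-vs-predicted correlation, test whether
sub-panels of alleles are exchangeable, and measure how exposures' absolute
effects scale with genetic burden. A simulator generates cohorts under
either architecture, so every claim the package makes can be exercised — and
falsified under the null — without restricted biobank data.

## The scores

For a risk-oriented panel of $L$ biallelic loci with dosages
$x_{ij} \in \{0,1,2\}$:

* allele-count GRS: $c_i = \sum_j x_{ij}$;
* weighted GRS: $w_i = \sum_j \ln(\mathrm{OR}_j)\, x_{ij}$ (natural log —
  "log odds ratio" is base-ambiguous, so the choice is stated here once).

Orientation (`flip_to_risk()`) guarantees $\mathrm{OR}_j \ge 1$, so every
counted allele increases risk; a variant with $\mathrm{OR} = 1$ exactly is
kept as given. Missing genotypes are replaced by their Hardy–Weinberg
expectation $2 \cdot \mathrm{RAF}_j$, taken from the published summary
statistics rather than the sample frequency (the published panel defines
the score; a `from = "sample"` switch exists). Expectation imputation
yields fractional counts; quantile strata use them as-is, while exact-count
grouping rounds half to even first (`round_counts()`) — both behaviours are
exposed because published analyses rarely state which was used.

## The stratification engine

`assign_quantile_strata()` guarantees stratum sizes differing by at most
one. This is not cosmetic: integer allele counts produce thousands-strong
ties at decile boundaries, and any deterministic tie rule would make decile
membership depend on input order. Ties are therefore broken by a seeded
random permutation within each tied value; a `"value_complete"` mode (all
carriers of a count share a stratum, sizes unequal) is available for
sensitivity analysis.

Per stratum the summary reports cases, controls, prevalence, mean ± sd
allele count, and **prevalence per risk allele** — stratum prevalence
divided by mean allele count. Under additive combination this quantity is
flat across strata; under multiplicative combination it rises, and its
top-vs-bottom fold is the headline amplification statistic.

On normality checking: allele counts are a sum of ~200 independent
Binomial(2, RAF) variables and are extremely close to normal, but they live
on an integer lattice. The one-sample Kolmogorov–Smirnov statistic against
a moment-matched normal is bounded below by about half the modal bin
probability — ≈ 0.023 at sd ≈ 9 — so at biobank sample sizes the KS *p*
value always rejects regardless of how normal the underlying distribution
is. `ks_normality()` therefore reports the statistic, and the package's
own normality criterion is $D < 0.05$, i.e. within noise of the lattice
floor. The asymptotic p value is reported for completeness, and a
Lilliefors-corrected option exists because estimating mean and sd from the
same data inflates the uncorrected p.

## The link-function comparison

Individuals are grouped by exact allele count and groups with more than 200
subjects are retained (strictly "more than"; the filter exists because the
tail groups' observed prevalences are dominated by noise). A binomial GLM
of status on count is fitted under four links: identity ("linear"), logit,
probit, log. Each fit is scored by the unweighted Pearson correlation
between observed and predicted group prevalence with a Fisher-z 95% CI —
Pearson, not Spearman, because the comparison concerns how well the curve's
*shape* is reproduced, and unweighted by default with a size-weighted
option, since the grouping already filtered unstable groups.

Numerical choices in `fit_link()`:

* Fitting is by iteratively reweighted least squares with **step-halving**
  whenever a step would increase the deviance, and fitted probabilities are
  clamped to $[10^{-12}, 1 - 10^{-12}]$. The identity and log links need
  this: their inverse can leave $(0,1)$, which is why `stats::glm()`
  refuses the identity link for the binomial family altogether and often
  fails to find log-link starting values. Starting values come from a
  weighted regression of the link-transformed, shrunken group prevalences
  $(y+0.5)/(n+1)$ on the count.
* The model is fitted on data aggregated by distinct count. With a single
  count covariate the aggregated binomial likelihood is *identical* to the
  individual-level Bernoulli likelihood, so this is a pure speed
  optimisation, not an approximation — fits take milliseconds at any cohort
  size.
* Convergence is declared on a relative deviance change below $10^{-10}$;
  non-convergence and separation (unbounded slope or all fitted values at
  the clamp) are flagged, never silently accepted.

The tests hold these fits to two independent standards: direct
maximum-likelihood optimisation (Nelder–Mead on the binomial
log-likelihood, plus a dense parameter grid) on small fixtures for all four
links, and `stats::glm()` agreement for the two links it supports robustly.

At population prevalences below ~10% the logit, probit and log links are
nearly affine reparameterisations of each other over the observed count
range, so their R values agree to within ~0.01–0.02 and no winner among
them should be expected or trusted; the meaningful contrast is non-linear
vs identity.

## Exchangeability analyses

`random_subsets()` + `replicate_fit_distribution()` re-run the grouping and
link fits on random sub-panels (e.g. half the loci). If only the *number*
of risk alleles matters, the distribution of R across random half-panels is
tight. The default replicate count for a production run is 10,000; the test
suite and examples use tens of replicates because the mean and sd of R
stabilise far earlier.

`match_by_or()` builds an effect-size-matched comparison panel for a tagged
subset (e.g. lipid-associated loci) by greedy nearest-neighbour matching on
$|\Delta \ln \mathrm{OR}|$ without replacement, processing targets in
descending odds ratio. Greedy rather than optimal assignment is the
default because it is deterministic and auditable pair by pair; matching
quality is reported (`delta_log_or` attribute) and a tolerance violation
warns or errors. `cross_classification()` fixes the top decile of one
sub-score and splits it by whole-population strata of the other (1st
decile / 2nd–9th / 10th); whole-population rather than within-stratum
boundaries are used so the "low/medium/high" labels mean the same thing in
both directions of the symmetric analysis.

## Gene–environment amplification

`stratified_prevalence()` tabulates prevalence per (genetic stratum ×
exposure level), with empty cells reported as missing (`NA` with `n = 0`),
never as zero prevalence. The amplification fold

$$\frac{p_{\text{high,exposed}} - p_{\text{high,unexposed}}}
       {p_{\text{low,exposed}} - p_{\text{low,unexposed}}}$$

is the absolute-difference analogue of the per-allele statistic: odds-scale
exposure effects produce folds tracking the strata's prevalence ratio,
additive effects produce 1. A non-positive reference difference makes the
fold undefined and raises an error rather than returning a misleading
number. Linear trends within exposure level and a quadratic fit to the
difference curve use ordinary least squares on prevalence as a *fraction*;
percent is a display scale only, applied at the very end, because mixing
the two silently rescales regression coefficients a hundred-fold.
Dichotomisation of raw covariates (BMI ≥ 30 kg/m², < 7.5 MET-h,
cholesterol > 6.18 mmol/L, age ≥ 55) lives in a separate small
preprocessor, `derive_exposures()`; the analysis core only ever sees 0/1
columns.

## The simulator

`sim_config()` defaults describe the cohort the analyses are designed for:

| parameter | default | why |
|---|---|---|
| `n_loci` | 198 | a current CAD genome-wide-significant panel size |
| `raf_law` | Uniform(0.1, 0.9) | common variants; mean count $2\sum\mathrm{RAF}_j \approx 198$ with sd ≈ 9 |
| `or_law` | log-OR ~ N(ln 1.05, 0.03), truncated ≥ 0 | small per-allele effects, all risk-increasing after orientation |
| `target_prevalence` | 0.0475 | CAD-like lifetime prevalence |
| `exposures` | smoking 45% / OR 1.8, obesity 24% / OR 1.5, diabetes 5% / OR 2.0 | fractions are UKB-plausible; odds ratios are epidemiologically typical CAD associations |
| `model` | multiplicative | the architecture under study; `additive` is the contrast null |
| `missing_rate` | 0 | masking is an observation process, added only when imputation is under test |

Genotypes are independent Binomial(2, RAF) draws — Hardy–Weinberg, no
linkage disequilibrium, because the target panels are pruned lead SNPs and
LD is out of analytic scope. Exposures are independent of genotype.
Randomness is split into named streams (panel, dosage, missingness,
exposure, phenotype) derived from one master seed, so e.g. enlarging the
panel does not perturb the phenotype draws, and identical configurations
reproduce cohorts exactly.

Under the multiplicative model, case probability is
$\operatorname{logit}^{-1}(\alpha + \sum_j \beta_j x_{ij} + \sum_k \gamma_k e_{ik})$
with $\alpha$ found by bisection on $[-30, 30]$ so the cohort mean equals
the target prevalence (tolerance $10^{-6}$; with all effects zero this is
exactly $\operatorname{logit}(p)$). The additive null is parameterised
with **zero intercept**: $P_i = \sum_j \delta_j x_{ij} + \sum_k \delta_k e_{ik}$,
$\delta_j \propto \beta_j$ scaled so the mean matches the same target, and
exposure increments $\delta_k = u(\mathrm{OR}_k - 1)$ with
$u = p /(1 + \sum_k f_k(\mathrm{OR}_k - 1))$. Zero intercept makes
per-allele prevalence exactly flat and exposure amplification exactly 1 in
expectation — the cleanest possible null — while matching the
multiplicative model's prevalence at the centre of the count distribution.
Probabilities are clamped to $[0,1]$ and the simulator warns if more than
1% of individuals clamp (a sign the additive parameters are mis-specified).

### What the simulator does and does not emulate

It reproduces the statistical structure the analyses assume: a near-normal
count distribution, calibrated prevalence, small multiplicative (or
additive) per-allele effects, genotype-independent exposures. It does
**not** emulate linkage disequilibrium, ascertainment or selection,
age-dependent incidence, relatedness, genotyping or imputation error
structure, or gene–environment correlation (a correlation knob exists but
defaults to zero). Tests passing on simulated cohorts therefore validate
the *pipeline's arithmetic and the models' discriminability*, not the
biology of any particular real cohort.

## Problem sizes and precision

The package's own verification runs choose Monte-Carlo sizes by precision
analysis, not convenience:

* Link-comparison checks simulate 200,000 individuals: a per-group
  prevalence then carries a relative SE of a few percent and the test
  suite's fitted-R checks (R ≥ 0.94; non-linear links within ΔR < 0.02 of
  each other) are resolved with margin.
* The gene–environment amplification check uses 500,000 individuals. The
  additive-null fold is unbiased at 1.0, but its Monte-Carlo sd is
  approximately $\sqrt{2}$ times the relative SE of a per-decile prevalence
  difference — about 0.13 at n = 200,000 for a 50% exposure of OR 2 at
  4.75% prevalence, too wide for a [0.8, 1.25] acceptance band. At
  n = 500,000 the sd is ≈ 0.085 and three sigmas fit inside the band.
* Parameter recovery fits 198 per-locus logistic regressions at
  n = 100,000, where the attenuation of marginal relative to conditional
  log-odds (logistic non-collapsibility over a background liability
  variance of ~0.3) is an order of magnitude below the per-locus standard
  error, so "within 3 SE" is the right yardstick.

## Known limitations

* The liability architecture is exchangeable-multiplicative by
  construction; real effect-size heterogeneity (a few large loci plus a
  polygenic tail) is only partly captured by the log-normal OR law.
* Covariate-adjusted GLMs (age/sex in the linear predictor) and formal
  non-nested model-selection tests are out of scope; the R comparison is a
  descriptive goodness-of-fit contrast, not a hypothesis test between
  links.
* Strand-ambiguous (A/T, C/G) variants are flagged on reading but never
  frequency-flipped; resolving them requires strand information the
  summary-statistics format does not carry.
* The 6.6-million-variant genome-wide score is supported only as an
  externally supplied weight file through the same scoring path; LD-aware
  weight construction is explicitly not implemented.
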