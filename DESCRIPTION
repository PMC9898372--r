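Package: riskburden
Title: Cumulative Risk-Allele Burden and Disease Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how common risk alleles combine with each
    other and with modifiable exposures to determine disease prevalence.
    Computes unweighted allele-count and log-odds-weighted genetic risk
    scores from GWAS summary statistics and genotype dosages, stratifies
    cohorts into score quantiles, derives prevalence and per-allele
    prevalence tables with fold changes, compares binomial regression
    models under identity, logit, probit and log link functions by the
    correlation between observed and predicted group prevalence, assesses
    exchangeability of risk-allele panels by subset resampling and
    odds-ratio matching, and quantifies amplification of exposure effects
    across genetic strata. A synthetic-cohort simulator generates panels,
    dosages and phenotypes under multiplicative-odds or additive-risk
    disease models so every analysis runs without access-controlled
    biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
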