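# Shared simulated cohorts, memoized so expensive simulations run once per
# test session.  Each entry returns list(panel, dosage, phenotypes, truth,
# config) plus precomputed count scores and decile labels.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(name, config) {
  if (!exists(name, envir = .cohort_cache)) {
    cohort <- simulate_cohort(config)
    cohort$counts <- count_score(impute_missing(cohort$dosage, cohort$panel))
    cohort$deciles <- assign_quantile_strata(cohort$counts, 10,
                                             seed = config$seed)
    assign(name, cohort, envir = .cohort_cache)
  }
  get(name, envir = .cohort_cache)
}

# Multiplicative cohort at the default study conditions, no exposures.
mult_cohort <- function(n = 200000) {
  cached_cohort(
    paste0("mult", n),
    sim_config(n_individuals = n, exposures = NULL,
               model = "multiplicative", seed = 101)
  )
}

# Additive-null cohort under otherwise identical conditions.
add_cohort <- function(n = 200000) {
  cached_cohort(
    paste0("add", n),
    sim_config(n_individuals = n, exposures = NULL,
               model = "additive", seed = 101)
  )
}

# Cohorts with a single 50% exposure of odds ratio 2, both disease models.
# Sized so the Monte-Carlo standard error of the decile-level amplification
# fold (~ sqrt(2) x the relative SE of a per-decile prevalence difference)
# is well under the width of the bands being tested.
gxe_cohort <- function(model) {
  cached_cohort(
    paste0("gxe_", model),
    sim_config(
      n_individuals = 500000,
      exposures = tibble::tibble(name = "exposure", fraction = 0.5,
                                 odds_ratio = 2),
      model = model, seed = 202
    )
  )
}

# A tiny deterministic panel for IO and scoring tests.
toy_panel <- function() {
  tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4"),
    chrom = c("1", "1", "2", "2"),
    pos = c(100L, 200L, 300L, 400L),
    effect_allele = c("G", "T", "A", "C"),
    other_allele = c("A", "C", "G", "A"),
    raf = c(0.3, 0.6, 0.25, 0.75),
    odds_ratio = c(1.2, 1.1, 1.05, 1.23),
    trait = "toy",
    tags = c("lipid", "", "", "lipid")
  )
}

write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", "v1", "A", "G", ".", ".", ".", "GT",
          "0/1", "1/1", "./.", sep = "\t"),
    paste("1", "200", "v2", "T", "C", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t")
  ), path)
  path
}

# Matrix holding the same risk-allele dosages as write_toy_vcf() under the
# two-variant head of toy_panel() (v1 risk = ALT G; v2 risk = REF T).
write_toy_matrix <- function(path) {
  writeLines(c(
    "individual_id\tv1\tv2",
    "S1\t1\t2",
    "S2\t2\t1",
    "S3\tNA\t0"
  ), path)
  path
}
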