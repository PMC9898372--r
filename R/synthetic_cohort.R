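#' Configure a synthetic cohort simulation
#'
#' Builds a validated configuration for [simulate_cohort()].  The defaults
#' emulate a large CAD-like biobank cohort: 198 independent biallelic
#' autosomal loci with risk-allele frequencies uniform on \[0.1, 0.9\] and
#' per-allele log odds ratios drawn from Normal(ln 1.05, 0.03) truncated at
#' zero, an overall prevalence calibrated to 4.75%, and three binary
#' exposures (smoking, obesity, diabetes) acting multiplicatively on the
#' odds scale.
#'
#' @param n_individuals Cohort size.
#' @param n_loci Number of independent biallelic loci.
#' @param raf_law List `list(dist = "uniform", min, max)` or
#'   `list(dist = "fixed", value)` for the risk-allele frequency.
#' @param or_law List `list(dist = "lognormal", meanlog, sdlog)` (log-OR
#'   normal, truncated at 0 so every allele is risk-increasing) or
#'   `list(dist = "fixed", value)` for the per-allele odds ratio.
#' @param target_prevalence Population prevalence the intercept is calibrated
#'   to, in (0, 1).
#' @param exposures Data frame with columns `name`, `fraction` (population
#'   frequency) and `odds_ratio`, or `NULL` for a purely genetic model.
#' @param model `"multiplicative"` (logistic; odds multiply) or `"additive"`
#'   (absolute risks add; the contrast null).
#' @param missing_rate Fraction of dosages masked as missing.
#' @param seed Master seed; named sub-streams (panel, dosage, missing,
#'   exposure, phenotype) are derived from it so stages stay independent.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 100000,
                       n_loci = 198,
                       raf_law = list(dist = "uniform", min = 0.1, max = 0.9),
                       or_law = list(dist = "lognormal",
                                     meanlog = log(1.05), sdlog = 0.03),
                       target_prevalence = 0.0475,
                       exposures = default_exposures(),
                       model = c("multiplicative", "additive"),
                       missing_rate = 0,
                       seed = 1) {
  model <- match.arg(model)
  stopifnot(
    n_individuals >= 1, n_loci >= 1,
    target_prevalence > 0, target_prevalence < 1,
    missing_rate >= 0, missing_rate < 1
  )
  if (!is.null(exposures)) {
    exposures <- tibble::as_tibble(exposures)
    stopifnot(
      all(c("name", "fraction", "odds_ratio") %in% names(exposures)),
      all(exposures$fraction > 0 & exposures$fraction < 1),
      all(exposures$odds_ratio > 0)
    )
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_loci = as.integer(n_loci),
    raf_law = raf_law, or_law = or_law,
    target_prevalence = target_prevalence,
    exposures = exposures, model = model,
    missing_rate = missing_rate, seed = seed
  ), class = "sim_config")
}

#' Default exposure specification for the simulator
#'
#' Smoking, obesity and diabetes with UKB-plausible population fractions and
#' epidemiologically typical CAD odds ratios.
#'
#' @return A tibble with columns `name`, `fraction`, `odds_ratio`.
#' @export
default_exposures <- function() {
  tibble::tibble(
    name = c("smoking", "obesity", "diabetes"),
    fraction = c(0.45, 0.24, 0.05),
    odds_ratio = c(1.8, 1.5, 2.0)
  )
}

draw_law <- function(law, n) {
  switch(law$dist,
    fixed = rep(law$value, n),
    uniform = runif(n, law$min, law$max),
    lognormal = {
      b <- rnorm(n, law$meanlog, law$sdlog)
      pmax(b, 0) # truncate: every allele risk-increasing
    },
    abort(sprintf("unknown distribution %s", sQuote(law$dist)))
  )
}

#' Simulate a risk-variant panel and dosage matrix
#'
#' Draws per-locus risk-allele frequencies and odds ratios from the
#' configured laws, then genotypes each individual independently at each
#' locus as Binomial(2, raf) — Hardy–Weinberg proportions with no linkage
#' disequilibrium, matching panels of pruned genome-wide-significant lead
#' variants.  A `missing_rate` fraction of entries is masked as `NA`.
#'
#' @param config A [sim_config()].
#' @return A list with `panel` (risk-oriented variant tibble) and `dosage`
#'   (individuals-by-loci matrix in \{0, 1, 2, NA\}).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$n_loci
  N <- config$n_individuals
  pan <- with_stream(config$seed, "panel", {
    raf <- draw_law(config$raf_law, L)
    or <- exp(draw_law(
      if (config$or_law$dist == "fixed") {
        list(dist = "fixed", value = log(config$or_law$value))
      } else {
        config$or_law
      }, L
    ))
    list(raf = raf, or = or)
  })
  panel <- tibble::tibble(
    variant_id = sprintf("sim%04d", seq_len(L)),
    chrom = as.character(rep_len(1:22, L)),
    pos = seq_len(L) * 1000L,
    effect_allele = "A",
    other_allele = "G",
    raf = pan$raf,
    odds_ratio = pan$or,
    trait = "simulated",
    tags = ""
  )
  dosage <- with_stream(config$seed, "dosage", {
    matrix(
      rbinom(N * L, size = 2L, prob = rep(pan$raf, each = N)),
      nrow = N, ncol = L
    )
  })
  if (config$missing_rate > 0) {
    dosage <- with_stream(config$seed, "missing", {
      mask <- runif(length(dosage)) < config$missing_rate
      dosage[mask] <- NA_integer_
      dosage
    })
  }
  dimnames(dosage) <- list(sprintf("ind%06d", seq_len(N)), panel$variant_id)
  list(panel = panel, dosage = dosage)
}

simulate_exposures <- function(config) {
  if (is.null(config$exposures) || nrow(config$exposures) == 0) {
    return(NULL)
  }
  N <- config$n_individuals
  with_stream(config$seed, "exposure", {
    out <- lapply(seq_len(nrow(config$exposures)), function(k) {
      rbinom(N, 1L, config$exposures$fraction[k])
    })
    names(out) <- config$exposures$name
    tibble::as_tibble(out)
  })
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' Finds by bisection the intercept `alpha` such that the mean of
#' `plogis(alpha + linear_predictor)` over the cohort equals the target
#' prevalence.  With all effects zero this reduces to `qlogis(target)`.
#'
#' @param linear_predictor Numeric vector: each individual's genetic plus
#'   exposure contribution on the log-odds scale (excluding the intercept).
#' @param target Target prevalence in (0, 1).
#' @param tol Convergence tolerance on the achieved prevalence.
#' @param bounds Search bracket for the intercept.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(linear_predictor, target,
                                tol = 1e-6, bounds = c(-30, 30)) {
  stopifnot(target > 0, target < 1)
  f <- function(a) mean(plogis(a + linear_predictor)) - target
  lo <- bounds[1]; hi <- bounds[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) {
    abort(sprintf(
      "intercept bracket [%g, %g] does not contain the target: achieved prevalence range [%g, %g]",
      lo, hi, flo + target, fhi + target
    ), class = "riskburden_numerical_error")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) < 1e-12) {
      return(mid)
    }
    if (fm > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Additive-null parameterization: zero intercept so per-allele prevalence is
# flat by construction; per-locus absolute increments proportional to the
# multiplicative log-ORs and exposure increments u*(OR-1), jointly scaled so
# the cohort mean equals the target prevalence.
additive_parameters <- function(panel, config) {
  beta <- log(panel$odds_ratio)
  if (!is.null(config$exposures) && nrow(config$exposures) > 0) {
    f <- config$exposures$fraction
    or <- config$exposures$odds_ratio
    u <- config$target_prevalence / (1 + sum(f * (or - 1)))
    delta_exposure <- u * (or - 1)
  } else {
    u <- config$target_prevalence
    delta_exposure <- numeric(0)
  }
  expected_count <- sum(beta * 2 * panel$raf)
  delta_locus <- beta * u / expected_count
  list(delta_locus = delta_locus, delta_exposure = delta_exposure)
}

#' Simulate case status for a generated panel
#'
#' Under the multiplicative model each individual's disease probability is
#' `plogis(alpha + sum(beta_j x_ij) + sum(gamma_k e_ik))`: every risk allele
#' and exposure multiplies the odds, so absolute effects grow with total
#' burden.  Under the additive null the probability is a zero-intercept sum
#' of fixed absolute increments (clamped to \[0, 1\]), so each allele adds
#' the same absolute risk regardless of background — the contrast that
#' isolates curvature downstream.
#'
#' @param panel Risk-oriented variant tibble (from [simulate_panel()]).
#' @param dosage Dosage matrix aligned to `panel`.
#' @param config The [sim_config()] used to generate the panel.
#' @param exposures Optional tibble of 0/1 exposure columns (one row per
#'   individual); generated internally by [simulate_cohort()].
#'
#' @return A list with `phenotypes` (tibble: `individual_id`, trait status
#'   column `case`, exposure columns) and `truth` (per-locus log-ORs or
#'   additive increments, exposure effects, intercept, realized prevalence).
#' @export
simulate_phenotypes <- function(panel, dosage, config, exposures = NULL) {
  stopifnot(inherits(config, "sim_config"))
  X <- dosage
  if (anyNA(X)) {
    # expectation-imputed burden drives the latent risk; masking is an
    # observation process, not a biological one
    X <- impute_missing(X, panel)
  }
  beta <- log(panel$odds_ratio)
  gamma <- if (!is.null(config$exposures)) log(config$exposures$odds_ratio) else numeric(0)
  E <- if (is.null(exposures)) NULL else as.matrix(exposures)

  if (config$model == "multiplicative") {
    lp <- drop(X %*% beta)
    if (!is.null(E) && length(gamma)) lp <- lp + drop(E %*% gamma)
    alpha <- calibrate_intercept(lp, config$target_prevalence)
    p <- plogis(alpha + lp)
    truth_effects <- beta
    truth_exposure <- gamma
  } else {
    par <- additive_parameters(panel, config)
    p <- drop(X %*% par$delta_locus)
    if (!is.null(E) && length(par$delta_exposure)) {
      p <- p + drop(E %*% par$delta_exposure)
    }
    clamped <- p < 0 | p > 1
    if (mean(clamped) > 0.01) {
      warn(sprintf(
        "additive model clamped %.1f%% of probabilities: parameters mis-specified",
        100 * mean(clamped)
      ))
    }
    p <- pmin(pmax(p, 0), 1)
    alpha <- 0
    truth_effects <- par$delta_locus
    truth_exposure <- par$delta_exposure
  }

  status <- with_stream(config$seed, "phenotype", {
    rbinom(length(p), 1L, p)
  })
  phenotypes <- tibble::tibble(
    individual_id = rownames(dosage) %||% sprintf("ind%06d", seq_along(p)),
    case = status
  )
  if (!is.null(exposures)) phenotypes <- dplyr::bind_cols(phenotypes, exposures)
  truth <- list(
    model = config$model,
    locus_effects = truth_effects,
    exposure_effects = truth_exposure,
    intercept = alpha,
    realized_prevalence = mean(status)
  )
  list(phenotypes = phenotypes, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' One-call wrapper: panel + dosages ([simulate_panel()]), exposures, and
#' case status ([simulate_phenotypes()]) under a fixed master seed.
#' Identical configurations produce identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A list with `panel`, `dosage`, `phenotypes`, `truth`, `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 500, n_loci = 20))
#' mean(cohort$phenotypes$case)
simulate_cohort <- function(config = sim_config()) {
  pd <- simulate_panel(config)
  exposures <- simulate_exposures(config)
  ph <- simulate_phenotypes(pd$panel, pd$dosage, config, exposures)
  list(
    panel = pd$panel, dosage = pd$dosage,
    phenotypes = ph$phenotypes, truth = ph$truth, config = config
  )
}
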