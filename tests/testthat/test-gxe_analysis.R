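toy_gxe_table <- function() {
  # three strata, hand-countable cells
  labels <- rep(c(1, 2, 3), each = 8)
  exposure <- rep(c(0, 0, 0, 0, 1, 1, 1, 1), 3)
  status <- c(
    0, 0, 0, 1, 0, 0, 1, 1, # stratum 1: unexp 1/4, exp 2/4
    0, 0, 1, 1, 0, 1, 1, 1, # stratum 2: unexp 2/4, exp 3/4
    0, 1, 1, 1, 1, 1, 1, 1  # stratum 3: unexp 3/4, exp 4/4
  )
  list(labels = labels, status = status, exposure = exposure)
}

test_that("stratified prevalence cells match hand counts", {
  d <- toy_gxe_table()
  tab <- stratified_prevalence(d$labels, d$status, d$exposure)
  expect_equal(tab$prev_unexposed, c(1, 2, 3) / 4)
  expect_equal(tab$prev_exposed, c(2, 3, 4) / 4)
  expect_equal(tab$difference, rep(0.25, 3))
  expect_equal(tab$n_unexposed + tab$n_exposed, rep(8L, 3))
  # empty exposed cells are missing, never zero prevalence
  tab2 <- stratified_prevalence(d$labels, d$status, rep(0L, 24))
  expect_true(all(is.na(tab2$prev_exposed)))
  expect_true(all(tab2$n_exposed == 0))
})

test_that("cell prevalences marginalize back to the stratum prevalence", {
  cohort <- gxe_cohort("multiplicative")
  e <- cohort$phenotypes$exposure
  tab <- stratified_prevalence(cohort$deciles, cohort$phenotypes$case, e)
  overall <- stratum_summary(cohort$deciles, cohort$phenotypes$case,
                             cohort$counts)
  mix <- (tab$n_unexposed * tab$prev_unexposed +
            tab$n_exposed * tab$prev_exposed) /
    (tab$n_unexposed + tab$n_exposed)
  expect_equal(mix, overall$prevalence, tolerance = 1e-12)
  # exposure raises prevalence in every decile
  expect_true(all(tab$difference > 0))
})

test_that("amplification folds divide high-stratum by low-stratum differences", {
  d <- toy_gxe_table()
  tab <- stratified_prevalence(d$labels, d$status, d$exposure)
  expect_equal(amplification_summary(tab, low = 1, high = 3), 1.0)
  # differences (1%, 2.7%) give fold 2.7
  tab2 <- tibble::tibble(
    stratum = c(1, 10),
    n_unexposed = c(1000, 1000), cases_unexposed = c(20, 50),
    prev_unexposed = c(0.020, 0.050),
    n_exposed = c(1000, 1000), cases_exposed = c(30, 77),
    prev_exposed = c(0.030, 0.077),
    difference = c(0.010, 0.027)
  )
  expect_equal(amplification_summary(tab2, 1, 10), 2.7, tolerance = 1e-12)
  # non-positive reference difference is undefined, reported not dropped
  tab3 <- tab2
  tab3$difference[1] <- 0
  expect_error(amplification_summary(tab3, 1, 10), "undefined",
               class = "riskburden_validation_error")
})

test_that("swapping exposure coding negates differences, preserving folds", {
  cohort <- gxe_cohort("multiplicative")
  e <- cohort$phenotypes$exposure
  tab <- stratified_prevalence(cohort$deciles, cohort$phenotypes$case, e)
  swapped <- stratified_prevalence(cohort$deciles, cohort$phenotypes$case,
                                   1L - e)
  expect_equal(swapped$difference, -tab$difference, tolerance = 1e-12)
  expect_equal(swapped$difference[10] / swapped$difference[1],
               tab$difference[10] / tab$difference[1], tolerance = 1e-12)
})

test_that("trends within exposure strata equal closed-form least squares", {
  tab <- tibble::tibble(
    stratum = 1:5,
    n_unexposed = 100, cases_unexposed = c(2, 3, 4, 5, 6),
    prev_unexposed = c(2, 3, 4, 5, 6) / 100,
    n_exposed = 100, cases_exposed = c(3, 5, 8, 11, 15),
    prev_exposed = c(3, 5, 8, 11, 15) / 100,
    difference = c(1, 2, 4, 6, 9) / 100
  )
  tr_un <- suppressWarnings(per_stratum_trend(tab, "unexposed"))
  expect_equal(unname(tr_un$coefficients["slope"]), 0.01, tolerance = 1e-12)
  expect_equal(tr_un$r, 1, tolerance = 1e-9)
  tr_ex <- per_stratum_trend(tab, "exposed")
  x <- 1:5; y <- tab$prev_exposed
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(unname(tr_ex$coefficients["slope"]), slope_hand,
               tolerance = 1e-12)
  expect_gt(tr_ex$coefficients["slope"] / tr_un$coefficients["slope"], 1)
})

test_that("quadratic difference fits solve the normal equations", {
  tab <- tibble::tibble(
    stratum = 1:5,
    n_unexposed = 1, cases_unexposed = 0, prev_unexposed = 0,
    n_exposed = 1, cases_exposed = 0, prev_exposed = 0,
    difference = c(0.011, 0.018, 0.031, 0.052, 0.080)
  )
  fit <- difference_curve_fit(tab, "quadratic")
  # independent oracle: solve X'X b = X'y directly
  X <- cbind(1, 1:5, (1:5)^2)
  b_hand <- drop(solve(t(X) %*% X, t(X) %*% tab$difference))
  expect_equal(unname(fit$coefficients), b_hand, tolerance = 1e-10)
  # exactly quadratic differences: r = 1
  tab$difference <- 0.002 + 0.001 * (1:5) + 0.0005 * (1:5)^2
  expect_equal(difference_curve_fit(tab, "quadratic")$r, 1, tolerance = 1e-9)
  # constant differences: curvature coefficient zero, r undefined
  tab$difference <- rep(0.02, 5)
  flat <- difference_curve_fit(tab, "quadratic")
  expect_equal(unname(flat$coefficients[3]), 0, tolerance = 1e-12)
  expect_true(is.na(flat$r))
  expect_error(difference_curve_fit(tab[1:3, ], "quadratic"),
               class = "riskburden_validation_error")
})

test_that("raw covariates dichotomize at the documented cutpoints", {
  raw <- tibble::tibble(
    bmi = c(29.9, 30, 35),
    met_hours = c(7.4, 7.5, 10),
    cholesterol = c(6.18, 6.19, 5.0),
    age = c(54, 55, 70)
  )
  d <- derive_exposures(raw)
  expect_equal(d$obesity, c(0L, 1L, 1L))
  expect_equal(d$sedentary, c(1L, 0L, 0L))
  expect_equal(d$high_cholesterol, c(0L, 1L, 0L))
  expect_equal(d$age55, c(0L, 1L, 1L))
})
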