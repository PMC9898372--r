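tiny_groups <- function() {
  # 3 allele-count groups, 60 individuals total
  list(c_g = c(5, 10, 15), y = c(2, 5, 9), n = c(20, 20, 20))
}

test_that("count groups filter strictly on size and keep ordering", {
  counts <- c(rep(190, 1000), rep(210, 150))
  status <- rep(0:1, length.out = 1150)
  curve <- group_by_count(counts, status, min_group_size = 200)
  expect_equal(nrow(curve), 1)
  expect_equal(curve$allele_count, 190)
  expect_equal(nrow(attr(curve, "dropped")), 1)
  # threshold zero keeps every distinct count
  all_groups <- group_by_count(counts, status, min_group_size = 0)
  expect_equal(all_groups$allele_count, c(190, 210))
  expect_equal(all_groups$per_allele,
               all_groups$observed_prevalence / all_groups$allele_count)
  # raising the threshold never increases retained groups
  sizes <- vapply(c(0, 50, 149, 200), function(m) {
    nrow(group_by_count(counts, status, min_group_size = m))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(group_by_count(counts, status, min_group_size = 2000),
               class = "riskburden_validation_error")
})

test_that("retained groups span the bulk of the count distribution", {
  cohort <- mult_cohort()
  curve <- group_by_count(cohort$counts, cohort$phenotypes$case, 200)
  m <- mean(cohort$counts); s <- sd(cohort$counts)
  expect_lt(min(curve$allele_count), m - 2 * s)
  expect_gt(max(curve$allele_count), m + 2 * s)
  expect_true(all(curve$allele_count > m - 3.5 * s &
                    curve$allele_count < m + 3.5 * s))
})

test_that("the logit fit recovers a curve generated exactly from itself", {
  c_g <- seq(150, 230, by = 5)
  n <- rep(1000, length(c_g))
  p <- plogis(-13 + 0.05 * c_g)
  fit <- fit_link(c_g, n * p, link = "logit", n = n)
  expect_true(fit$converged)
  expect_equal(fit$intercept, -13, tolerance = 1e-6)
  expect_equal(fit$slope, 0.05, tolerance = 1e-6)
})

test_that("status independent of counts gives near-zero slopes in every link", {
  set.seed(12)
  counts <- rbinom(20000, 396, 0.5)
  status <- rbinom(20000, 1, 0.05)
  for (lk in c("linear", "logit", "probit", "log")) {
    fit <- fit_link(counts, status, link = lk)
    expect_true(fit$converged)
    expect_lt(abs(fit$slope * sd(counts)), 0.05)
  }
})

test_that("IRLS estimates agree with a direct likelihood optimizer", {
  g <- tiny_groups()
  for (lk in c("linear", "logit", "probit", "log")) {
    fit <- fit_link(g$c_g, g$y, link = lk, n = g$n)
    orc <- oracle_ml(g$c_g, g$y, g$n, lk)
    expect_equal(fit$intercept, orc$par[1], tolerance = 1e-4)
    expect_equal(fit$slope, orc$par[2], tolerance = 1e-4)
  }
})

test_that("no point of a dense parameter grid beats the IRLS optimum", {
  g <- tiny_groups()
  for (lk in c("logit", "log")) {
    fit <- fit_link(g$c_g, g$y, link = lk, n = g$n)
    orc <- oracle_ml(g$c_g, g$y, g$n, lk)
    grid_a <- fit$intercept + seq(-1, 1, length.out = 201)
    grid_b <- fit$slope + seq(-0.2, 0.2, length.out = 201)
    grid_best <- min(outer(grid_a, grid_b, Vectorize(
      function(a, b) orc$nll(c(a, b))
    )))
    expect_lte(orc$nll(c(fit$intercept, fit$slope)), grid_best + 1e-8)
  }
})

test_that("IRLS matches stats::glm where glm supports the link", {
  set.seed(30)
  c_g <- seq(160, 220, by = 4)
  n <- rpois(length(c_g), 400) + 50
  y <- rbinom(length(c_g), n, plogis(-12 + 0.045 * c_g))
  for (lk in c("logit", "probit")) {
    fit <- fit_link(c_g, y, link = lk, n = n)
    ref <- glm(cbind(y, n - y) ~ c_g, family = binomial(link = lk))
    expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
    expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-6)
  }
})

test_that("goodness of fit is the Pearson correlation with a Fisher-z CI", {
  curve <- tibble::tibble(
    allele_count = c(170, 180, 190, 200, 210),
    n = rep(1000, 5), n_cases = c(20, 28, 41, 60, 88),
    observed_prevalence = c(0.020, 0.028, 0.041, 0.060, 0.088)
  )
  fake_fit <- structure(list(
    link = "logit", intercept = -12.5, slope = 0.047,
    predict = function(x) plogis(-12.5 + 0.047 * x)
  ), class = "link_fit")
  gof <- goodness_of_fit(curve, fake_fit)
  # textbook Pearson formula, computed independently
  x <- curve$observed_prevalence
  y <- fake_fit$predict(curve$allele_count)
  r_hand <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    sqrt((sum(x^2) - length(x) * mean(x)^2) * (sum(y^2) - length(y) * mean(y)^2))
  expect_equal(gof$r, r_hand, tolerance = 1e-12)
  z <- atanh(r_hand); se <- 1 / sqrt(5 - 3)
  expect_equal(gof$ci, tanh(c(z - qnorm(0.975) * se, z + qnorm(0.975) * se)),
               tolerance = 1e-12)
  # predictions identical to observations: r = 1
  ideal <- structure(list(predict = function(x) curve$observed_prevalence),
                     class = "link_fit")
  expect_equal(goodness_of_fit(curve, ideal)$r, 1)
  # constant predictions are degenerate, not r = 0
  flat <- structure(list(predict = function(x) rep(0.05, length(x))),
                    class = "link_fit")
  expect_error(goodness_of_fit(curve, flat),
               class = "riskburden_degenerate_error")
  expect_error(goodness_of_fit(curve[1:2, ], fake_fit),
               class = "riskburden_validation_error")
})

test_that("link comparison is deterministic on identical data", {
  cohort <- mult_cohort()
  idx <- seq_len(40000)
  a <- compare_links(cohort$counts[idx], cohort$phenotypes$case[idx],
                     min_group_size = 100)
  b <- compare_links(cohort$counts[idx], cohort$phenotypes$case[idx],
                     min_group_size = 100)
  expect_identical(a$link, b$link)
  expect_identical(a$r, b$r)
})

test_that("weighted scores group into fixed-width bins before filtering", {
  cohort <- mult_cohort()
  idx <- seq_len(50000)
  w <- weighted_score(cohort$dosage[idx, ], cohort$panel)
  curve <- group_by_bin(w, cohort$phenotypes$case[idx], width = 0.05,
                        min_group_size = 200)
  expect_true(all(curve$n > 200))
  # bin centres sit at odd multiples of half the width
  expect_equal(curve$allele_count / 0.05 - 0.5,
               round(curve$allele_count / 0.05 - 0.5), tolerance = 1e-9)
  expect_gt(nrow(curve), 5)
})
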