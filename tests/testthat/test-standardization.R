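test_that("average-registry transform has the lognormal closed form", {
  # sigma = 0: plug-in transform exactly
  f0 <- known_fit(log(0.01), matrix(0, 1, 1), 0, "log", age_degree = 0)
  expect_identical(average_registry_rate(f0, "F", 50), exp(log(0.01)))
  # log link, sigma 0.5: 0.01 * exp(0.125)
  f1 <- known_fit(log(0.01), matrix(0, 1, 1), 0.5, "log", age_degree = 0)
  expect_equal(average_registry_rate(f1, "F", 50), 0.01 * exp(0.125),
               tolerance = 1e-12)
  # strictly above the median-registry rate for sigma > 0
  expect_gt(average_registry_rate(f1, "F", 50), exp(log(0.01)))
})

test_that("logit-link averaging matches brute-force integration", {
  eta <- stats::qlogis(0.12)
  f <- known_fit(eta, matrix(0, 1, 1), 0.8, "logit", age_degree = 0)
  got <- average_registry_rate(f, "M", 40)
  u <- seq(-8 * 0.8, 8 * 0.8, length.out = 20001)
  du <- u[2] - u[1]
  ref <- sum(stats::plogis(eta + u) * stats::dnorm(u, 0, 0.8)) * du
  expect_lt(abs(got - ref), 1e-8)
  expect_gt(got, stats::plogis(eta - 4 * 0.8))
  expect_lt(got, stats::plogis(eta + 4 * 0.8))
})

test_that("no extrapolation beyond the fitted age range", {
  fit <- known_fit(c(-5, 0.5), diag(0, 2), 0, "log", age_degree = 1,
                   age_classes = 9:18)  # ages 42.5 and up
  expect_error(average_registry_rate(fit, "F", 20), "extrapolation")
})

test_that("standardization is a population-weighted average per 1,000", {
  pop <- uniform_pop(1000)
  f0 <- known_fit(log(0.005), matrix(0, 1, 1), 0, "log", age_degree = 0)
  expect_equal(standardize_per_1000(f0, pop), 5.0, tolerance = 1e-12)
  # point mass: per-1,000 equals that cell's rate x 1000
  d <- as.data.frame(pop)
  d$population <- ifelse(d$sex == "F" & d$age_class == "60-64", 777, 0)
  expect_equal(standardize_per_1000(f0, standard_population(d)), 5.0)
  # two-cell toy with rates 0.002 / 0.006 at weights 3:1 -> 3.0 per 1,000
  g <- age_grid()
  b <- ortho_basis(g$midpoint, 1)
  X <- cbind(1, morbrank:::eval_ortho(b, c(42.5, 62.5)))
  beta <- solve(X, log(c(0.002, 0.006)))
  f1 <- known_fit(beta, diag(0, 2), 0, "log", age_degree = 1)
  d2 <- as.data.frame(pop)
  d2$population <- 0
  d2$population[d2$sex == "F" & d2$age_class == "40-44"] <- 3
  d2$population[d2$sex == "F" & d2$age_class == "60-64"] <- 1
  expect_equal(standardize_per_1000(f1, standard_population(d2)), 3.0,
               tolerance = 1e-10)
})

test_that("excluded young age classes dilute the rate but stay in the denominator", {
  pop <- uniform_pop(1000)
  fit <- known_fit(log(0.01), matrix(0, 1, 1), 0, "log", age_degree = 0,
                   age_classes = 10:18)  # top half of the grid only
  expect_equal(standardize_per_1000(fit, pop), 10 * 9 / 18,
               tolerance = 1e-12)
})

test_that("standardization is invariant to rescaling the weights", {
  f1 <- known_fit(c(-5, 0.4), diag(0, 2), 0.3, "log", age_degree = 1)
  pop <- uniform_pop(1000)
  d <- as.data.frame(pop); d$population <- d$population * 7
  expect_equal(standardize_per_1000(f1, pop),
               standardize_per_1000(f1, standard_population(d)),
               tolerance = 1e-12)
})

test_that("zero uncertainty collapses the interval to the point", {
  f0 <- known_fit(log(0.005), matrix(0, 1, 1), 0, "log", age_degree = 0)
  est <- interval_per_1000(f0, uniform_pop(), TRUE, n_draws = 1000,
                           seed = 1)
  expect_equal(est$lower, est$point, tolerance = 1e-12)
  expect_equal(est$upper, est$point, tolerance = 1e-12)
})

test_that("Monte Carlo percentiles match lognormal quantiles", {
  v <- 0.04
  f <- known_fit(log(0.005), matrix(v, 1, 1), 0, "log", age_degree = 0)
  est <- interval_per_1000(f, uniform_pop(), FALSE, n_draws = 5000,
                           seed = 3)
  ref <- 5 * exp(stats::qnorm(c(0.025, 0.975)) * sqrt(v))
  expect_lt(abs(est$lower / ref[1] - 1), 0.02)
  expect_lt(abs(est$upper / ref[2] - 1), 0.02)
})

test_that("between-registry variance widens the interval", {
  preset <- scenario_library()$`arthritis-like`
  tabs <- simulate_scenario(preset, seed = 10)$arth_inc
  fit <- fit_glmm(tabs, model_formula(2, TRUE), "log", n_starts = 1)
  pop <- uniform_pop()
  a <- interval_per_1000(fit, pop, FALSE, n_draws = 2000, seed = 5)
  b <- interval_per_1000(fit, pop, TRUE, n_draws = 2000, seed = 5)
  expect_gt(b$upper - b$lower, a$upper - a$lower)
  # the total interval contains the point estimate
  expect_gte(a$point, b$lower)
  expect_lte(a$point, b$upper)
  est <- rate_estimate(fit, pop, n_draws = 2000, seed = 5)
  expect_equal(est$ci_fixed, c(a$lower, a$upper))
  expect_equal(est$ci_total, c(b$lower, b$upper))
})

test_that("a non-PSD coefficient covariance is refused", {
  bad <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3, -1
  f <- known_fit(c(-5, 0.1), bad, 0, "log", age_degree = 1)
  expect_error(interval_per_1000(f, uniform_pop(), FALSE, 1000, 1),
               "positive semi-definite")
})
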