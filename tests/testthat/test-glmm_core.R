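test_that("design matrix has the documented column structure", {
  ages <- age_grid()$midpoint
  sexes <- rep(c("F", "M"), each = 18)
  d <- build_design(rep(ages, 2), sexes, model_formula(4, TRUE, 0))
  expect_equal(ncol(d$X), 6)
  expect_equal(colnames(d$X),
               c("(Intercept)", paste0("age", 1:4), "sexM"))
  d0 <- build_design(rep(ages, 2), sexes, model_formula(0, FALSE))
  expect_equal(ncol(d0$X), 1)
  di <- build_design(rep(ages, 2), sexes, model_formula(3, TRUE, 2))
  expect_equal(ncol(di$X), 1 + 3 + 1 + 2)
  expect_equal(unname(di$X[20, "sexM:age1"]), unname(di$X[20, "age1"]))
})

test_that("orthogonal bases are orthonormal over the evaluation ages", {
  for (deg in c(1, 4, 8)) {
    b <- ortho_basis(age_grid()$midpoint, deg)
    gram <- crossprod(b$B)
    expect_lt(max(abs(gram - diag(deg + 1))), 1e-10)
    expect_equal(length(unique(round(b$B[, 1], 12))), 1)  # constant column
  }
  expect_error(ortho_basis(c(10, 20), 2), "distinct ages")
})

test_that("model formulas enforce their own invariants", {
  expect_error(model_formula(2, TRUE, 3), "must not exceed")
  expect_error(model_formula(2, FALSE, 1), "require the sex main effect")
  expect_equal(format(model_formula(2, TRUE, 1)),
               "f(age, age^2, sex, sex*age)")
})

test_that("the degenerate random effect reduces to the pooled GLM", {
  f <- model_formula(1, include_sex = TRUE)
  for (measure in c("incidence", "prevalence")) {
    tabs <- toy_tables(measure)
    dat <- morbrank:::prepare_glmm_data(tabs, f)
    link <- dat$link
    g <- if (link == "log") {
      stats::glm(dat$y ~ dat$X - 1 + offset(log(dat$expo)),
                 family = stats::poisson())
    } else {
      stats::glm(cbind(dat$y, dat$expo - dat$y) ~ dat$X - 1,
                 family = stats::binomial())
    }
    ll <- marginal_loglik(stats::coef(g), -20, tabs, f, link)
    expect_lt(abs(ll - as.numeric(stats::logLik(g))), 1e-6)
  }
})

test_that("AGHQ agrees with brute-force integration on a small instance", {
  f <- model_formula(1, include_sex = TRUE)
  beta <- c(-4.8, 0.25, 0.15)
  for (link in c("log", "logit")) {
    tabs <- toy_tables(if (link == "log") "incidence" else "prevalence")
    a <- marginal_loglik(beta, log(0.3), tabs, f, link, quad_points = 15)
    b <- trap_loglik(beta, 0.3, tabs, f, link)
    expect_lt(abs(a - b), 1e-8)
  }
})

test_that("the quadrature is converged at the default node count", {
  preset <- scenario_library()$`diabetes-like`
  tabs <- simulate_scenario(preset, seed = 2)$diab_inc
  f <- model_formula(2, include_sex = TRUE)
  dat <- morbrank:::prepare_glmm_data(tabs, f)
  g <- stats::glm(dat$y ~ dat$X - 1 + offset(log(dat$expo)),
                  family = stats::poisson())
  l15 <- marginal_loglik(stats::coef(g), log(0.1), tabs, f, "log", 15)
  l30 <- marginal_loglik(stats::coef(g), log(0.1), tabs, f, "log", 30)
  expect_lt(abs(l15 - l30), 1e-8)
})

test_that("fitting recovers known parameters and dominates the truth", {
  p <- scenario_library()$flat$diseases$flat_inc
  tabs <- simulate_registry_counts(p, 10, seed = 1, registry_sizes = 1e5,
                                   disease_id = "flat_inc")
  fit <- fit_glmm(tabs, model_formula(0, include_sex = FALSE), "log")
  expect_true(fit$sigma_u >= 0.1 && fit$sigma_u <= 0.6)
  se <- sqrt(fit$vcov_beta[1, 1])
  expect_lt(abs(fit$beta[1] - log(0.005)), 3 * se)
  # MLE dominance over the generating parameters on the same data
  ll_truth <- marginal_loglik(log(0.005), log(0.3), tabs,
                              model_formula(0, FALSE), "log")
  expect_gte(fit$loglik, ll_truth - 1e-8)
})

test_that("a zero variance component is recovered at the boundary", {
  p <- true_params("log", intercept = log(0.005), sigma_u = 0)
  tabs <- simulate_registry_counts(p, 20, seed = 4, registry_sizes = 2e5)
  fit <- fit_glmm(tabs, model_formula(0, include_sex = FALSE), "log")
  expect_lte(fit$sigma_u, 0.05)
  expect_equal(fit$sigma_effectively_zero, fit$sigma_u < 1e-4)
})

test_that("a single registry pins sigma_u to zero with a warning", {
  p <- true_params("log", intercept = log(0.005), sigma_u = 0)
  tabs <- simulate_registry_counts(p, 1, seed = 5)
  expect_warning(fit <- fit_glmm(tabs, model_formula(0, FALSE), "log"),
                 "pinned")
  expect_equal(fit$sigma_u, 0)
})

test_that("log-likelihood is monotone in nested fixed-effect structures", {
  tabs <- simulate_registry_counts(
    scenario_library()$`diabetes-like`$diseases$diab_inc, 5, seed = 6,
    registry_sizes = c(12000, 350000, 88000, 30000, 13000))
  lls <- vapply(0:3, function(d)
    fit_glmm(tabs, model_formula(d, include_sex = FALSE), "log",
             n_starts = 1)$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
  # BIC bookkeeping: -2 loglik + (p_beta + 1) log(n_cells)
  fit <- fit_glmm(tabs, model_formula(2, FALSE), "log", n_starts = 1)
  expect_equal(fit$bic, -2 * fit$loglik + 4 * log(fit$n_obs))
})

test_that("BIC ties break towards the simpler formula", {
  tab <- data.frame(age_degree = c(2, 1, 1), include_sex = c(TRUE, FALSE, TRUE),
                    sex_age_degree = c(0, 0, 0), n_params = c(5, 3, 4),
                    bic = c(100, 100 + 5e-10, 100.2))
  expect_equal(morbrank:::pick_best_bic(tab), 2)
  tab$bic[3] <- 100 - 1  # clear winner beats any tie rule
  expect_equal(morbrank:::pick_best_bic(tab), 3)
})

test_that("a singleton candidate space returns the intercept-only fit", {
  p <- true_params("log", intercept = log(0.005), sigma_u = 0.1)
  tabs <- simulate_registry_counts(p, 4, seed = 8, registry_sizes = 5e4)
  fit <- select_model(tabs, "log", max_age_degree = 0,
                      include_sex = FALSE, n_starts = 1)
  expect_equal(fit$formula$age_degree, 0)
  expect_false(fit$formula$include_sex)
  expect_equal(nrow(attr(fit, "bic_table")), 1)
})
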