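#' Average-registry rate on the natural scale
#'
#' The registry intercept is "fixed at its average value on the outcome
#' scale": the prediction is the expectation of the inverse-link transform
#' over the random-intercept distribution, E_u[g^-1(x'beta + u)] with
#' u ~ N(0, sigma_u^2). This differs from setting u = 0 whenever the link
#' is nonlinear: for the log link the closed form is
#' exp(x'beta + sigma_u^2 / 2) (the lognormal mean), strictly above the
#' median-registry rate exp(x'beta) when sigma_u > 0; for the logit link
#' the expectation is computed by Gauss-Hermite quadrature.
#'
#' @param fit A \code{\link{glmm_fit}}.
#' @param sex Sex codes "M"/"F" (vector).
#' @param age Ages in years (vector, same length). Must lie within the
#'   fitted age range; no extrapolation is allowed.
#' @return Rates (log link) or probabilities (logit link), one per cell.
#' @export
average_registry_rate <- function(fit, sex, age) {
  rng <- range(fit$basis$ages)
  if (any(age < rng[1] - 1e-9 | age > rng[2] + 1e-9)) {
    stop("age outside the fitted range [", rng[1], ", ", rng[2],
         "]: extrapolation not allowed", call. = FALSE)
  }
  X <- build_design(age, sex, fit$formula, fit$basis)$X
  eta <- drop(X %*% fit$beta)
  inverse_link_mean(eta, fit$sigma_u, fit$link, fit$quad_points)
}

# E_u[g^-1(eta + u)], u ~ N(0, sigma^2); eta may be vector or matrix
inverse_link_mean <- function(eta, sigma, link, quad_points = 15) {
  if (link == "log") {
    return(exp(eta + sigma^2 / 2))
  }
  if (sigma <= 0) return(stats::plogis(eta))
  gh <- pracma::gaussHermite(quad_points)
  out <- 0
  for (j in seq_along(gh$x)) {
    out <- out + gh$w[j] / sqrt(pi) *
      stats::plogis(eta + sqrt(2) * sigma * gh$x[j])
  }
  out
}

# population cells covered by the fit, with design matrix and weights.
# Cells below the disease's minimum analysis age get rate 0 but stay in
# the denominator, so "per 1,000" always means per 1,000 total population.
pop_design <- function(fit, pop) {
  modelled <- fit$grid$label[fit$age_classes]
  idx <- which(pop$age_class %in% modelled)
  if (!length(idx)) stop("population does not cover the fitted ages",
                         call. = FALSE)
  ages <- age_midpoints(pop$age_class[idx], fit$grid)
  X <- build_design(ages, pop$sex[idx], fit$formula, fit$basis)$X
  total <- sum(pop$population)
  if (total <= 0) stop("zero total population", call. = FALSE)
  list(X = X, w = pop$population[idx], total = total)
}

#' Directly standardized cases per 1,000
#'
#' Weights the average-registry cell rates by a standard population's
#' age/sex distribution: 1000 * sum_c pop_c * rate_c / sum_all pop. Age
#' classes outside the disease's analysis range contribute zero cases but
#' remain in the denominator, so diseases with different age restrictions
#' are comparable in one league table.
#'
#' @param fit A \code{\link{glmm_fit}}.
#' @param pop A \code{\link{standard_population}} on the full grid.
#' @return Standardized cases per 1,000 population (scalar).
#' @export
standardize_per_1000 <- function(fit, pop) {
  pd <- pop_design(fit, pop)
  eta <- drop(pd$X %*% fit$beta)
  rate <- inverse_link_mean(eta, fit$sigma_u, fit$link, fit$quad_points)
  1000 * sum(pd$w * rate) / pd$total
}

# lower-triangular factor A with A A' = V; errors on negative curvature
psd_factor <- function(V) {
  if (all(V == 0)) return(V)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  tol <- -1e-8 * max(abs(ev$values), 1e-300)
  if (any(ev$values < tol)) {
    stop("vcov_beta is not positive semi-definite", call. = FALSE)
  }
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow = length(ev$values))
}

# one vector of standardized per-1,000 replicates, consuming the current
# RNG stream: beta* ~ MVN(beta, vcov); include_random additionally adds a
# fresh registry shift u* ~ N(0, sigma_u^2) per replicate
sample_standardized <- function(fit, pop, n_draws, include_random) {
  pd <- pop_design(fit, pop)
  p <- length(fit$beta)
  A <- psd_factor(fit$vcov_beta)
  Z <- matrix(stats::rnorm(n_draws * p), p, n_draws)
  B <- fit$beta + A %*% Z                      # p x n_draws
  Eta <- pd$X %*% B                            # cells x n_draws
  if (include_random) {
    u <- stats::rnorm(n_draws, 0, fit$sigma_u)
    Eta <- sweep(Eta, 2, u, "+")
    Rate <- if (fit$link == "log") exp(Eta) else stats::plogis(Eta)
  } else {
    Rate <- inverse_link_mean(Eta, fit$sigma_u, fit$link, fit$quad_points)
  }
  vals <- 1000 * drop(crossprod(Rate, pd$w)) / pd$total
  if (any(!is.finite(vals))) {
    stop("non-finite replicate for ", fit$disease_id, " at draw ",
         which(!is.finite(vals))[1], call. = FALSE)
  }
  vals
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Monte Carlo uncertainty interval for the standardized rate
#'
#' Draws fixed-effect vectors from MVN(beta, vcov_beta) on the link scale;
#' with \code{include_random = TRUE} a fresh registry shift
#' u* ~ N(0, sigma_u^2) is added to each replicate's linear predictor, so
#' the interval additionally reflects between-registry heterogeneity. Each
#' replicate is standardized per 1,000; the interval is the empirical 2.5th
#' and 97.5th percentile. The point estimate is the plug-in
#' \code{\link{standardize_per_1000}}, not the mean of the draws.
#' Uncertainty in sigma_u itself is not propagated.
#'
#' @inheritParams standardize_per_1000
#' @param include_random Include between-registry variance in the draws?
#' @param n_draws Number of Monte Carlo replicates (>= 1000;
#'   default 5,000).
#' @param seed Integer seed for the draws.
#' @return List with \code{point}, \code{lower}, \code{upper},
#'   \code{include_random}, \code{n_draws}, \code{seed}.
#' @export
interval_per_1000 <- function(fit, pop, include_random, n_draws = 5000,
                              seed = 1) {
  if (n_draws < 1000) stop("n_draws must be at least 1,000", call. = FALSE)
  vals <- with_local_seed(seed,
    sample_standardized(fit, pop, n_draws, include_random))
  q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  list(point = standardize_per_1000(fit, pop), lower = q[1], upper = q[2],
       include_random = include_random, n_draws = n_draws, seed = seed)
}

#' Standardized rate with both interval types
#'
#' Convenience wrapper producing the point estimate plus the fixed-only
#' interval and the total interval (including between-registry variance)
#' from one seed.
#'
#' @inheritParams interval_per_1000
#' @return Object of class \code{rate_estimate} with \code{disease_id},
#'   \code{measure}, \code{point}, \code{ci_fixed}, \code{ci_total},
#'   \code{n_draws}, \code{seed}.
#' @export
rate_estimate <- function(fit, pop, n_draws = 5000, seed = 1) {
  fixed <- interval_per_1000(fit, pop, FALSE, n_draws, seed)
  total <- interval_per_1000(fit, pop, TRUE, n_draws, seed)
  structure(list(disease_id = fit$disease_id, measure = fit$measure,
                 point = fixed$point,
                 ci_fixed = c(fixed$lower, fixed$upper),
                 ci_total = c(total$lower, total$upper),
                 n_draws = n_draws, seed = seed),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %s %s: %.3f per 1,000\n  fixed-only 95%%: [%.3f, %.3f]\n  incl. registry variance: [%.3f, %.3f]  (%d draws, seed %d)\n",
    x$disease_id, x$measure, x$point, x$ci_fixed[1], x$ci_fixed[2],
    x$ci_total[1], x$ci_total[2], x$n_draws, x$seed))
  invisible(x)
}
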