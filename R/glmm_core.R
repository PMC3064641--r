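#' Fixed-effect structure of an age/sex model
#'
#' Describes which terms enter the linear predictor: orthogonal age
#' polynomials up to \code{age_degree}, an optional sex main effect, and
#' sex-by-age interaction polynomials up to \code{sex_age_degree}.
#'
#' @param age_degree Highest orthogonal age-polynomial order (>= 0).
#' @param include_sex Include a sex indicator (female = reference)?
#' @param sex_age_degree Highest age order interacting with sex (requires
#'   \code{include_sex}; must not exceed \code{age_degree}).
#' @return An object of class \code{model_formula}.
#' @export
model_formula <- function(age_degree, include_sex = TRUE,
                          sex_age_degree = 0) {
  stopifnot(age_degree >= 0, sex_age_degree >= 0)
  if (sex_age_degree > age_degree) {
    stop("sex_age_degree must not exceed age_degree", call. = FALSE)
  }
  if (sex_age_degree > 0 && !include_sex) {
    stop("sex interactions require the sex main effect", call. = FALSE)
  }
  structure(list(age_degree = as.integer(age_degree),
                 include_sex = isTRUE(include_sex),
                 sex_age_degree = as.integer(sex_age_degree)),
            class = "model_formula")
}

#' @export
format.model_formula <- function(x, ...) {
  terms <- character(0)
  if (x$age_degree >= 1) terms <- paste0("age", c("", paste0("^", 2:99))[seq_len(x$age_degree)])
  if (x$include_sex) terms <- c(terms, "sex")
  if (x$sex_age_degree >= 1) {
    terms <- c(terms, paste0("sex*age",
                             c("", paste0("^", 2:99))[seq_len(x$sex_age_degree)]))
  }
  if (!length(terms)) terms <- "1"
  paste0("f(", paste(terms, collapse = ", "), ")")
}

#' @export
print.model_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

n_fixed_params <- function(formula) {
  1L + formula$age_degree +
    (if (formula$include_sex) 1L + formula$sex_age_degree else 0L)
}

#' Orthogonal polynomial basis over age-class midpoints
#'
#' Builds polynomials of order 0..\code{degree} orthonormal over the
#' distinct evaluation ages (unweighted). Orthogonal age polynomials keep
#' the design well conditioned when high powers of age are needed. The
#' basis is computed per disease on its included age range, so two diseases
#' with different age restrictions have different bases.
#'
#' @param midpoints Age values (class midpoints); duplicates allowed.
#' @param degree Highest polynomial order.
#' @return Object of class \code{ortho_basis} with elements \code{ages}
#'   (sorted distinct evaluation ages), \code{degree}, \code{coefs}
#'   (recurrence coefficients for prediction at new ages) and \code{B}, the
#'   (length(ages)) x (degree + 1) orthonormal basis matrix whose first
#'   column is the constant \code{1/sqrt(m)}.
#' @export
ortho_basis <- function(midpoints, degree) {
  ages <- sort(unique(as.numeric(midpoints)))
  if (length(ages) < degree + 1) {
    stop("need at least degree + 1 distinct ages (have ", length(ages),
         ", degree ", degree, ")", call. = FALSE)
  }
  m <- length(ages)
  if (degree == 0) {
    B <- matrix(1 / sqrt(m), m, 1)
    coefs <- NULL
  } else {
    p <- stats::poly(ages, degree)
    coefs <- attr(p, "coefs")
    B <- cbind(1 / sqrt(m), unclass(p))
  }
  structure(list(ages = ages, degree = as.integer(degree), coefs = coefs,
                 B = B),
            class = "ortho_basis")
}

# evaluate the order-1..degree orthogonal polynomials at arbitrary ages
eval_ortho <- function(basis, ages, degree = basis$degree) {
  if (degree == 0) return(matrix(0, length(ages), 0))
  out <- stats::poly(ages, degree = basis$degree, coefs = basis$coefs)
  unclass(out)[, seq_len(degree), drop = FALSE]
}

#' Build the fixed-effect design matrix
#'
#' Columns: intercept, age orthogonal polynomials 1..\code{age_degree}, sex
#' indicator (male = 1) if included, and sex-by-age interaction columns
#' 1..\code{sex_age_degree}.
#'
#' @param ages Age midpoints, one per observation cell.
#' @param sexes Sex codes ("M"/"F"), one per cell.
#' @param formula A \code{\link{model_formula}}.
#' @param basis Optional pre-built \code{\link{ortho_basis}}; built from the
#'   distinct \code{ages} when omitted.
#' @return List with the design matrix \code{X} and the \code{basis}.
#' @export
build_design <- function(ages, sexes, formula, basis = NULL) {
  if (is.null(basis)) basis <- ortho_basis(ages, formula$age_degree)
  if (basis$degree < formula$age_degree) {
    stop("basis degree below formula age_degree", call. = FALSE)
  }
  s <- sex_indicator(sexes)
  P <- eval_ortho(basis, ages, formula$age_degree)
  X <- cbind(`(Intercept)` = 1, P)
  if (formula$age_degree > 0) {
    colnames(X)[2:(1 + formula$age_degree)] <-
      paste0("age", seq_len(formula$age_degree))
  }
  if (formula$include_sex) {
    X <- cbind(X, sexM = s)
    if (formula$sex_age_degree > 0) {
      XI <- P[, seq_len(formula$sex_age_degree), drop = FALSE] * s
      colnames(XI) <- paste0("sexM:age", seq_len(formula$sex_age_degree))
      X <- cbind(X, XI)
    }
  }
  list(X = X, basis = basis)
}

# stack a list of registry_table objects into fitting arrays
prepare_glmm_data <- function(tables, formula, basis = NULL) {
  stopifnot(length(tables) >= 1)
  measure <- tables[[1]]$measure
  disease <- tables[[1]]$disease_id
  for (t in tables) {
    if (t$measure != measure || t$disease_id != disease) {
      stop("all tables must share one disease and measure", call. = FALSE)
    }
  }
  cells <- do.call(rbind, lapply(tables, function(t) {
    data.frame(registry_id = t$registry_id, t$cells,
               stringsAsFactors = FALSE)
  }))
  grid <- tables[[1]]$grid
  ages <- age_midpoints(cells$age_class, grid)
  des <- build_design(ages, cells$sex, formula, basis)
  link <- if (measure == "incidence") "log" else "logit"
  expo <- cells$exposure
  if (link == "logit") expo <- round(expo)
  list(X = des$X, basis = des$basis, y = cells$events, expo = expo,
       reg = match(cells$registry_id, unique(cells$registry_id)),
       registry_ids = unique(cells$registry_id),
       n_obs = nrow(cells), n_reg = length(unique(cells$registry_id)),
       link = link, measure = measure, disease_id = disease, grid = grid,
       age_classes = sort(unique(match(cells$age_class, grid$label))))
}

# cell log-likelihood at linear predictor eta (vector or matrix)
cell_loglik <- function(eta, y, expo, link) {
  if (link == "log") {
    stats::dpois(y, expo * exp(eta), log = TRUE)
  } else {
    stats::dbinom(y, expo, stats::plogis(eta), log = TRUE)
  }
}

# derivative pieces wrt a registry intercept shift u:
# score contribution per cell = y - mean; curvature per cell = variance
cell_score_curv <- function(eta, y, expo, link) {
  if (link == "log") {
    mu <- expo * exp(eta)
    list(score = y - mu, curv = mu)
  } else {
    p <- stats::plogis(eta)
    list(score = y - expo * p, curv = expo * p * (1 - p))
  }
}

log_sum_exp <- function(m) {
  # rowwise logsumexp of a matrix
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# AGHQ marginal log-likelihood, all registries vectorised.
# dat: output of prepare_glmm_data; gh: pracma::gaussHermite(quad_points)
mll_aghq <- function(beta, sigma, dat, gh) {
  eta0 <- drop(dat$X %*% beta)
  if (sigma <= 0) {
    ll <- sum(cell_loglik(eta0, dat$y, dat$expo, dat$link))
    if (!is.finite(ll)) stop("non-finite likelihood", call. = FALSE)
    return(ll)
  }
  R <- dat$n_reg
  # posterior mode of u per registry by safeguarded Newton
  u <- numeric(R)
  for (it in 1:100) {
    sc <- cell_score_curv(eta0 + u[dat$reg], dat$y, dat$expo, dat$link)
    g <- drop(rowsum(sc$score, dat$reg)) - u / sigma^2
    h <- -drop(rowsum(sc$curv, dat$reg)) - 1 / sigma^2
    step <- -g / h
    # damp very large steps (log-link likelihood can be locally flat)
    step <- pmax(pmin(step, 2), -2)
    u <- u + step
    if (max(abs(step)) < 1e-12) break
  }
  sc <- cell_score_curv(eta0 + u[dat$reg], dat$y, dat$expo, dat$link)
  h <- -drop(rowsum(sc$curv, dat$reg)) - 1 / sigma^2
  tau <- 1 / sqrt(-h)
  # nodes: R x Q matrix of evaluation points
  U <- outer(tau, sqrt(2) * gh$x) + u
  Eta <- eta0 + U[dat$reg, , drop = FALSE]
  LL <- cell_loglik(Eta, dat$y, dat$expo, dat$link)
  ll_req <- rowsum(LL, dat$reg)  # R x Q
  lw <- ll_req + stats::dnorm(U, 0, sigma, log = TRUE) +
    matrix(log(gh$w) + gh$x^2, nrow = R, ncol = length(gh$x), byrow = TRUE)
  out <- sum(log_sum_exp(lw) + log(sqrt(2) * tau))
  if (!is.finite(out)) {
    bad <- which(!is.finite(log_sum_exp(lw)))[1]
    stop("non-finite likelihood for registry ",
         dat$registry_ids[min(bad, R)], call. = FALSE)
  }
  out
}

#' Marginal log-likelihood of the random-intercept model
#'
#' Integrates the registry-specific intercept out of the joint likelihood
#' by adaptive Gauss-Hermite quadrature: for each registry the integral
#' over u ~ Normal(0, sigma_u^2) is recentred at that registry's posterior
#' mode of u and rescaled by the posterior curvature before applying the
#' Gauss-Hermite rule. Incidence uses a Poisson likelihood with log link
#' and log person-years offset; prevalence a binomial likelihood with logit
#' link and persons as trial counts.
#'
#' @param beta Fixed-effect coefficient vector (matching
#'   \code{\link{build_design}} column order).
#' @param log_sigma_u Log of the between-registry SD on the link scale.
#' @param tables List of \code{\link{registry_table}} for one disease and
#'   measure.
#' @param formula A \code{\link{model_formula}}.
#' @param link \code{"log"} or \code{"logit"}; must match the measure.
#' @param quad_points Number of quadrature nodes (default 15).
#' @return The marginal log-likelihood (a scalar).
#' @export
marginal_loglik <- function(beta, log_sigma_u, tables, formula,
                            link = c("log", "logit"), quad_points = 15) {
  link <- match.arg(link)
  dat <- prepare_glmm_data(tables, formula)
  if (dat$link != link) {
    stop("link ", link, " inconsistent with measure ", dat$measure,
         call. = FALSE)
  }
  gh <- pracma::gaussHermite(quad_points)
  mll_aghq(beta, exp(log_sigma_u), dat, gh)
}

# Newton/IRLS maximisation of the fixed-effect likelihood at sigma = 0
# (plain GLM on pooled cells); returns beta
newton_glm <- function(dat, beta0) {
  beta <- beta0
  for (it in 1:50) {
    eta <- drop(dat$X %*% beta)
    sc <- cell_score_curv(eta, dat$y, dat$expo, dat$link)
    g <- drop(crossprod(dat$X, sc$score))
    H <- crossprod(dat$X * sc$curv, dat$X)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # halve until the likelihood does not decrease
    ll0 <- sum(cell_loglik(eta, dat$y, dat$expo, dat$link))
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll1 <- sum(cell_loglik(drop(dat$X %*% cand), dat$y, dat$expo,
                             dat$link))
      if (is.finite(ll1) && ll1 >= ll0 - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    beta <- beta + lam * step
    if (max(abs(lam * step)) < 1e-12) break
  }
  beta
}

crude_start <- function(dat) {
  rate <- sum(dat$y) / sum(dat$expo)
  rate <- min(max(rate, 1e-8), 1 - 1e-8)
  b0 <- if (dat$link == "log") log(rate) else stats::qlogis(rate)
  c(b0, rep(0, ncol(dat$X) - 1))
}

#' Fit a random-intercept GLMM by maximum likelihood
#'
#' Maximises the adaptive Gauss-Hermite marginal likelihood over the fixed
#' effects and \code{log(sigma_u)} by quasi-Newton iteration with jittered
#' restarts. The fixed-effect covariance is the corresponding block of the
#' inverse observed information (numerical Hessian at the optimum). The
#' variance is parameterised as \code{log(sigma_u)} so the optimisation is
#' unconstrained; estimates below 1e-4 are flagged effectively zero.
#'
#' @inheritParams marginal_loglik
#' @param n_starts Number of optimiser starts (deterministic jitter).
#' @param fix_sigma Optional fixed value for \code{sigma_u} (e.g. 0 to fit
#'   a plain pooled GLM); \code{NULL} (default) estimates it. With a single
#'   registry \code{sigma_u} is pinned to 0 with a warning.
#' @param bic_n Sample-size convention for BIC: number of aggregated cells
#'   (\code{"cells"}, default) or total exposure (\code{"exposure"}).
#' @return An object of class \code{glmm_fit}: fixed effects \code{beta},
#'   covariance \code{vcov_beta}, \code{sigma_u}, \code{loglik}, \code{bic},
#'   the \code{formula}, \code{basis}, link, and bookkeeping fields.
#' @export
fit_glmm <- function(tables, formula, link = c("log", "logit"),
                     quad_points = 15, n_starts = 3, fix_sigma = NULL,
                     bic_n = c("cells", "exposure")) {
  link <- match.arg(link)
  bic_n <- match.arg(bic_n)
  dat <- prepare_glmm_data(tables, formula)
  if (dat$link != link) {
    stop("link ", link, " inconsistent with measure ", dat$measure,
         call. = FALSE)
  }
  if (sum(dat$y) == 0) stop("all event counts are zero", call. = FALSE)
  if (dat$n_reg < 2 && is.null(fix_sigma)) {
    warning("single registry: sigma_u pinned to 0")
    fix_sigma <- 0
  }
  gh <- pracma::gaussHermite(quad_points)
  p_beta <- ncol(dat$X)

  # stage 1: pooled-GLM solution as a robust centre for all starts
  beta_glm <- newton_glm(dat, crude_start(dat))

  estimate_sigma <- is.null(fix_sigma)
  if (!estimate_sigma && fix_sigma == 0) {
    beta_hat <- beta_glm
    ll_hat <- mll_aghq(beta_hat, 0, dat, gh)
    sigma_hat <- 0
    H <- {
      sc <- cell_score_curv(drop(dat$X %*% beta_hat), dat$y, dat$expo,
                            dat$link)
      crossprod(dat$X * sc$curv, dat$X)
    }
    vcov_beta <- solve(H)
    conv <- TRUE
  } else {
    negll <- if (estimate_sigma) {
      function(par) -mll_aghq(par[seq_len(p_beta)], exp(par[p_beta + 1]),
                              dat, gh)
    } else {
      function(par) -mll_aghq(par, fix_sigma, dat, gh)
    }
    numgrad <- function(par) {
      hstep <- 1e-6 * (abs(par) + 1)
      g <- numeric(length(par))
      for (i in seq_along(par)) {
        e <- numeric(length(par)); e[i] <- hstep[i]
        g[i] <- (negll(par + e) - negll(par - e)) / (2 * hstep[i])
      }
      g
    }
    base_start <- if (estimate_sigma) c(beta_glm, log(0.2)) else beta_glm
    best <- NULL
    for (k in seq_len(max(1, n_starts))) {
      jit <- if (k == 1) 0 else
        0.25 * sin(seq_along(base_start) * 1.7 + k)  # deterministic jitter
      st <- base_start + jit
      res <- tryCatch(
        stats::optim(st, negll, gr = numgrad, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value)) {
        best <- res
      }
    }
    if (is.null(best)) {
      stop("optimizer failed to converge from all starts", call. = FALSE)
    }
    par_hat <- best$par
    beta_hat <- par_hat[seq_len(p_beta)]
    sigma_hat <- if (estimate_sigma) exp(par_hat[p_beta + 1]) else fix_sigma
    ll_hat <- -best$value
    conv <- best$convergence == 0

    # observed information; drop the variance direction when the estimate
    # sits on the boundary (its curvature degenerates there)
    at_boundary <- estimate_sigma && sigma_hat < 1e-4
    hpar <- if (at_boundary || !estimate_sigma) beta_hat else par_hat
    hfun <- if (at_boundary) {
      function(b) -mll_aghq(b, sigma_hat, dat, gh)
    } else {
      negll
    }
    H <- pracma::hessian(hfun, hpar)
    Hb <- H[seq_len(p_beta), seq_len(p_beta), drop = FALSE]
    Hinv <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(Hinv)) {
      Hinv <- tryCatch(solve(Hb), error = function(e) NULL)
      if (is.null(Hinv)) {
        stop("singular Hessian: consider a simpler formula", call. = FALSE)
      }
      vcov_beta <- Hinv
    } else {
      vcov_beta <- Hinv[seq_len(p_beta), seq_len(p_beta), drop = FALSE]
    }
  }
  vcov_beta <- (vcov_beta + t(vcov_beta)) / 2
  dimnames(vcov_beta) <- list(colnames(dat$X), colnames(dat$X))
  names(beta_hat) <- colnames(dat$X)

  p <- p_beta + if (estimate_sigma) 1L else 0L
  n_bic <- if (bic_n == "cells") dat$n_obs else sum(dat$expo)
  new_glmm_fit(link = dat$link, measure = dat$measure,
               disease_id = dat$disease_id, formula = formula,
               basis = dat$basis, beta = beta_hat,
               vcov_beta = vcov_beta, sigma_u = sigma_hat,
               loglik = ll_hat, bic = -2 * ll_hat + p * log(n_bic),
               n_params = p, n_obs = dat$n_obs,
               n_registries = dat$n_reg, quad_points = quad_points,
               age_classes = dat$age_classes, grid = dat$grid,
               converged = conv)
}

# internal constructor; also used to assemble fits with known parameters
new_glmm_fit <- function(link, measure, disease_id, formula, basis, beta,
                         vcov_beta, sigma_u, loglik = NA_real_,
                         bic = NA_real_, n_params = length(beta) + 1L,
                         n_obs = NA_integer_, n_registries = NA_integer_,
                         quad_points = 15,
                         age_classes = seq_len(nrow(grid)),
                         grid = age_grid(), converged = TRUE) {
  structure(list(link = link, measure = measure, disease_id = disease_id,
                 formula = formula, basis = basis, beta = beta,
                 vcov_beta = vcov_beta, sigma_u = sigma_u,
                 sigma_effectively_zero = sigma_u < 1e-4,
                 loglik = loglik, bic = bic, n_params = n_params,
                 n_obs = n_obs, n_registries = n_registries,
                 quad_points = quad_points, age_classes = age_classes,
                 grid = grid, converged = converged),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "<glmm_fit> %s %s (%s link) %s\n  %d registries, %d cells; sigma_u = %.4g%s\n  loglik = %.3f, BIC = %.2f\n",
    x$disease_id, x$measure, x$link, format(x$formula), x$n_registries,
    x$n_obs, x$sigma_u,
    if (x$sigma_effectively_zero) " (effectively zero)" else "",
    x$loglik, x$bic))
  invisible(x)
}

# enumerate all admissible formulas
candidate_formulas <- function(max_age_degree, max_sex_age_degree,
                               include_sex = TRUE) {
  out <- list()
  for (d in 0:max_age_degree) {
    out[[length(out) + 1]] <- model_formula(d, include_sex = FALSE)
    if (include_sex) {
      for (sad in 0:min(d, max_sex_age_degree)) {
        out[[length(out) + 1]] <- model_formula(d, include_sex = TRUE,
                                                sex_age_degree = sad)
      }
    }
  }
  out
}

# index of the winning row of a BIC table: minimal BIC, ties within 1e-9
# broken towards fewer parameters, then lower age degree, then fewer sex
# terms
pick_best_bic <- function(tab) {
  ok <- !is.na(tab$bic)
  bmin <- min(tab$bic[ok])
  tied <- which(ok & tab$bic <= bmin + 1e-9)
  tied[order(tab$n_params[tied], tab$age_degree[tied],
             tab$include_sex[tied] + tab$sex_age_degree[tied])][1]
}

#' Select the fixed-effect structure by BIC
#'
#' Fits every admissible age/sex formula (exhaustive search, not stepwise)
#' and returns the fit minimising BIC. Ties within 1e-9 are broken towards
#' fewer parameters, then lower age degree, then fewer sex terms.
#'
#' @inheritParams fit_glmm
#' @param max_age_degree Largest age-polynomial order considered
#'   (default 8; capped at the number of distinct midpoints minus one).
#' @param max_sex_age_degree Largest sex-by-age interaction order.
#' @param include_sex Allow sex terms in the candidate space?
#' @return The best \code{\link{glmm_fit}}, with the full BIC table in
#'   attribute \code{"bic_table"}.
#' @export
select_model <- function(tables, link = c("log", "logit"),
                         max_age_degree = 8, max_sex_age_degree = 8,
                         quad_points = 15, n_starts = 3,
                         bic_n = c("cells", "exposure"),
                         include_sex = TRUE) {
  link <- match.arg(link)
  bic_n <- match.arg(bic_n)
  n_ages <- length(unique(unlist(lapply(tables, function(t)
    age_midpoints(t$cells$age_class, t$grid)))))
  max_age_degree <- min(max_age_degree, n_ages - 1)
  cands <- candidate_formulas(max_age_degree, max_sex_age_degree,
                              include_sex)
  fits <- vector("list", length(cands))
  rows <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    f <- cands[[i]]
    fit <- tryCatch(
      fit_glmm(tables, f, link, quad_points = quad_points,
               n_starts = n_starts, bic_n = bic_n),
      error = function(e) e)
    fits[[i]] <- fit
    ok <- inherits(fit, "glmm_fit")
    rows[[i]] <- data.frame(
      formula = format(f), age_degree = f$age_degree,
      include_sex = f$include_sex, sex_age_degree = f$sex_age_degree,
      n_params = n_fixed_params(f) + 1L,
      bic = if (ok) fit$bic else NA_real_,
      loglik = if (ok) fit$loglik else NA_real_,
      converged = ok && fit$converged,
      error = if (ok) "" else conditionMessage(fit),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$bic)
  if (!any(ok)) {
    stop("no candidate model converged (", sum(!ok), " failures)",
         call. = FALSE)
  }
  best <- fits[[pick_best_bic(tab)]]
  attr(best, "bic_table") <- tab[order(tab$bic), ]
  best
}
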