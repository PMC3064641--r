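#' True generative parameters for one synthetic disease
#'
#' The truth is expressed on a raw polynomial basis in scaled age
#' \code{a = age / 100} (deliberately different from the orthogonal basis
#' used when fitting, so the simulator and the fitter communicate only
#' through data): the cell linear predictor is
#' \deqn{\eta = \beta_0 + \sum_k \beta_k a^k + \gamma \cdot male +
#'   \sum_k \delta_k a^k \cdot male + u_r,}
#' with one registry shift \eqn{u_r \sim N(0, \sigma_u^2)} shared by all
#' cells of a registry. Incidence counts are Poisson with mean
#' \code{exposure * exp(eta)}; prevalence counts are binomial with
#' probability \code{plogis(eta)} and the cell population as trial count.
#' There is no extra cell-level overdispersion.
#'
#' @param link \code{"log"} (incidence) or \code{"logit"} (prevalence).
#' @param intercept Intercept on the link scale.
#' @param age_coef Coefficients of \code{a, a^2, ...} (may be empty).
#' @param sex_coef Additive male effect on the link scale.
#' @param sex_age_coef Coefficients of \code{a*male, a^2*male, ...}.
#' @param sigma_u Between-registry SD on the link scale (>= 0).
#' @param min_age_class Lowest age class the disease is analysed on.
#' @return Object of class \code{true_params}.
#' @export
true_params <- function(link = c("log", "logit"), intercept,
                        age_coef = numeric(0), sex_coef = 0,
                        sex_age_coef = numeric(0), sigma_u = 0,
                        min_age_class = "0-4") {
  link <- match.arg(link)
  stopifnot(sigma_u >= 0, length(sex_coef) == 1)
  if (length(sex_age_coef) > length(age_coef)) {
    stop("sex_age_coef longer than age_coef", call. = FALSE)
  }
  structure(list(link = link, intercept = intercept,
                 age_coef = as.numeric(age_coef), sex_coef = sex_coef,
                 sex_age_coef = as.numeric(sex_age_coef),
                 sigma_u = sigma_u, min_age_class = min_age_class),
            class = "true_params")
}

#' True linear predictor of a synthetic disease
#'
#' @param params A \code{\link{true_params}}.
#' @param age Age in years (vector).
#' @param sex Sex codes "M"/"F" (vector, recycled against \code{age}).
#' @return Linear predictor on the link scale (no registry shift).
#' @export
true_eta <- function(params, age, sex) {
  a <- age / 100
  male <- sex_indicator(sex)
  eta <- rep(params$intercept, length.out = max(length(a), length(male)))
  for (k in seq_along(params$age_coef)) {
    eta <- eta + params$age_coef[k] * a^k
  }
  eta <- eta + params$sex_coef * male
  for (k in seq_along(params$sex_age_coef)) {
    eta <- eta + params$sex_age_coef[k] * a^k * male
  }
  eta
}

#' Default registry exposure: a realistic age pyramid
#'
#' Distributes a registry's person total over the 36 (sex, age class)
#' cells: equal sex split, near-uniform weights up to age 60, then
#' geometrically declining (factor 0.72 per 5-year class), imitating the
#' thinning of a western population pyramid at old age so that direct
#' standardization is exercised non-trivially.
#'
#' @param total_persons Registry size (persons; also used as person-years).
#' @param grid Age grid to cover (possibly restricted).
#' @return Data frame \code{sex, age_class, exposure}.
#' @export
default_exposure <- function(total_persons, grid = age_grid()) {
  w <- ifelse(grid$midpoint <= 60, 1, 0.72^((grid$midpoint - 60) / 5))
  w <- w / sum(w) / 2
  out <- expand.grid(sex = sex_levels(), age_class = grid$label,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$exposure <- round(total_persons * w[match(out$age_class, grid$label)])
  out$exposure <- pmax(out$exposure, 1)
  out
}

#' Simulate multi-registry count tables from known parameters
#'
#' Draws one registry intercept shift \code{u_r ~ N(0, sigma_u^2)} per
#' registry and then Poisson (incidence) or binomial (prevalence) counts
#' per cell. Identical seeds give identical output.
#'
#' @param params A \code{\link{true_params}}.
#' @param n_registries Number of registries (>= 1).
#' @param seed Integer RNG seed.
#' @param registry_sizes Person totals per registry (recycled); default
#'   100,000 each.
#' @param disease_id Disease identifier stamped on the tables.
#' @param grid Full age grid (restricted internally to
#'   \code{params$min_age_class}).
#' @param exposures Optional explicit cell exposures: a data frame with
#'   columns \code{sex, age_class, exposure} applied to every registry,
#'   overriding the default age pyramid.
#' @return List of \code{\link{registry_table}}, one per registry, with the
#'   drawn shifts in attribute \code{"u"}.
#' @export
simulate_registry_counts <- function(params, n_registries, seed,
                                     registry_sizes = 1e5,
                                     disease_id = "disease",
                                     grid = age_grid(),
                                     exposures = NULL) {
  stopifnot(n_registries >= 1)
  sub <- age_grid_from(grid, params$min_age_class)
  sizes <- rep_len(registry_sizes, n_registries)
  measure <- if (params$link == "log") "incidence" else "prevalence"
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  u <- stats::rnorm(n_registries, 0, params$sigma_u)
  out <- vector("list", n_registries)
  for (r in seq_len(n_registries)) {
    cells <- if (is.null(exposures)) default_exposure(sizes[r], sub) else
      exposures[exposures$age_class %in% sub$label,
                c("sex", "age_class", "exposure")]
    age <- age_midpoints(cells$age_class, sub)
    eta <- true_eta(params, age, cells$sex) + u[r]
    if (params$link == "log") {
      if (any(eta > 30)) {
        stop("Poisson mean overflow (eta > 30): review parameters",
             call. = FALSE)
      }
      cells$events <- stats::rpois(nrow(cells), cells$exposure * exp(eta))
    } else {
      cells$events <- stats::rbinom(nrow(cells), cells$exposure,
                                    stats::plogis(eta))
    }
    out[[r]] <- registry_table(sprintf("R%02d", r), disease_id, measure,
                               cells, sub)
  }
  attr(out, "u") <- u
  out
}

# quadratic log-curve helper: a log/logit "bump" peaking at age m (scaled)
# with width s is exactly quadratic on the link scale
bump_coef <- function(peak_value_link, m, s) {
  c(intercept = peak_value_link - m^2 / s^2,
    a1 = 2 * m / s^2, a2 = -1 / s^2)
}

#' Library of named simulation scenarios
#'
#' Three families of presets spanning the behaviours seen across chronic
#' diseases in GP registry data:
#' \describe{
#'   \item{flat}{Age-constant rates, 10 registries of 100,000 persons,
#'     between-registry SD 0.3 — the baseline for parameter-recovery and
#'     interval-coverage checks.}
#'   \item{diabetes-like}{A quartic age curve with a modest male excess and
#'     small between-registry SD, on five registries whose sizes mirror a
#'     realistic mix of small and large networks (12,000-350,000).}
#'   \item{arthritis-like}{A quadratic age curve with a female excess and a
#'     large between-registry SD (0.8 incidence, 0.5 prevalence), the
#'     regime where intervals widen dramatically once between-registry
#'     variance is included.}
#' }
#' Each preset carries an incidence (log link) and a prevalence (logit
#' link) disease.
#'
#' @return Named list of presets; each has \code{name},
#'   \code{n_registries}, \code{registry_sizes} and a named list
#'   \code{diseases} of \code{\link{true_params}}.
#' @export
scenario_library <- function() {
  diab_inc <- bump_coef(log(0.006), 0.75, 0.45)
  diab_prev <- bump_coef(stats::qlogis(0.15), 0.75, 0.35)
  arth_inc <- bump_coef(log(0.012), 0.78, 0.50)
  arth_prev <- bump_coef(stats::qlogis(0.10), 0.80, 0.45)
  list(
    flat = list(
      name = "flat", n_registries = 10, registry_sizes = 1e5,
      diseases = list(
        flat_inc = true_params("log", intercept = log(0.005),
                               sigma_u = 0.3),
        flat_prev = true_params("logit", intercept = stats::qlogis(0.05),
                                sigma_u = 0.3))),
    `diabetes-like` = list(
      name = "diabetes-like", n_registries = 5,
      registry_sizes = c(12000, 350000, 88000, 30000, 13000),
      diseases = list(
        diab_inc = true_params(
          "log", intercept = diab_inc[1],
          age_coef = c(diab_inc[2], diab_inc[3], 0, -0.8),
          sex_coef = 0.15, sigma_u = 0.08),
        diab_prev = true_params(
          "logit", intercept = diab_prev[1],
          age_coef = c(diab_prev[2], diab_prev[3], 0, -1.0),
          sex_coef = 0.10, sigma_u = 0.05))),
    `arthritis-like` = list(
      name = "arthritis-like", n_registries = 4,
      registry_sizes = c(12000, 88000, 350000, 30000),
      diseases = list(
        arth_inc = true_params(
          "log", intercept = arth_inc[1],
          age_coef = c(arth_inc[2], arth_inc[3]),
          sex_coef = -0.35, sigma_u = 0.8, min_age_class = "30-34"),
        arth_prev = true_params(
          "logit", intercept = arth_prev[1],
          age_coef = c(arth_prev[2], arth_prev[3]),
          sex_coef = -0.50, sigma_u = 0.5, min_age_class = "30-34")))
  )
}

#' Simulate every disease of a scenario preset
#'
#' @param preset One element of \code{\link{scenario_library}()}.
#' @param seed Integer seed; each disease uses a sub-stream derived from it
#'   so diseases do not perturb one another.
#' @param grid Full age grid.
#' @return Named list (by disease) of lists of \code{registry_table}.
#' @export
simulate_scenario <- function(preset, seed, grid = age_grid()) {
  out <- lapply(names(preset$diseases), function(id) {
    simulate_registry_counts(preset$diseases[[id]], preset$n_registries,
                             seed = sub_seed(seed, id),
                             registry_sizes = preset$registry_sizes,
                             disease_id = id, grid = grid)
  })
  names(out) <- names(preset$diseases)
  out
}

#' Derive a deterministic sub-stream seed from a master seed and a label
#'
#' Used wherever several independent random streams (one per disease) must
#' be reproducible from a single master seed: the derived seed depends only
#' on the master seed and the label, so adding or removing other labels
#' never changes a stream.
#'
#' @param seed Master integer seed.
#' @param label Character label (e.g. a disease id).
#' @return An integer seed in [0, 2^31 - 2].
#' @export
sub_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
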