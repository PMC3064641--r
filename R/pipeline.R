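#' Pipeline configuration
#'
#' @param counts Path to the counts CSV (both measures, one dialect).
#' @param population Path to the standard-population CSV.
#' @param diseases Path to the disease-config YAML, or a
#'   \code{disease_config} object.
#' @param measures Which measures to run.
#' @param max_age_degree,max_sex_age_degree Search bounds for
#'   \code{\link{select_model}}.
#' @param quad_points Quadrature nodes.
#' @param n_draws Monte Carlo draws (>= 1,000; default 5,000).
#' @param seed Master seed (required; no unseeded runs).
#' @param out_dir Output directory.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(counts, population, diseases,
                       measures = c("incidence", "prevalence"),
                       max_age_degree = 8, max_sex_age_degree = 8,
                       quad_points = 15, n_draws = 5000, seed,
                       out_dir = "results") {
  if (missing(seed) || is.null(seed)) {
    stop("a master seed is required", call. = FALSE)
  }
  if (n_draws < 1000) stop("n_draws must be >= 1,000", call. = FALSE)
  measures <- match.arg(measures, several.ok = TRUE)
  structure(list(counts = counts, population = population,
                 diseases = diseases, measures = measures,
                 max_age_degree = max_age_degree,
                 max_sex_age_degree = max_sex_age_degree,
                 quad_points = quad_points, n_draws = n_draws,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

fit_to_list <- function(fit) {
  list(disease_id = fit$disease_id, measure = fit$measure,
       link = fit$link,
       formula = format(fit$formula),
       age_degree = fit$formula$age_degree,
       include_sex = fit$formula$include_sex,
       sex_age_degree = fit$formula$sex_age_degree,
       basis_ages = fit$basis$ages,
       beta = as.list(fit$beta),
       vcov_beta = fit$vcov_beta,
       sigma_u = fit$sigma_u,
       sigma_effectively_zero = fit$sigma_effectively_zero,
       loglik = fit$loglik, bic = fit$bic,
       n_obs = fit$n_obs, n_registries = fit$n_registries)
}

#' Run the full estimation and ranking pipeline
#'
#' Validates every input first (files, grid coverage, and that each
#' configured disease has count tables for each requested measure), then
#' per disease and measure restricts the age range, selects the fixed-
#' effect structure by BIC, computes the standardized rate with both
#' interval types, and finally builds one stochastic league table per
#' measure. All outputs are written as JSON under the configured output
#' directory together with a manifest recording seeds and BIC tables.
#'
#' @param config A \code{\link{run_config}}.
#' @param grid Full age grid.
#' @return The manifest (list), invisibly; side effect: JSON files under
#'   \code{config$out_dir}.
#' @export
run_pipeline <- function(config, grid = age_grid()) {
  stopifnot(inherits(config, "run_config"))
  # ---- validation first: nothing is fitted until all inputs check out
  for (f in c(config$counts, config$population)) {
    if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
  }
  pop <- read_standard_population(config$population, grid)
  dconf <- if (inherits(config$diseases, "disease_config"))
    config$diseases else disease_config(config$diseases, grid)
  tables <- lapply(config$measures, function(m)
    read_counts(config$counts, m, grid))
  names(tables) <- config$measures
  plan <- list()
  for (m in config$measures) {
    ids <- vapply(tables[[m]], function(t) t$disease_id, "")
    reg_key <- paste0(if (m == "incidence") "incidence" else "prevalence",
                      "_registries")
    for (id in names(dconf)) {
      wanted <- dconf[[id]][[reg_key]]
      if (!is.null(wanted) && length(wanted) == 0) next
      have <- which(ids == id)
      if (!length(have)) {
        stop("no ", m, " counts found for configured disease ", id,
             call. = FALSE)
      }
      plan[[paste(id, m, sep = ".")]] <-
        list(disease = id, measure = m, tables = tables[[m]][have])
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- fit, estimate
  fits <- list(); estimates <- list(); bic_tables <- list()
  for (key in names(plan)) {
    p <- plan[[key]]
    message("fitting ", key)
    tabs <- lapply(p$tables, restrict_age_range, config = dconf[[p$disease]])
    link <- if (p$measure == "incidence") "log" else "logit"
    fit <- select_model(tabs, link,
                        max_age_degree = config$max_age_degree,
                        max_sex_age_degree = config$max_sex_age_degree,
                        quad_points = config$quad_points)
    est <- rate_estimate(fit, pop, config$n_draws,
                         seed = sub_seed(config$seed, key))
    fits[[key]] <- fit
    estimates[[key]] <- est
    bic_tables[[key]] <- attr(fit, "bic_table")
    jsonlite::write_json(fit_to_list(fit),
                         file.path(config$out_dir,
                                   paste0("fit_", key, ".json")),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(est),
                         file.path(config$out_dir,
                                   paste0("estimate_", key, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }

  # ---- league tables per measure
  leagues <- list()
  for (m in config$measures) {
    keys <- names(plan)[vapply(plan, function(p) p$measure, "") == m]
    mfits <- fits[keys]
    if (length(mfits) >= 2) {
      message("ranking ", m)
      lt <- league_table(mfits, pop, config$n_draws, config$seed)
      leagues[[m]] <- lt
      jsonlite::write_json(
        list(measure = m, probs = lt$probs, diseases = rownames(lt$probs),
             points = as.list(lt$points), modal_ranks = lt$modal_ranks,
             rank_spans = lt$rank_spans, n_draws = lt$n_draws,
             seed = config$seed),
        file.path(config$out_dir, paste0("league_", m, ".json")),
        auto_unbox = TRUE, digits = NA)
      writeLines(format_league_table(lt),
                 file.path(config$out_dir, paste0("league_", m, ".md")))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("morbrank")),
    seed = config$seed, n_draws = config$n_draws,
    quad_points = config$quad_points,
    inputs = list(counts = config$counts, population = config$population),
    fits = lapply(fits, function(f)
      list(formula = format(f$formula), bic = f$bic,
           sigma_u = f$sigma_u)),
    outputs = c(paste0("fit_", names(plan), ".json"),
                paste0("estimate_", names(plan), ".json"),
                paste0("league_", names(leagues), ".json")))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, fits = fits, estimates = estimates,
                 leagues = leagues, bic_tables = bic_tables))
}
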