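#' Registry count tables: construction and validation
#'
#' A registry table holds the aggregated counts of one registry (GPRN) for
#' one disease and one measure: events and exposure per (sex, age class)
#' cell. For incidence the exposure is person-years lived during the year;
#' for prevalence it is the number of registered persons at the reference
#' date, so events can never exceed exposure.
#'
#' @param registry_id,disease_id Identifiers (strings).
#' @param measure \code{"incidence"} or \code{"prevalence"}.
#' @param cells Data frame with columns \code{sex} ("M"/"F"),
#'   \code{age_class}, \code{events}, \code{exposure}.
#' @param grid The \code{\link{age_grid}} the age labels must belong to.
#' @return An object of class \code{registry_table}.
#' @export
registry_table <- function(registry_id, disease_id, measure, cells,
                           grid = age_grid()) {
  measure <- match.arg(measure, c("incidence", "prevalence"))
  req <- c("sex", "age_class", "events", "exposure")
  if (!all(req %in% names(cells))) {
    stop("cells must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  cells <- as.data.frame(cells)[req]
  if (!all(cells$sex %in% sex_levels())) {
    stop("sex must be coded \"M\"/\"F\"", call. = FALSE)
  }
  if (!all(cells$age_class %in% grid$label)) {
    bad <- setdiff(unique(cells$age_class), grid$label)
    stop("unknown age_class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cells[c("sex", "age_class")])) {
    stop("duplicate (sex, age_class) cell in registry ", registry_id,
         call. = FALSE)
  }
  if (any(cells$events < 0) || any(cells$events != round(cells$events))) {
    stop("events must be non-negative integers", call. = FALSE)
  }
  if (any(cells$exposure <= 0)) {
    stop("exposure must be positive", call. = FALSE)
  }
  if (measure == "prevalence" && any(cells$events > cells$exposure)) {
    stop("prevalence events exceed exposure in registry ", registry_id,
         call. = FALSE)
  }
  # canonical cell order: age within sex (F first)
  ord <- order(match(cells$sex, sex_levels()),
               match(cells$age_class, grid$label))
  cells <- cells[ord, , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(registry_id = as.character(registry_id),
                 disease_id = as.character(disease_id),
                 measure = measure, cells = cells, grid = grid),
            class = "registry_table")
}

#' @export
print.registry_table <- function(x, ...) {
  cat(sprintf("<registry_table> %s / %s (%s): %d cells, %d events\n",
              x$registry_id, x$disease_id, x$measure, nrow(x$cells),
              sum(x$cells$events)))
  invisible(x)
}

#' Read aggregated registry counts from CSV
#'
#' The counts CSV has one row per (registry, disease, measure, sex, age
#' class) cell with header
#' \code{registry_id,disease,measure,sex,age_class,events,exposure}.
#' One dialect serves both measures; the \code{measure} column decides
#' whether \code{exposure} means person-years (incidence) or persons at the
#' reference date (prevalence).
#'
#' @param path CSV file path.
#' @param measure Which measure to load, \code{"incidence"} or
#'   \code{"prevalence"}.
#' @param grid Age grid for label validation.
#' @return A list of \code{\link{registry_table}} objects, one per
#'   (registry, disease) pair present for the requested measure; empty list
#'   for a header-only file.
#' @export
read_counts <- function(path, measure, grid = age_grid()) {
  measure <- match.arg(measure, c("incidence", "prevalence"))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(events = "numeric",
                                      exposure = "numeric"))
  req <- c("registry_id", "disease", "measure", "sex", "age_class",
           "events", "exposure")
  if (!all(req %in% names(d))) {
    stop("counts CSV must have columns ", paste(req, collapse = ","),
         call. = FALSE)
  }
  d$row <- seq_len(nrow(d)) + 1L  # +1 for the header line
  d <- d[d$measure == measure, , drop = FALSE]
  if (nrow(d) == 0) return(list())
  key <- paste(d$registry_id, d$disease, d$sex, d$age_class, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate cell at row ", d$row[duplicated(key)][1], " of ", path,
         call. = FALSE)
  }
  bad_age <- !(d$age_class %in% grid$label)
  if (any(bad_age)) {
    stop("unknown age_class \"", d$age_class[bad_age][1], "\" at row ",
         d$row[bad_age][1], call. = FALSE)
  }
  if (measure == "prevalence" && any(d$events > d$exposure)) {
    i <- which(d$events > d$exposure)[1]
    stop("prevalence events > exposure at row ", d$row[i], call. = FALSE)
  }
  split_key <- paste(d$registry_id, d$disease, sep = "\r")
  parts <- split(d, split_key)
  out <- lapply(parts, function(p) {
    registry_table(p$registry_id[1], p$disease[1], measure,
                   p[c("sex", "age_class", "events", "exposure")], grid)
  })
  names(out) <- NULL
  # stable order: registry then disease
  ord <- order(vapply(out, function(t) t$registry_id, ""),
               vapply(out, function(t) t$disease_id, ""))
  out[ord]
}

#' Write registry tables back to the counts CSV dialect
#'
#' @param tables List of \code{\link{registry_table}} objects.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(tables, path) {
  rows <- lapply(tables, function(t) {
    data.frame(registry_id = t$registry_id, disease = t$disease_id,
               measure = t$measure, t$cells, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop age classes below a disease's minimum analysis age
#'
#' Diseases only relevant at older ages are analysed on a restricted grid;
#' cells below the configured minimum class are discarded. Idempotent.
#'
#' @param table A \code{\link{registry_table}}.
#' @param config A \code{\link{disease_config}} entry (or any list with
#'   \code{min_age_class}).
#' @return The restricted \code{registry_table}; its \code{grid} is the
#'   restricted grid.
#' @export
restrict_age_range <- function(table, config) {
  sub <- age_grid_from(table$grid, config$min_age_class)
  keep <- table$cells$age_class %in% sub$label
  if (!any(keep)) {
    stop("no cells remain after age restriction for ", table$disease_id,
         ": grid/config mismatch", call. = FALSE)
  }
  table$cells <- table$cells[keep, , drop = FALSE]
  rownames(table$cells) <- NULL
  table$grid <- sub
  table
}

#' Read a standard population table
#'
#' CSV with columns \code{sex,age_class,population} covering every (sex,
#' age class) cell of the full grid — the reference age/sex distribution
#' used for direct standardization.
#'
#' @param path CSV file path.
#' @param grid The full \code{\link{age_grid}} the table must cover.
#' @return An object of class \code{standard_population}: data frame
#'   \code{sex, age_class, population} in canonical cell order.
#' @export
read_standard_population <- function(path, grid = age_grid()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sex", "age_class", "population")
  if (!all(req %in% names(d))) {
    stop("standard population CSV must have columns ",
         paste(req, collapse = ","), call. = FALSE)
  }
  standard_population(d, grid)
}

#' @rdname read_standard_population
#' @param d Data frame with columns \code{sex,age_class,population}.
#' @export
standard_population <- function(d, grid = age_grid()) {
  full <- expand.grid(sex = sex_levels(), age_class = grid$label,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_full <- paste(full$sex, full$age_class)
  key_d <- paste(d$sex, d$age_class)
  if (anyDuplicated(key_d)) {
    stop("duplicate (sex, age_class) in standard population", call. = FALSE)
  }
  missing <- setdiff(key_full, key_d)
  if (length(missing)) {
    stop("standard population incomplete; missing cell(s): ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  extra <- setdiff(key_d, key_full)
  if (length(extra)) {
    stop("unknown cell(s) in standard population: ",
         paste(extra, collapse = "; "), call. = FALSE)
  }
  if (any(d$population < 0)) stop("negative population", call. = FALSE)
  if (sum(d$population) <= 0) stop("total population is zero", call. = FALSE)
  d <- d[match(key_full, key_d), c("sex", "age_class", "population")]
  rownames(d) <- NULL
  structure(d, grid = grid, class = c("standard_population", "data.frame"))
}

#' Read disease configuration from YAML
#'
#' The configuration maps each disease id to its display name, minimum
#' analysis age class, diagnostic code lists (ICPC-1 and E-codes — carried
#' as metadata only; inputs are pre-aggregated) and the registries that
#' report each measure.
#'
#' @param path YAML file path.
#' @param grid Age grid used to validate \code{min_age_class}.
#' @return Named list of per-disease config lists, class
#'   \code{disease_config}.
#' @export
disease_config <- function(path, grid = age_grid()) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(id) {
    c0 <- raw[[id]]
    c0$disease_id <- id
    if (is.null(c0$min_age_class)) c0$min_age_class <- grid$label[1]
    if (!c0$min_age_class %in% grid$label) {
      stop("disease ", id, ": invalid min_age_class ", c0$min_age_class,
           call. = FALSE)
    }
    c0
  })
  names(out) <- names(raw)
  structure(out, class = "disease_config")
}
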