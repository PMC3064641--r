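#' Five-year age-class grid
#'
#' The national reporting grid has 18 five-year age classes, \code{"0-4"},
#' \code{"5-9"}, ..., \code{"80-84"}, \code{"85+"}. Age enters all models
#' through a single representative value per class: the class midpoint
#' (2.5, 7.5, ..., 82.5). The open-ended top class has no natural midpoint;
#' it defaults to 90 years and is configurable.
#'
#' @param top_midpoint Midpoint (years) assigned to the open-ended "85+"
#'   class. Default 90.
#' @return An object of class \code{age_grid}: a data frame with columns
#'   \code{label}, \code{lower} (lower bound in years) and \code{midpoint},
#'   ordered by age.
#' @examples
#' g <- age_grid()
#' nrow(g)        # 18
#' g$label[18]    # "85+"
#' @export
age_grid <- function(top_midpoint = 90) {
  lower <- seq(0, 85, by = 5)
  label <- c(paste(lower[-18], lower[-18] + 4, sep = "-"), "85+")
  midpoint <- c(lower[-18] + 2.5, top_midpoint)
  stopifnot(top_midpoint > 85)
  g <- data.frame(label = label, lower = lower, midpoint = midpoint,
                  stringsAsFactors = FALSE)
  class(g) <- c("age_grid", "data.frame")
  g
}

#' Restrict an age grid to classes at or above a minimum class
#'
#' @param grid An \code{\link{age_grid}}.
#' @param min_label Label of the lowest class to keep (e.g. \code{"50-54"}).
#' @return The subset of \code{grid}, same class, order preserved.
#' @export
age_grid_from <- function(grid, min_label) {
  i <- match(min_label, grid$label)
  if (is.na(i)) {
    stop("unknown age class label: ", min_label, call. = FALSE)
  }
  out <- grid[seq(i, nrow(grid)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("age_grid", "data.frame")
  out
}

#' Look up class midpoints for a vector of labels
#'
#' @param labels Character vector of age-class labels.
#' @param grid An \code{\link{age_grid}}.
#' @return Numeric vector of midpoints, same length as \code{labels}.
#' @export
age_midpoints <- function(labels, grid = age_grid()) {
  i <- match(labels, grid$label)
  if (anyNA(i)) {
    stop("unknown age class label(s): ",
         paste(unique(labels[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  grid$midpoint[i]
}

# internal: canonical sex codes used throughout ("F" reference, "M" = 1)
sex_levels <- function() c("F", "M")

sex_indicator <- function(sex) {
  if (!all(sex %in% sex_levels())) {
    stop("sex must be coded \"M\"/\"F\"", call. = FALSE)
  }
  as.integer(sex == "M")
}
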