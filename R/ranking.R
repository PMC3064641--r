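#' Monte Carlo draws of standardized rates for several diseases
#'
#' For every disease, coefficients are repeatedly drawn from a multivariate
#' normal on the link scale, a fresh registry shift is added (the draws
#' include the between-registry variance), and each replicate is
#' standardized per 1,000. Diseases are treated as independent: each gets
#' its own random sub-stream derived from the master seed (see
#' \code{\link{sub_seed}}), so adding a disease never perturbs another
#' disease's draws.
#'
#' @param fits Named list of \code{\link{glmm_fit}} (one measure).
#' @param pop The shared \code{\link{standard_population}}.
#' @param n_draws Draws per disease (default 5,000).
#' @param seed Master integer seed.
#' @return \code{n_draws} x \code{length(fits)} matrix of cases per 1,000;
#'   columns named by disease.
#' @export
draw_rates <- function(fits, pop, n_draws = 5000, seed = 1) {
  ids <- vapply(fits, function(f) f$disease_id, "")
  if (anyDuplicated(ids)) stop("duplicate disease ids", call. = FALSE)
  out <- matrix(NA_real_, n_draws, length(fits),
                dimnames = list(NULL, ids))
  for (i in seq_along(fits)) {
    out[, i] <- with_local_seed(sub_seed(seed, ids[i]),
      sample_standardized(fits[[i]], pop, n_draws, include_random = TRUE))
  }
  out
}

#' Stochastic league table from rate draws
#'
#' Within each Monte Carlo draw the diseases are ranked in descending order
#' of magnitude (rank 1 = highest); exact ties are broken uniformly at
#' random. The rank-probability matrix P[d, k] is the fraction of draws in
#' which disease d took rank k; each draw assigns every rank exactly once,
#' so P is doubly stochastic.
#'
#' @param rate_draws Draws x diseases matrix (e.g. from
#'   \code{\link{draw_rates}}).
#' @param points Optional point estimates per disease used to order the
#'   table rows (descending); defaults to the draw means.
#' @param seed Optional seed for the (measure-zero) random tie-breaks.
#' @param threshold Display threshold used for the rank spans.
#' @return Object of class \code{rank_table}: \code{probs} (diseases x
#'   ranks, rows ordered by descending point estimate), \code{points},
#'   \code{point_ranks}, \code{modal_ranks}, \code{rank_spans},
#'   \code{n_draws}.
#' @export
stochastic_rank <- function(rate_draws, points = NULL, seed = NULL,
                            threshold = 0.005) {
  rate_draws <- as.matrix(rate_draws)
  D <- ncol(rate_draws)
  n <- nrow(rate_draws)
  stopifnot(D >= 2, n >= 1)
  ids <- colnames(rate_draws)
  if (is.null(ids)) ids <- paste0("d", seq_len(D))
  if (is.null(points)) points <- colMeans(rate_draws)
  rank_one <- function(x) rank(-x, ties.method = "random")
  ranks <- if (is.null(seed)) t(apply(rate_draws, 1, rank_one)) else
    with_local_seed(sub_seed(seed, "tie-break"),
                    t(apply(rate_draws, 1, rank_one)))
  P <- t(vapply(seq_len(D), function(d) tabulate(ranks[, d], D),
                numeric(D))) / n
  dimnames(P) <- list(ids, seq_len(D))
  ord <- order(-points)
  P <- P[ord, , drop = FALSE]
  points <- points[ord]
  structure(list(probs = P, points = points,
                 point_ranks = seq_len(D),
                 modal_ranks = apply(P, 1, which.max),
                 rank_spans = apply(P, 1, function(p)
                   sum(p >= threshold)),
                 threshold = threshold, n_draws = n),
            class = "rank_table")
}

#' Full stochastic league table from fitted models
#'
#' @inheritParams draw_rates
#' @return A \code{\link{stochastic_rank}} table whose rows are ordered by
#'   the plug-in point estimates.
#' @export
league_table <- function(fits, pop, n_draws = 5000, seed = 1) {
  draws <- draw_rates(fits, pop, n_draws, seed)
  points <- vapply(fits, standardize_per_1000, numeric(1), pop = pop)
  names(points) <- colnames(draws)
  tab <- stochastic_rank(draws, points = points, seed = seed)
  tab$seed <- seed
  tab
}

# accept a rank_table or a plain probability matrix with disease rownames
as_rank_matrix <- function(table) {
  if (inherits(table, "rank_table")) return(table$probs)
  m <- as.matrix(table)
  if (is.null(rownames(m))) stop("matrix needs disease rownames",
                                 call. = FALSE)
  m
}

#' Number of rank positions a disease plausibly occupies
#'
#' Counts the rank positions whose probability is at or above the display
#' threshold (default 0.005, i.e. entries that would round to at least
#' 0.01 in a two-decimal table).
#'
#' @param table A \code{\link{stochastic_rank}} table or a probability
#'   matrix with disease rownames.
#' @param disease Disease id (row name).
#' @param threshold Display probability threshold.
#' @return Integer rank span.
#' @export
rank_span <- function(table, disease, threshold = 0.005) {
  m <- as_rank_matrix(table)
  if (!disease %in% rownames(m)) stop("unknown disease: ", disease,
                                      call. = FALSE)
  sum(m[disease, ] >= threshold)
}

#' Row-wise and column-wise maxima of a league table
#'
#' Flags, for every disease (row), the rank position(s) it is most likely
#' to occupy ("modal"), and for every rank position (column), the
#' disease(s) most likely to take it ("leader"). Ties are flagged jointly.
#'
#' @param table A \code{\link{stochastic_rank}} table or probability
#'   matrix.
#' @param tol Tie tolerance on probabilities.
#' @return List with \code{modal} (per disease, integer vector of rank
#'   positions) and \code{leader} (per rank, character vector of disease
#'   ids).
#' @export
annotate_league_table <- function(table, tol = 1e-12) {
  m <- as_rank_matrix(table)
  modal <- lapply(seq_len(nrow(m)), function(d) {
    unname(which(m[d, ] >= max(m[d, ]) - tol))
  })
  names(modal) <- rownames(m)
  leader <- lapply(seq_len(ncol(m)), function(k) {
    rownames(m)[m[, k] >= max(m[, k]) - tol]
  })
  names(leader) <- colnames(m)
  list(modal = modal, leader = leader)
}

#' Render a league table with modal and leader markers
#'
#' Two-decimal rank probabilities; blanks below the display threshold;
#' row maxima (modal rank positions) bracketed, column maxima (rank
#' leaders) bold.
#'
#' @param table A \code{\link{stochastic_rank}} table or probability
#'   matrix.
#' @param format \code{"markdown"} or \code{"csv"}.
#' @param threshold Display threshold below which entries print blank.
#' @return Character vector of output lines.
#' @export
format_league_table <- function(table, format = c("markdown", "csv"),
                                threshold = 0.005) {
  format <- match.arg(format)
  m <- as_rank_matrix(table)
  ann <- annotate_league_table(m)
  D <- nrow(m); K <- ncol(m)
  cells <- matrix("", D, K)
  for (d in seq_len(D)) {
    for (k in seq_len(K)) {
      if (m[d, k] < threshold) next
      s <- sprintf("%.2f", m[d, k])
      if (rownames(m)[d] %in% ann$leader[[k]]) s <- paste0("**", s, "**")
      if (k %in% ann$modal[[d]]) s <- paste0("[", s, "]")
      cells[d, k] <- s
    }
  }
  if (format == "markdown") {
    header <- paste0("| disease | ", paste(seq_len(K), collapse = " | "),
                     " |")
    sep <- paste0("|", paste(rep("---", K + 1), collapse = "|"), "|")
    rows <- vapply(seq_len(D), function(d) {
      paste0("| ", rownames(m)[d], " | ",
             paste(cells[d, ], collapse = " | "), " |")
    }, "")
    c(header, sep, rows)
  } else {
    c(paste(c("disease", seq_len(K)), collapse = ","),
      vapply(seq_len(D), function(d)
        paste(c(rownames(m)[d], cells[d, ]), collapse = ","), ""))
  }
}

#' Read a transcribed rank-probability table from CSV
#'
#' CSV with a \code{disease} column followed by one column per rank
#' position; empty cells are zero probability. Intended for published
#' two-decimal tables, whose rows need not sum exactly to 1.
#'
#' @param path CSV file path.
#' @return Probability matrix with disease rownames.
#' @export
read_rank_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE,
                       stringsAsFactors = FALSE)
  stopifnot(names(d)[1] == "disease")
  m <- as.matrix(d[, -1, drop = FALSE])
  m[is.na(m)] <- 0
  rownames(m) <- d$disease
  m
}
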