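test_that("separated diseases give a permutation matrix", {
  draws <- cbind(A = rnorm(500, 100, 1), B = rnorm(500, 5, 1))
  tab <- stochastic_rank(draws, seed = 1)
  expect_equal(unname(tab$probs), rbind(c(1, 0), c(0, 1)))
  expect_equal(rownames(tab$probs), c("A", "B"))
})

test_that("exchangeable diseases split rank one evenly", {
  set.seed(11)
  draws <- cbind(A = rnorm(5000, 5, 0.5), B = rnorm(5000, 5, 0.5))
  tab <- stochastic_rank(draws, seed = 2)
  expect_lt(abs(tab$probs["A", 1] - 0.5), 0.02)
})

test_that("rank tables are doubly stochastic", {
  set.seed(12)
  draws <- cbind(a = rnorm(2000, 5), b = rnorm(2000, 4.8),
                 c = rnorm(2000, 4.6), d = rnorm(2000, 1))
  tab <- stochastic_rank(draws, seed = 3)
  expect_lt(max(abs(rowSums(tab$probs) - 1)), 1e-9)
  expect_lt(max(abs(colSums(tab$probs) - 1)), 1e-9)
  expect_true(all(tab$probs >= 0 & tab$probs <= 1))
})

test_that("exact ties are split at random rather than by column order", {
  draws <- cbind(A = rep(1, 4000), B = rep(1, 4000))
  tab <- stochastic_rank(draws, seed = 4)
  expect_lt(abs(tab$probs["A", 1] - 0.5), 0.05)
})

test_that("disease draw streams are independent of the disease set", {
  fits <- list(
    x = known_fit(log(0.004), matrix(0.02, 1, 1), 0.2, "log", 0,
                  disease_id = "x"),
    y = known_fit(log(0.003), matrix(0.03, 1, 1), 0.1, "log", 0,
                  disease_id = "y"),
    z = known_fit(log(0.005), matrix(0.01, 1, 1), 0.3, "log", 0,
                  disease_id = "z"))
  pop <- uniform_pop()
  all3 <- draw_rates(fits, pop, n_draws = 500, seed = 7)
  just_y <- draw_rates(fits["y"], pop, n_draws = 500, seed = 7)
  expect_identical(all3[, "y"], just_y[, "y"])
  # same protocol as the interval machinery: identical replicate stream
  vals <- morbrank:::with_local_seed(
    sub_seed(7, "y"),
    morbrank:::sample_standardized(fits$y, pop, 500, TRUE))
  expect_identical(all3[, "y"], vals)
})

test_that("zero-uncertainty league table is the point-estimate permutation", {
  fits <- list(
    hi = known_fit(log(0.006), matrix(0, 1, 1), 0, "log", 0,
                   disease_id = "hi"),
    mid = known_fit(log(0.004), matrix(0, 1, 1), 0, "log", 0,
                    disease_id = "mid"),
    lo = known_fit(log(0.002), matrix(0, 1, 1), 0, "log", 0,
                   disease_id = "lo"))
  tab <- league_table(fits, uniform_pop(), n_draws = 1000, seed = 9)
  expect_equal(unname(tab$probs), diag(3))
  expect_equal(rownames(tab$probs), c("hi", "mid", "lo"))
  expect_equal(unname(tab$modal_ranks), 1:3)
  expect_equal(unname(tab$rank_spans), c(1L, 1L, 1L))
})

test_that("shrinking all variances sharpens the point-estimate ranks", {
  mu <- c(5, 4, 3)
  set.seed(21)
  z <- matrix(rnorm(5000 * 3), 5000, 3)
  p_at <- function(c) {
    draws <- sweep(z * c, 2, mu, "+")
    colnames(draws) <- c("a", "b", "c")
    tab <- stochastic_rank(draws, points = mu, seed = 5)
    diag(tab$probs)
  }
  expect_true(all(p_at(0.5) >= p_at(1)))
})

test_that("published league-table summaries reproduce the printed structure", {
  inc <- published_table("incidence")
  expect_equal(dim(inc), c(18, 18))
  expect_equal(rank_span(inc, "Arthritis"), 12)
  expect_equal(rank_span(inc, "Coronary heart disease"), 5)
  ann <- annotate_league_table(inc)
  expect_equal(ann$modal$Arthritis, 1)
  expect_equal(ann$leader$`2`, "Cataracts")
  prev <- published_table("prevalence")
  expect_equal(rank_span(prev, "Multiple sclerosis"), 2)
  # arthritis leads rank 1 for prevalence although diabetes is first on
  # point estimates (row order)
  expect_equal(annotate_league_table(prev)$leader$`1`, "Arthritis")
  expect_equal(rownames(prev)[1], "Diabetes")
})

test_that("identity tables have span one and diagonal annotations", {
  m <- diag(3)
  dimnames(m) <- list(c("a", "b", "c"), 1:3)
  for (d in rownames(m)) expect_equal(rank_span(m, d), 1)
  ann <- annotate_league_table(m)
  expect_equal(unlist(ann$modal), c(a = 1L, b = 2L, c = 3L))
  expect_equal(unlist(ann$leader), c(`1` = "a", `2` = "b", `3` = "c"))
  expect_error(rank_span(m, "nope"), "unknown disease")
})

test_that("rendered tables carry modal and leader markers", {
  m <- rbind(A = c(0.7, 0.3), B = c(0.3, 0.7))
  colnames(m) <- 1:2
  md <- format_league_table(m, "markdown")
  expect_true(any(grepl("[**0.70**]", md, fixed = TRUE)))
  csv <- format_league_table(m, "csv")
  expect_equal(length(csv), 3)
})
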