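# shared fixtures: all built in code, nothing read from disk

# small two-registry instance with 2 sexes x 2 age classes per registry
toy_tables <- function(measure = "incidence") {
  cells <- expand.grid(sex = c("F", "M"), age_class = c("40-44", "60-64"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  c1 <- cells; c1$events <- c(12, 25, 30, 41)
  c1$exposure <- c(3000, 2500, 2800, 2600)
  c2 <- cells; c2$events <- c(20, 14, 35, 28)
  c2$exposure <- c(4000, 1800, 3100, 2200)
  list(registry_table("A", "toy", measure, c1),
       registry_table("B", "toy", measure, c2))
}

# brute-force trapezoid integration of the marginal likelihood over
# u in [-8 sigma, 8 sigma]; the independent oracle for the AGHQ path
trap_loglik <- function(beta, sigma, tables, formula, link,
                        nodes = 20001) {
  dat <- morbrank:::prepare_glmm_data(tables, formula)
  eta0 <- drop(dat$X %*% beta)
  total <- 0
  for (r in seq_len(dat$n_reg)) {
    i <- dat$reg == r
    u <- seq(-8 * sigma, 8 * sigma, length.out = nodes)
    h <- vapply(u, function(uu) {
      sum(morbrank:::cell_loglik(eta0[i] + uu, dat$y[i], dat$expo[i],
                                 link)) +
        stats::dnorm(uu, 0, sigma, log = TRUE)
    }, numeric(1))
    mx <- max(h)
    du <- u[2] - u[1]
    s <- sum(exp(h - mx)) - 0.5 * (exp(h[1] - mx) + exp(h[nodes] - mx))
    total <- total + mx + log(s * du)
  }
  total
}

# uniform standard population (same count in every cell)
uniform_pop <- function(per_cell = 1000, grid = age_grid()) {
  d <- expand.grid(sex = c("F", "M"), age_class = grid$label,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$population <- per_cell
  standard_population(d, grid)
}

# assemble a glmm_fit with known parameters (for standardization and
# ranking tests that need exact control over beta, vcov and sigma_u)
known_fit <- function(beta, vcov_beta, sigma_u, link = "log",
                      age_degree = length(beta) - 1L,
                      disease_id = "known", grid = age_grid(),
                      age_classes = seq_len(nrow(grid))) {
  formula <- model_formula(age_degree, include_sex = FALSE)
  basis <- ortho_basis(grid$midpoint[age_classes], age_degree)
  morbrank:::new_glmm_fit(
    link = link,
    measure = if (link == "log") "incidence" else "prevalence",
    disease_id = disease_id, formula = formula, basis = basis,
    beta = beta, vcov_beta = vcov_beta, sigma_u = sigma_u,
    age_classes = age_classes, grid = grid)
}

published_table <- function(measure) {
  read_rank_table(system.file("extdata",
                              paste0("ranktable_", measure, "_2007.csv"),
                              package = "morbrank"))
}
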