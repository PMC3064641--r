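#!/usr/bin/env Rscript
# Stage 3: convert each fitted model into directly standardized cases per
# 1,000 for the average registry, with 95% intervals excluding and
# including the between-registry variance (5,000 Monte Carlo draws each).

suppressMessages(library(morbrank))
seed <- as.integer(Sys.getenv("MORBRANK_SEED", "1"))
pop <- read_standard_population(
  system.file("extdata", "standard_population_nl2007_synthetic.csv",
              package = "morbrank"))

files <- list.files("results/fits", pattern = "\\.rds$",
                    full.names = TRUE)
rows <- lapply(files, function(f) {
  fit <- readRDS(f)
  est <- rate_estimate(fit, pop, n_draws = 5000,
                       seed = sub_seed(seed, fit$disease_id))
  data.frame(disease = est$disease_id, measure = est$measure,
             per_1000 = est$point,
             fixed_lo = est$ci_fixed[1], fixed_hi = est$ci_fixed[2],
             total_lo = est$ci_total[1], total_hi = est$ci_total[2],
             sigma_u = fit$sigma_u)
})
tab <- do.call(rbind, rows)
tab <- tab[order(tab$measure, -tab$per_1000), ]
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/standardized_rates.csv",
                 row.names = FALSE)
print(tab, row.names = FALSE, digits = 4)
cat("\nNote how the total interval hardly differs from the fixed-only\n",
    "interval where sigma_u is small, but widens dramatically for the\n",
    "arthritis-like diseases.\n", sep = "")
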