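#!/usr/bin/env Rscript
# Stage 4: stochastic league tables. 5,000 draws per disease from the
# fitted sampling distributions (including between-registry variance),
# ranked within each draw; the result is the probability that each
# disease occupies each rank, rendered with row-maximum (modal rank,
# bracketed) and column-maximum (rank leader, bold) markers.

suppressMessages(library(morbrank))
seed <- as.integer(Sys.getenv("MORBRANK_SEED", "1"))
pop <- read_standard_population(
  system.file("extdata", "standard_population_nl2007_synthetic.csv",
              package = "morbrank"))

fits <- lapply(list.files("results/fits", pattern = "\\.rds$",
                          full.names = TRUE), readRDS)
for (measure in c("incidence", "prevalence")) {
  mf <- Filter(function(f) f$measure == measure, fits)
  if (length(mf) < 2) next
  lt <- league_table(mf, pop, n_draws = 5000, seed = seed)
  lines <- format_league_table(lt)
  writeLines(lines, file.path("results",
                              paste0("league_", measure, ".md")))
  cat("\n==", measure, "league table (rank probabilities) ==\n")
  writeLines(lines)
  cat("rank spans:", paste(rownames(lt$probs), lt$rank_spans,
                           sep = "=", collapse = ", "), "\n")
}
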