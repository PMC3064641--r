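# Reference data

- `ranktable_incidence_2007.csv`, `ranktable_prevalence_2007.csv`:
  published stochastic league tables (rank-position probabilities, two
  decimals, blank = below display threshold) for 18 chronic diseases in
  Dutch general-practice registration networks, year 2007. Transcribed
  from print; rows sum to 1 only up to rounding. Used as fixed inputs for
  the table-summary operations (`rank_span`, `annotate_league_table`,
  `read_rank_table`), never as fitting targets.
- `standard_population_nl2007_synthetic.csv`: synthetic stand-in for a
  national age/sex standard population (persons per sex and 5-year age
  class, smooth pyramid, 16.4M total). The true reference distribution is
  not shipped; this file only has to be a plausible weighting.
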