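#!/usr/bin/env Rscript
# Stage 3: descriptive tables and nonparametric comparisons.
#
# Rebuilds the cohort deliverables from the scored table: claim/indicator
# prevalence per imitation category, median (Q1, Q3) composition by
# category x origin and by matrix within plant products, the Nutri-Score
# grade distribution, and the plant-vs-animal / across-matrix comparison
# battery (Mann-Whitney U / Kruskal-Wallis, adjusted alpha printed in every
# row). Writes one CSV per table under results/.

suppressMessages({
  library(nutriprofiler)
  library(dplyr)
  library(readr)
})

out_dir <- "results"
db <- read_products(file.path(out_dir, "products.csv"))
sc <- score_products(db$products)
tables <- run_report(sc$scored)

write_csv(tables$prevalence,
  file.path(out_dir, "claims_prevalence.csv"), na = "")
write_csv(tables$composition_by_origin,
  file.path(out_dir, "composition_by_origin.csv"), na = "")
write_csv(tables$composition_by_matrix,
  file.path(out_dir, "composition_by_matrix.csv"), na = "")
write_csv(
  mutate(tables$grade_distribution, grade = as.character(grade)),
  file.path(out_dir, "grade_distribution.csv"), na = ""
)
write_csv(select(tables$comparisons, -summary),
  file.path(out_dir, "comparisons.csv"), na = "")

message("modal grade per cheese group:")
tables$grade_distribution |>
  filter(category == "cheese") |>
  group_by(origin) |>
  slice_max(pct, n = 1) |>
  select(origin, grade, pct) |>
  print()

message("plant vs animal comparisons flagged significant:")
tables$comparisons |>
  filter(test != "skipped", grepl("animal", groups), significant) |>
  count(stratum) |>
  print()
message("alpha used: ", unique(tables$comparisons$alpha_adjusted))
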