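#!/usr/bin/env Rscript
# Stage 2: score every product.
#
# Reads results/products.csv, applies the missing-data exclusion policy,
# estimates FV% from each ingredient list, computes the FSAm-NPS score and
# Nutri-Score grade, and writes results/scored.csv plus the exclusion and
# rejection reports. Every input row lands in exactly one of the three
# outputs.

suppressMessages({
  library(nutriprofiler)
  library(dplyr)
  library(readr)
})

out_dir <- "results"
db <- read_products(file.path(out_dir, "products.csv"))
message(sprintf(
  "read %d products (%d malformed rows rejected)",
  nrow(db$products), nrow(db$rejects)
))

sc <- score_products(db$products)
stopifnot(
  nrow(db$products) == nrow(sc$scored) + nrow(sc$excluded)
)
message(sprintf(
  "scored %d products; %d excluded for missing negative-nutrient data",
  nrow(sc$scored), nrow(sc$excluded)
))

flat <- sc$scored |>
  select(-ingredients, -claims, -indicators) |>
  mutate(grade = as.character(grade))
write_csv(flat, file.path(out_dir, "scored.csv"), na = "")
write_csv(sc$excluded, file.path(out_dir, "excluded.csv"), na = "")
write_csv(db$rejects, file.path(out_dir, "rejected.csv"), na = "")

message("grade counts by origin:")
print(table(sc$scored$origin, sc$scored$grade))
if (all(sc$scored$fv_points == 0)) {
  message("no product earned FV points (as in the real imitation cohort)")
}
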