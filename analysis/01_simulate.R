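#!/usr/bin/env Rscript
# Stage 1: generate the study-like product database.
#
# Draws a synthetic branded-food database with the statistical structure of
# the meat/dairy imitation cohort (14 groups: 7 categories x plant/animal;
# published group sizes, median/quartile nutrient targets, matrix mixtures,
# claim prevalences, label missingness) and writes it to
# results/products.csv plus the specification used to results/spec.yaml.

suppressMessages(library(nutriprofiler))

seed <- 1L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

spec <- study_like_spec()
message(sprintf(
  "simulating %d products across %d groups (seed %d)",
  sum(spec$n), nrow(spec), seed
))
products <- generate_products(spec, seed = seed)
write_products(products, file.path(out_dir, "products.csv"))
write_spec_yaml(spec, file.path(out_dir, "spec.yaml"))

counts <- table(products$category, products$origin)
print(counts)
message("wrote ", file.path(out_dir, "products.csv"))
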