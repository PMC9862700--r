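Package: nutriprofiler
Title: FSAm-NPS Nutrient Profiling and Cohort Comparison for Branded Foods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the FSAm-NPS nutrient profiling score and the derived
    Nutri-Score grade (A-E) for branded food products, including the
    conditional protein rule, the cheese exception, the solid-food treatment
    of plant-based beverages, and the two-step estimation of the
    fruit/vegetable/pulse/nut/specific-oil content (FV%) from ingredient
    lists. Provides descriptive and nonparametric comparison tools
    (median/IQR summaries, claim-prevalence tables, Kruskal-Wallis and
    Mann-Whitney tests with Bonferroni-adjusted significance) for comparing
    plant-based meat and dairy imitation products with their animal-based
    counterparts, and a calibrated synthetic generator of branded-food
    databases for end-to-end testing of the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    nortest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
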