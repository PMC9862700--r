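# Small in-code fixtures shared across test files.

make_ingredients <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) return(empty_ingredients())
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      name = r[[1]], eligibility_class = r[[2]], form = r[[3]],
      declared_pct = if (length(r) > 3) as.numeric(r[[4]]) else NA_real_
    )
  }))
}

fixture_products <- function(n = 6) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    product_record(
      product_id = sprintf("p%03d", i),
      name = paste("product", i),
      category = rep(c("cheese", "milk", "sausages"), length.out = n)[i],
      origin = if (i %% 2 == 0) "animal" else "plant",
      matrix = if (i %% 2 == 0) "not_applicable" else "soy",
      energy_kcal = 100 + i, protein_g = i, fat_g = 10 + i, sfa_g = i,
      carb_g = 2 * i, sugars_g = i, fiber_g = i / 2, salt_g = 0.1 * i,
      ingredients = make_ingredients(
        list("water", "other", "other_processed"),
        list("soy protein isolate", "pulse", "powder", 30)
      ),
      claims = if (i %% 2 == 1) c("protein") else character(),
      indicators = if (i %% 2 == 1) c("vegan_vegetarian") else character()
    )
  }))
}

tiny_spec <- function(n_plant = 30, n_animal = 30) {
  spec <- study_like_spec()
  spec <- spec[spec$category == "cheese", ]
  spec$n <- c(n_plant, n_animal)
  spec
}
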