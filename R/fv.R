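# FV% estimator: the fraction of product mass from fruits, vegetables,
# pulses, nuts and rapeseed/walnut/olive oils, estimated from the ordered
# ingredient list in two steps -- a cheap >= 40% screen on optimistic upper
# bounds, then a quantification only for products that pass it.

fv_eligible_classes <- c("fruit", "vegetable", "pulse", "nut", "eligible_oil")

#' Eligible fraction of an ingredient for FV% counting
#'
#' Form-based eligibility rules: fruits, vegetables, pulses and nuts count
#' in fresh/whole, juice or dried form; concentrates, powders, candied
#' preparations and flours never count; the eligible oils (rapeseed, walnut,
#' olive) count as oil; coconut (name-matched) counts only as fresh coconut
#' product, in no other form. All other ingredient classes count zero.
#'
#' @param ingredients Ingredient tibble (`name`, `eligibility_class`,
#'   `form`, `declared_pct`).
#' @return Numeric vector in `{0, 1}`, one element per ingredient.
#' @export
ingredient_eligible_fraction <- function(ingredients) {
  if (nrow(ingredients) == 0) return(numeric())
  cls <- ingredients$eligibility_class
  form <- ingredients$form
  is_coconut <- grepl("coconut", ingredients$name, ignore.case = TRUE)
  ok_class <- cls %in% fv_eligible_classes
  ok_form <- ifelse(
    cls == "eligible_oil",
    form %in% c("oil", "fresh_or_whole"),
    form %in% c("fresh_or_whole", "juice", "dried")
  )
  # coconut: fresh product only, regardless of how it is classed
  ok_form[is_coconut] <- form[is_coconut] == "fresh_or_whole"
  as.numeric(ok_class & ok_form)
}

# Per-ingredient mass bounds from the declaration order. A declared (QUID)
# percentage is its own bound. An undeclared entry at rank r cannot exceed
# 100/r (descending order), nor the smallest declared percentage above it,
# nor the mass left after all declared percentages. Lower bound is 0.
ingredient_bounds <- function(ingredients) {
  n <- nrow(ingredients)
  pct <- ingredients$declared_pct
  upper <- numeric(n)
  declared_total <- sum(pct, na.rm = TRUE)
  min_declared_above <- Inf
  for (r in seq_len(n)) {
    if (!is.na(pct[r])) {
      upper[r] <- pct[r]
      min_declared_above <- min(min_declared_above, pct[r])
    } else {
      upper[r] <- max(0, min(100 / r, min_declared_above, 100 - declared_total))
    }
  }
  tibble::tibble(upper = upper, lower = ifelse(is.na(pct), 0, pct))
}

#' Screen for the 40% minimum FV content
#'
#' First step of the FV% estimation: the optimistic upper bound of eligible
#' content (declared percentages where present, declaration-order bounds
#' otherwise) must reach at least 40% of product mass; otherwise the product
#' gets 0 FV points with no quantification.
#'
#' @inheritParams ingredient_eligible_fraction
#' @return `TRUE` if the upper bound reaches 40%.
#' @export
screen_min_content <- function(ingredients) {
  if (nrow(ingredients) == 0) return(FALSE)
  frac <- ingredient_eligible_fraction(ingredients)
  b <- ingredient_bounds(ingredients)
  sum(frac * b$upper) >= 40
}

#' Estimate FV% and FV points for one ingredient list
#'
#' Two-step estimate: if [screen_min_content()] fails, the result is 0 FV
#' points with no quantification. Otherwise the FV percentage is the sum of
#' each ingredient's eligible fraction times its estimated mass share --
#' the declared percentage where present, the midpoint of the
#' declaration-order bounds otherwise -- clipped to \[0, 100\], and points
#' follow the ladder 0 (<= 40), 1 (> 40), 2 (> 60), 5 (> 80).
#'
#' @inheritParams ingredient_eligible_fraction
#' @return One-row tibble: `passed_screen`, `fv_pct`, `fv_points`,
#'   `quantified` (`FALSE` when the screen failed and quantification was
#'   skipped).
#' @export
estimate_fv <- function(ingredients) {
  if (!screen_min_content(ingredients)) {
    return(tibble::tibble(
      passed_screen = FALSE, fv_pct = 0, fv_points = 0L, quantified = FALSE
    ))
  }
  frac <- ingredient_eligible_fraction(ingredients)
  b <- ingredient_bounds(ingredients)
  share <- ifelse(
    is.na(ingredients$declared_pct), (b$lower + b$upper) / 2,
    ingredients$declared_pct
  )
  fv_pct <- min(100, max(0, sum(frac * share)))
  tibble::tibble(
    passed_screen = TRUE,
    fv_pct = fv_pct,
    fv_points = fv_points_from_pct(fv_pct),
    quantified = TRUE
  )
}

#' Estimate FV results for every product in a table
#'
#' @param products A validated product tibble.
#' @return A tibble with `product_id` and the [estimate_fv()] columns.
#' @export
estimate_fv_products <- function(products) {
  res <- dplyr::bind_rows(lapply(products$ingredients, estimate_fv))
  dplyr::bind_cols(tibble::tibble(product_id = products$product_id), res)
}

#' Load the ingredient lexicon
#'
#' The lexicon maps free-text ingredient names to an eligibility class and
#' a default physical form via case-insensitive regular expressions (first
#' match wins). The packaged lexicon covers the common ingredients of
#' plant-based imitation products; it is a plain CSV
#' (`name_pattern,eligibility_class,form_default`) and can be replaced.
#'
#' @param path Lexicon CSV path; defaults to the packaged lexicon.
#' @return Tibble with `name_pattern`, `eligibility_class`, `form_default`.
#' @export
read_fv_lexicon <- function(path = system.file("extdata", "fv_lexicon.csv",
                                               package = "nutriprofiler")) {
  lex <- readr::read_csv(path, col_types = "ccc", progress = FALSE)
  stopifnot(all(c("name_pattern", "eligibility_class", "form_default") %in% names(lex)))
  lex
}

#' Classify raw ingredient names through the lexicon
#'
#' Fills `eligibility_class` and `form` for ingredient entries from their
#' free-text names. Unmatched names default to class `other`, form
#' `other_processed`. Existing declared percentages are preserved.
#'
#' @param names Character vector of ingredient names (declaration order).
#' @param declared_pct Optional numeric vector of QUID percentages.
#' @param lexicon Lexicon tibble from [read_fv_lexicon()].
#' @return Ingredient tibble ready for [estimate_fv()].
#' @export
classify_ingredients <- function(names, declared_pct = rep(NA_real_, length(names)),
                                 lexicon = read_fv_lexicon()) {
  cls <- rep("other", length(names))
  form <- rep("other_processed", length(names))
  for (i in seq_along(names)) {
    hit <- which(vapply(
      lexicon$name_pattern,
      function(p) grepl(p, names[i], ignore.case = TRUE),
      logical(1)
    ))
    if (length(hit) > 0) {
      cls[i] <- lexicon$eligibility_class[hit[1]]
      form[i] <- lexicon$form_default[hit[1]]
    }
  }
  tibble::tibble(
    name = names, eligibility_class = cls, form = form,
    declared_pct = declared_pct
  )
}
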