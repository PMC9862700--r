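# Product data model: enumerations, constructors, validation, and the
# missing-data (scoring eligibility) policy.

#' Closed enumerations of the product data model
#'
#' Category tokens follow the seven meat and dairy imitation categories
#' (lower-snake-case); the matrix is the main protein/fat ingredient base of
#' a plant-based product (`not_applicable` for animal-based products).
#' Claims and indicators are the on-pack nutrition claims and quality
#' indicators tabulated by the prevalence module.
#'
#' @name enumerations
#' @export
product_categories <- c(
  "cold_cuts", "sausages", "red_meat", "poultry", "milk", "yogurt", "cheese"
)

#' @rdname enumerations
#' @export
product_matrices <- c(
  "soy", "wheat", "pulse", "nut", "coconut", "grain", "vegetable_oil",
  "mixed", "other", "not_applicable"
)

#' @rdname enumerations
#' @export
claim_types <- c("protein", "sugar", "fat", "fiber", "vitamin", "minerals")

#' @rdname enumerations
#' @export
indicator_types <- c(
  "vegan_vegetarian", "meat_free", "dairy_free", "gluten_free", "soy_free",
  "bio_organic", "natural"
)

#' @rdname enumerations
#' @export
nutrient_fields <- c(
  "energy_kcal", "protein_g", "fat_g", "sfa_g", "carb_g", "sugars_g",
  "fiber_g", "salt_g"
)

# negative components whose absence excludes a product from scoring
negative_fields <- c("energy_kcal", "sfa_g", "sugars_g", "salt_g")

ingredient_classes <- c(
  "fruit", "vegetable", "pulse", "nut", "eligible_oil", "other"
)
ingredient_forms <- c(
  "fresh_or_whole", "juice", "concentrate", "powder", "candied", "flour",
  "dried", "oil", "other_processed"
)

#' Construct a product record tibble
#'
#' Builds one validated product row in the canonical layout used throughout
#' the package: identity and grouping columns, the eight nutrient
#' declarations per 100 g/mL (`NA` = not declared), and list-columns for the
#' ordered ingredient list, on-pack claims and quality indicators.
#'
#' @param product_id Opaque identifier.
#' @param name Free-text product name.
#' @param category One of [product_categories].
#' @param origin `"plant"` or `"animal"`.
#' @param matrix One of [product_matrices]; must be `"not_applicable"` iff
#'   `origin == "animal"`.
#' @param basis `"per_100g"` or `"per_100mL"`.
#' @param energy_kcal,protein_g,fat_g,sfa_g,carb_g,sugars_g,fiber_g,salt_g
#'   Declared composition (`NA` = absent from the label).
#' @param ingredients Tibble with columns `name`, `eligibility_class`,
#'   `form`, `declared_pct` in declaration order (descending content).
#' @param claims,indicators Character vectors of claim/indicator tokens.
#' @return A one-row tibble in canonical product layout.
#' @export
product_record <- function(product_id, name, category, origin,
                           matrix = if (origin == "animal") "not_applicable" else "other",
                           basis = "per_100g",
                           energy_kcal = NA_real_, protein_g = NA_real_,
                           fat_g = NA_real_, sfa_g = NA_real_,
                           carb_g = NA_real_, sugars_g = NA_real_,
                           fiber_g = NA_real_, salt_g = NA_real_,
                           ingredients = empty_ingredients(),
                           claims = character(), indicators = character()) {
  rec <- tibble::tibble(
    product_id = as.character(product_id),
    name = as.character(name),
    category = as.character(category),
    origin = as.character(origin),
    matrix = as.character(matrix),
    basis = as.character(basis),
    energy_kcal = as.numeric(energy_kcal),
    protein_g = as.numeric(protein_g),
    fat_g = as.numeric(fat_g),
    sfa_g = as.numeric(sfa_g),
    carb_g = as.numeric(carb_g),
    sugars_g = as.numeric(sugars_g),
    fiber_g = as.numeric(fiber_g),
    salt_g = as.numeric(salt_g),
    ingredients = list(ingredients),
    claims = list(as.character(claims)),
    indicators = list(as.character(indicators))
  )
  v <- validate_products(rec)
  if (nrow(v$rejects) > 0) {
    stop("invalid product record: ", v$rejects$reason[1], call. = FALSE)
  }
  rec
}

#' @rdname product_record
#' @export
empty_ingredients <- function() {
  tibble::tibble(
    name = character(),
    eligibility_class = character(),
    form = character(),
    declared_pct = numeric()
  )
}

#' Validate a product table
#'
#' Checks every row against the data-model invariants: closed category,
#' origin, matrix and basis enumerations; `matrix == "not_applicable"`
#' exactly for animal-based products; non-negative nutrient values with
#' `sfa_g <= fat_g` and `sugars_g <= carb_g` when both are present; valid
#' claim/indicator tokens; and well-formed ingredient lists (known class and
#' form tokens, declared percentages in \[0, 100\] summing to at most 100.5).
#'
#' Malformed rows are not dropped silently: they are collected into a
#' rejects report with the row number and the first failing reason.
#'
#' @param products A product tibble (canonical layout).
#' @return A list with `valid` (the passing rows) and `rejects` (tibble with
#'   `row`, `product_id`, `reason`).
#' @export
validate_products <- function(products) {
  stopifnot(is.data.frame(products))
  if (nrow(products) == 0) {
    return(list(valid = products, rejects = empty_rejects()))
  }
  reasons <- character(nrow(products))
  for (i in seq_len(nrow(products))) {
    reasons[i] <- row_problem(products[i, ])
  }
  bad <- reasons != ""
  rejects <- tibble::tibble(
    row = which(bad),
    product_id = as.character(products$product_id[bad]),
    reason = reasons[bad]
  )
  list(valid = products[!bad, , drop = FALSE], rejects = rejects)
}

empty_rejects <- function() {
  tibble::tibble(row = integer(), product_id = character(), reason = character())
}

row_problem <- function(rec) {
  if (!rec$category %in% product_categories) {
    return(paste0("unknown category token: '", rec$category, "'"))
  }
  if (!rec$origin %in% c("plant", "animal")) {
    return(paste0("unknown origin token: '", rec$origin, "'"))
  }
  if (!rec$matrix %in% product_matrices) {
    return(paste0("unknown matrix token: '", rec$matrix, "'"))
  }
  if ((rec$matrix == "not_applicable") != (rec$origin == "animal")) {
    return("matrix must be 'not_applicable' exactly for animal-based products")
  }
  if (!rec$basis %in% c("per_100g", "per_100mL")) {
    return(paste0("unknown basis token: '", rec$basis, "'"))
  }
  vals <- unlist(rec[nutrient_fields])
  if (any(vals < 0, na.rm = TRUE)) {
    return("negative nutrient value")
  }
  if (!is.na(rec$sfa_g) && !is.na(rec$fat_g) && rec$sfa_g > rec$fat_g) {
    return("sfa_g exceeds fat_g")
  }
  if (!is.na(rec$sugars_g) && !is.na(rec$carb_g) && rec$sugars_g > rec$carb_g) {
    return("sugars_g exceeds carb_g")
  }
  cl <- rec$claims[[1]]
  if (!all(cl %in% claim_types)) {
    return(paste0("unknown claim token: '", setdiff(cl, claim_types)[1], "'"))
  }
  ind <- rec$indicators[[1]]
  if (!all(ind %in% indicator_types)) {
    return(paste0("unknown indicator token: '", setdiff(ind, indicator_types)[1], "'"))
  }
  ing <- rec$ingredients[[1]]
  if (!is.data.frame(ing)) {
    return("ingredients must be a data frame")
  }
  if (nrow(ing) > 0) {
    if (!all(ing$eligibility_class %in% ingredient_classes)) {
      return("unknown ingredient eligibility class")
    }
    if (!all(ing$form %in% ingredient_forms)) {
      return("unknown ingredient form")
    }
    pct <- ing$declared_pct
    if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
      return("declared_pct outside [0, 100]")
    }
    if (sum(pct, na.rm = TRUE) > 100.5) {
      return("declared ingredient percentages sum above 100")
    }
    if (any(grepl("[|;]", ing$name))) {
      return("ingredient names must not contain '|' or ';'")
    }
  }
  ""
}

#' Scoring eligibility under the missing-data policy
#'
#' A product can be scored only if all four negative components (energy,
#' SFA, total sugars, salt/sodium) are declared; a product missing any of
#' them is excluded from scoring. Missing positive nutrients (fibre,
#' protein) do not exclude -- they are imputed as zero by the scoring
#' engine.
#'
#' @param products A validated product tibble.
#' @return A tibble with `product_id`, `eligible` (logical) and
#'   `missing_fields` (comma-separated negative fields absent, `""` when
#'   eligible).
#' @export
scoring_eligibility <- function(products) {
  miss <- vapply(seq_len(nrow(products)), function(i) {
    absent <- negative_fields[vapply(
      negative_fields, function(f) is.na(products[[f]][i]), logical(1)
    )]
    paste(absent, collapse = ",")
  }, character(1))
  tibble::tibble(
    product_id = products$product_id,
    eligible = miss == "",
    missing_fields = miss
  )
}
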