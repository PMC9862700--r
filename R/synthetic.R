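# Synthetic branded-food database generator. Emulates the statistical
# structure of a national branded-food database's meat/dairy imitation
# records: right-skewed, sometimes-zero nutrient declarations summarised as
# median (Q1, Q3), per-category main-ingredient (matrix) mixtures, on-pack
# claim/indicator prevalences, and label missingness.
#
# Nutrients are drawn from quantile fits to the printed quartiles
# (lognormal; zero-inflated lognormal where the printed Q1 or median is 0).
# The two ratio constraints SFA <= fat and sugars <= carbohydrate are
# enforced by quantile coupling: each pair shares one uniform draw, so both
# marginal medians are reproduced exactly while the constraint holds at
# every draw (a residual far-tail crossing is capped).

#' Fit a lognormal from a median and quartiles
#'
#' Quartile-matching fit: `mu = log(median)`,
#' `sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75))`. The fitted
#' distribution reproduces the median exactly; its quartiles match `q1`,
#' `q3` exactly when the median is the geometric midpoint of the two.
#'
#' @param median,q1,q3 Positive quartiles with `q1 <= median <= q3`.
#' @return List with `mu` and `sigma`.
#' @export
fit_lognormal_from_quartiles <- function(median, q1, q3) {
  stopifnot(q1 > 0, q1 <= median, median <= q3)
  list(mu = log(median), sigma = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

# General quartile fit, covering the zero-inflated and degenerate cases and
# the fallbacks for unusable printed cells:
#   * q3 missing: q3 = median + max(median - q1, median / 2, 0.05)
#   * q1 > median (corrupted cell): q1 = max(2 * median - q3, median / 2)
#   * median = q1 = q3 = 0: point mass at zero
#   * median = 0 < q3: zero mass 0.6, conditional lognormal through q3
#     (sigma fixed at 0.6)
#   * q1 = 0 < median: zero mass 0.3, conditional lognormal through the
#     median and q3
quartile_fit <- function(median, q1, q3) {
  if (is.na(median)) {
    return(list(type = "absent"))
  }
  if (is.na(q1)) q1 <- median
  if (q1 > median) q1 <- max(2 * median - q3, median / 2)
  if (is.na(q3)) q3 <- median + max(median - q1, median / 2, 0.05)
  if (median == 0 && q3 == 0) {
    return(list(type = "zero"))
  }
  if (median == 0) {
    p0 <- 0.6
    sigma <- 0.6
    mu <- log(q3) - sigma * stats::qnorm((0.75 - p0) / (1 - p0))
    return(list(type = "zi_lognormal", p0 = p0, mu = mu, sigma = sigma))
  }
  if (q1 == 0) {
    p0 <- 0.3
    z_med <- stats::qnorm((0.5 - p0) / (1 - p0))
    z_q3 <- stats::qnorm((0.75 - p0) / (1 - p0))
    sigma <- if (q3 > median) (log(q3) - log(median)) / (z_q3 - z_med) else 0
    mu <- log(median) - sigma * z_med
    return(list(type = "zi_lognormal", p0 = p0, mu = mu, sigma = sigma))
  }
  f <- fit_lognormal_from_quartiles(median, q1, q3)
  list(type = "lognormal", p0 = 0, mu = f$mu, sigma = f$sigma)
}

# Quantile function of a quartile_fit, vectorised over p in (0, 1).
q_quartile_fit <- function(fit, p) {
  switch(fit$type,
    absent = rep(NA_real_, length(p)),
    zero = rep(0, length(p)),
    {
      out <- numeric(length(p))
      pos <- p > fit$p0
      out[pos] <- exp(fit$mu + fit$sigma *
        stats::qnorm((p[pos] - fit$p0) / (1 - fit$p0)))
      out
    }
  )
}

#' Study-like database specification
#'
#' Packaged specification of a study-like database of meat and dairy
#' imitation products and their animal-based counterparts: 14 groups
#' (7 categories x plant/animal) with per-nutrient median (Q1, Q3) targets,
#' main-ingredient (matrix) mixtures for the plant groups, on-pack
#' claim/indicator prevalences, group sizes, and per-nutrient label
#' missingness rates. The calibration constants are transcribed in
#' `spec_constants()` below; [generate_products()] reproduces every target
#' median exactly in distribution.
#'
#' @param scale Multiplier on every group size (e.g. `scale = 100` for
#'   calibration checks at large n).
#' @return A tibble with one row per group: `category`, `origin`, `n`,
#'   `basis`, and list-columns `nutrients` (tibble: `nutrient`, `median`,
#'   `q1`, `q3`, `missing_rate`), `matrix_probs`, `claim_probs`,
#'   `indicator_probs` (named numeric vectors).
#' @export
study_like_spec <- function(scale = 1) {
  spec <- spec_constants()
  spec$n <- as.integer(round(spec$n * scale))
  spec
}

nutrient_targets <- function(...) {
  # rows of (nutrient, median, q1, q3); NA marks unusable/absent cells
  m <- matrix(c(...), ncol = 4, byrow = TRUE)
  miss_default <- c(
    energy_kcal = 0.02, protein_g = 0.01, fat_g = 0.01, sfa_g = 0.02,
    carb_g = 0.01, sugars_g = 0.02, fiber_g = 0.20, salt_g = 0.02
  )
  tibble::tibble(
    nutrient = nutrient_fields,
    median = as.numeric(m[, 2]),
    q1 = as.numeric(m[, 3]),
    q3 = as.numeric(m[, 4]),
    missing_rate = ifelse(is.na(as.numeric(m[, 2])), 1,
      unname(miss_default[nutrient_fields])
    )
  )
}

spec_constants <- function() {
  nt <- function(energy, protein, fat, sfa, carb, sugars, fiber, salt) {
    nutrient_targets(
      1, energy[1], energy[2], energy[3],
      2, protein[1], protein[2], protein[3],
      3, fat[1], fat[2], fat[3],
      4, sfa[1], sfa[2], sfa[3],
      5, carb[1], carb[2], carb[3],
      6, sugars[1], sugars[2], sugars[3],
      7, fiber[1], fiber[2], fiber[3],
      8, salt[1], salt[2], salt[3]
    )
  }
  no_claims <- stats::setNames(rep(0, length(claim_types)), claim_types)
  no_ind <- stats::setNames(rep(0, length(indicator_types)), indicator_types)
  claims <- function(...) {
    v <- no_claims
    args <- c(...)
    v[names(args)] <- args / 100
    v
  }
  inds <- function(...) {
    v <- no_ind
    args <- c(...)
    v[names(args)] <- args / 100
    v
  }
  mx <- function(...) {
    v <- c(...)
    v / sum(v)
  }
  animal_mx <- c(not_applicable = 1)

  g <- function(category, origin, n, basis, nutrients, matrix_probs,
                claim_probs, indicator_probs) {
    tibble::tibble(
      category = category, origin = origin, n = as.integer(n), basis = basis,
      nutrients = list(nutrients), matrix_probs = list(matrix_probs),
      claim_probs = list(claim_probs), indicator_probs = list(indicator_probs)
    )
  }

  dplyr::bind_rows(
    g("cold_cuts", "plant", 18, "per_100g",
      nt(c(221.5, 180.0, 248.3), c(27.3, 5.2, 32.2), c(12.2, 8.4, 16.0),
         c(1.8, 1.2, 3.6), c(5.4, 2.9, 6.5), c(1.7, 0.8, 2.4),
         c(4.4, 4.1, 5.0), c(2.1, 1.8, 2.6)),
      mx(soy = 1, wheat = 9, mixed = 8),
      claims(protein = 27.8, fiber = 11.1),
      inds(vegan_vegetarian = 88.9, meat_free = 66.7, dairy_free = 38.9,
           gluten_free = 16.7, soy_free = 11.1, bio_organic = 83.3,
           natural = 11.1)),
    g("cold_cuts", "animal", 66, "per_100g",
      nt(c(169.5, 101.5, 273.0), c(14.5, 12.7, 21.8), c(10.0, 2.3, 22.0),
         c(3.0, 0.8, 7.0), c(4.0, 1.2, 6.0), c(0.9, 0.0, 1.1),
         c(0.0, 0.0, 0.0), c(2.5, 2.2, 2.8)),
      animal_mx, no_claims, no_ind),
    g("sausages", "plant", 19, "per_100g",
      nt(c(247.0, 211.0, 269.0), c(25.2, 19.4, 30.6), c(12.5, 10.3, 15.0),
         c(1.3, 1.0, 7.4), c(4.2, 3.6, 5.6), c(0.6, 0.5, 2.0),
         c(3.2, 0.7, 4.5), c(1.5, 1.3, 1.8)),
      mx(soy = 3, wheat = 12, mixed = 4),
      claims(protein = 42.1, fiber = 10.5),
      inds(vegan_vegetarian = 94.7, meat_free = 78.9, dairy_free = 42.1,
           gluten_free = 21.1, soy_free = 5.3, bio_organic = 68.4,
           natural = 10.5)),
    g("sausages", "animal", 27, "per_100g",
      nt(c(247.0, 224.0, 300.5), c(13.5, 12.2, 15.0), c(20.1, 15.5, 25.5),
         c(7.5, 5.5, 9.8), c(2.8, 1.0, 5.9), c(0.9, 0.48, 1.2),
         c(1.5, 1.3, NA), c(2.3, 1.8, 2.5)),
      animal_mx, no_claims, no_ind),
    g("red_meat", "plant", 43, "per_100g",
      nt(c(231.0, 195.0, 252.0), c(17.6, 14.9, 24.0), c(12.5, 7.6, 15.2),
         c(1.8, 0.9, 7.9), c(7.0, 4.1, 10.5), c(1.1, 0.6, 2.0),
         c(4.1, 2.0, 5.7), c(1.3, 1.0, 1.8)),
      mx(soy = 9, wheat = 12, mixed = 22),
      claims(protein = 37.2, fat = 9.3, fiber = 18.6, vitamin = 11.6,
             minerals = 11.6),
      inds(vegan_vegetarian = 72.1, meat_free = 48.8, dairy_free = 11.6,
           gluten_free = 23.3, soy_free = 18.6, bio_organic = 23.3,
           natural = 27.9)),
    g("red_meat", "animal", 6, "per_100g",
      nt(c(213.0, 183.3, 234.3), c(12.9, 11.3, 18.5), c(15.6, 10.6, 17.0),
         c(6.7, 4.2, 8.2), c(6.7, 2.0, 8.1), c(1.1, 0.8, NA),
         c(NA, NA, NA), c(1.2, 1.2, 1.6)),
      animal_mx, no_claims, no_ind),
    g("poultry", "plant", 16, "per_100g",
      nt(c(219.5, 190.3, 247.3), c(12.2, 9.4, 14.0), c(8.0, 7.3, 12.0),
         c(1.0, 0.7, 3.0), c(15.9, 13.3, 20.0), c(1.4, 0.6, 2.6),
         c(4.7, 2.3, 6.1), c(1.3, 1.0, 1.6)),
      mx(soy = 8, wheat = 3, mixed = 5),
      claims(protein = 68.8, fat = 12.5, fiber = 37.5, vitamin = 25,
             minerals = 25),
      inds(vegan_vegetarian = 87.5, meat_free = 62.5, dairy_free = 12.5,
           gluten_free = 12.5, soy_free = 12.5, natural = 18.8)),
    g("poultry", "animal", 14, "per_100g",
      # the printed poultry carbohydrate Q1 is unusable (exceeds the
      # median); quartile_fit() falls back to a symmetric lower quartile
      nt(c(194.0, 189.5, 230.5), c(16.4, 12.8, 18.4), c(9.6, 9.0, 11.9),
         c(3.7, 3.0, 4.2), c(11.0, NA, 13.5), c(0.6, 0.5, 1.2),
         c(3.7, 0.4, NA), c(1.5, 1.3, 1.7)),
      animal_mx, no_claims, no_ind),
    g("milk", "plant", 221, "per_100mL",
      nt(c(46.0, 32.8, 57.0), c(0.7, 0.5, 1.2), c(1.6, 1.2, 2.2),
         c(0.2, 0.2, 0.4), c(5.7, 2.5, 9.0), c(3.4, 1.3, 6.0),
         c(0.6, 0.4, 1.1), c(0.1, 0.1, 0.1)),
      mx(nut = 36.2, grain = 34.1, coconut = 11.7, pulse = 14.2,
         mixed = 3.6),
      claims(protein = 10.4, sugar = 58.1, fat = 15.4, fiber = 10.8,
             vitamin = 17.4, minerals = 20.7),
      # the printed gluten-free and soy-free milk cells are arithmetically
      # inconsistent and are not reconstructed (prevalence 0 here)
      inds(vegan_vegetarian = 53.9, dairy_free = 29.9, bio_organic = 46.1,
           natural = 26.6)),
    g("milk", "animal", 119, "per_100mL",
      nt(c(63.0, 46.0, 65.0), c(3.3, 3.3, 3.5), c(1.6, 1.5, 3.5),
         c(1.1, 0.8, 2.2), c(4.7, 4.7, 5.1), c(4.7, 4.6, 5.1),
         c(0.4, 0.0, NA), c(0.1, 0.1, 0.1)),
      animal_mx, no_claims, no_ind),
    g("yogurt", "plant", 40, "per_100g",
      nt(c(80.0, 69.8, 97.5), c(2.1, 1.0, 3.8), c(2.3, 1.9, 4.7),
         c(0.4, 0.3, 0.7), c(11.8, 5.6, 15.0), c(8.5, 0.8, 11.0),
         c(1.0, 0.5, 1.4), c(0.1, 0.1, 0.1)),
      mx(pulse = 37.5, nut = 31.3, coconut = 16.7, grain = 14.6),
      claims(protein = 19.1, sugar = 21.3, fat = 10.6, vitamin = 14.9,
             minerals = 14.9),
      inds(vegan_vegetarian = 48.9, meat_free = 48.9, dairy_free = 21.3,
           gluten_free = 44.7, soy_free = 27.7, bio_organic = 25.5,
           natural = 23.4)),
    g("yogurt", "animal", 137, "per_100g",
      nt(c(78.0, 69.0, 97.0), c(6.2, 4.8, 8.2), c(2.0, 1.6, 4.4),
         c(1.3, 1.0, 2.7), c(5.2, 4.0, 8.7), c(5.1, 4.0, 8.7),
         c(0.0, 0.0, 0.8), c(0.1, 0.1, 0.2)),
      animal_mx, no_claims, no_ind),
    g("cheese", "plant", 80, "per_100g",
      nt(c(283.0, 248.0, 305.0), c(0.5, 0.0, 1.6), c(23.0, 20.0, 24.0),
         c(20.5, 15.8, 21.0), c(21.0, 11.5, 23.0), c(0.0, 0.0, 0.5),
         c(1.9, 0.5, 2.9), c(1.9, 1.7, 2.1)),
      mx(vegetable_oil = 66, pulse = 9, mixed = 3, nut = 2),
      no_claims,
      inds(vegan_vegetarian = 70.6, meat_free = 70.6, dairy_free = 72.9,
           soy_free = 54.1, bio_organic = 16.5, natural = 28.2)),
    g("cheese", "animal", 172, "per_100g",
      nt(c(302.5, 247.0, 361.0), c(23.0, 16.0, 26.0), c(24.0, 17.6, 29.0),
         c(16.0, 11.5, 20.0), c(0.5, 0.0, 1.9), c(0.3, 0.0, 1.0),
         c(0.0, 0.0, 0.0), c(1.8, 1.4, 2.2)),
      animal_mx, no_claims, no_ind)
  )
}

# Per-matrix ingredient templates. FV-ineligible by construction: the plant
# matrices enter as protein isolates, flours, non-fresh coconut
# preparations or non-eligible oils, mirroring how imitation products
# declare them -- which is why real products earn no FV points.
ingredient_template <- function(matrix) {
  ing <- function(name, cls, form, pct = NA_real_) {
    tibble::tibble(
      name = name, eligibility_class = cls, form = form, declared_pct = pct
    )
  }
  switch(matrix,
    soy = dplyr::bind_rows(
      ing("water", "other", "other_processed"),
      ing("soy protein isolate", "pulse", "powder", 30),
      ing("sunflower oil", "other", "oil"),
      ing("salt", "other", "other_processed")
    ),
    wheat = dplyr::bind_rows(
      ing("water", "other", "other_processed"),
      ing("wheat gluten", "other", "flour", 35),
      ing("wheat flour", "other", "flour"),
      ing("salt", "other", "other_processed")
    ),
    pulse = dplyr::bind_rows(
      ing("water", "other", "other_processed"),
      ing("pea protein", "pulse", "powder", 20),
      ing("starch", "other", "flour"),
      ing("salt", "other", "other_processed")
    ),
    nut = dplyr::bind_rows(
      ing("water", "other", "other_processed"),
      ing("almond", "nut", "fresh_or_whole", 2.3),
      ing("sugar", "other", "other_processed"),
      ing("salt", "other", "other_processed")
    ),
    coconut = dplyr::bind_rows(
      ing("water", "other", "other_processed"),
      ing("coconut milk", "fruit", "other_processed", 5),
      ing("sugar", "other", "other_processed")
    ),
    grain = dplyr::bind_rows(
      ing("water", "other", "other_processed"),
      ing("oat", "other", "other_processed", 10),
      ing("sunflower oil", "other", "oil")
    ),
    vegetable_oil = dplyr::bind_rows(
      ing("water", "other", "other_processed"),
      ing("coconut oil", "fruit", "oil", 23),
      ing("modified starch", "other", "flour", 20),
      ing("salt", "other", "other_processed")
    ),
    mixed = dplyr::bind_rows(
      ing("water", "other", "other_processed"),
      ing("wheat gluten", "other", "flour", 20),
      ing("pea protein", "pulse", "powder", 15),
      ing("sunflower oil", "other", "oil")
    ),
    empty_ingredients()
  )
}

#' Generate a synthetic product database
#'
#' Draws a product table from a database specification (see
#' [study_like_spec()]): per group, nutrient declarations from the quartile
#' fits (with quantile coupling enforcing SFA <= fat and sugars <=
#' carbohydrate), a matrix label from the group's mixture, Bernoulli claims
#' and indicators at the specified prevalences, per-nutrient label
#' missingness, and a per-matrix ingredient-list template. Deterministic
#' for a fixed seed.
#'
#' @param spec Specification tibble as returned by [study_like_spec()].
#' @param seed Integer RNG seed.
#' @param inject_eligible If `TRUE`, append a declared 45% whole-chickpea
#'   ingredient to every plant product, exercising the FV-positive path
#'   (real imitation products earn no FV points; this is a test hook).
#' @return A validated product tibble.
#' @export
generate_products <- function(spec = study_like_spec(), seed = 1,
                              inject_eligible = FALSE) {
  stopifnot(is.data.frame(spec), nrow(spec) > 0)
  set.seed(as.integer(seed))
  groups <- lapply(seq_len(nrow(spec)), function(i) {
    generate_group(spec[i, ], inject_eligible)
  })
  out <- dplyr::bind_rows(groups)
  v <- validate_products(out)
  if (nrow(v$rejects) > 0) {
    stop("generator produced invalid records: ", v$rejects$reason[1],
      call. = FALSE
    )
  }
  out
}

generate_group <- function(grp, inject_eligible = FALSE) {
  n <- grp$n
  if (n == 0) {
    return(product_record("x", "x", "milk", "plant", "grain")[0, ])
  }
  nut <- grp$nutrients[[1]]
  fits <- lapply(seq_len(nrow(nut)), function(i) {
    quartile_fit(nut$median[i], nut$q1[i], nut$q3[i])
  })
  names(fits) <- nut$nutrient

  # one uniform per nutrient, shared within the two ratio-coupled pairs
  u <- list()
  for (f in nutrient_fields) u[[f]] <- stats::runif(n)
  u$sfa_g <- u$fat_g
  u$sugars_g <- u$carb_g

  vals <- lapply(nutrient_fields, function(f) q_quartile_fit(fits[[f]], u[[f]]))
  names(vals) <- nutrient_fields
  vals$sfa_g <- pmin(vals$sfa_g, vals$fat_g) # far-tail crossing guard
  vals$sugars_g <- pmin(vals$sugars_g, vals$carb_g)
  # declarations are printed at one decimal on-pack; rounding is monotone,
  # so the ratio constraints survive it
  vals <- lapply(vals, round, digits = 1)

  # label missingness (missing completely at random, per nutrient)
  for (i in seq_len(nrow(nut))) {
    f <- nut$nutrient[i]
    drop <- stats::runif(n) < nut$missing_rate[i]
    vals[[f]][drop] <- NA_real_
  }

  mp <- grp$matrix_probs[[1]]
  matrix_lab <- sample(names(mp), n, replace = TRUE, prob = mp)
  cp <- grp$claim_probs[[1]]
  ip <- grp$indicator_probs[[1]]
  claim_draw <- matrix(
    stats::runif(n * length(cp)) < rep(cp, each = n), nrow = n
  )
  ind_draw <- matrix(
    stats::runif(n * length(ip)) < rep(ip, each = n), nrow = n
  )

  templates <- lapply(stats::setNames(nm = unique(matrix_lab)), function(m) {
    tmpl <- ingredient_template(m)
    if (inject_eligible && grp$origin == "plant") {
      tmpl <- dplyr::bind_rows(
        tibble::tibble(
          name = "chickpeas", eligibility_class = "pulse",
          form = "fresh_or_whole", declared_pct = 45
        ),
        tmpl
      )
    }
    tmpl
  })

  tibble::tibble(
    product_id = sprintf("%s_%s_%04d", grp$category, grp$origin, seq_len(n)),
    name = paste(grp$origin, matrix_lab, grp$category, seq_len(n)),
    category = grp$category,
    origin = grp$origin,
    matrix = matrix_lab,
    basis = grp$basis,
    energy_kcal = vals$energy_kcal,
    protein_g = vals$protein_g,
    fat_g = vals$fat_g,
    sfa_g = vals$sfa_g,
    carb_g = vals$carb_g,
    sugars_g = vals$sugars_g,
    fiber_g = vals$fiber_g,
    salt_g = vals$salt_g,
    ingredients = unname(templates[matrix_lab]),
    claims = lapply(seq_len(n), function(i) names(cp)[claim_draw[i, ]]),
    indicators = lapply(seq_len(n), function(i) names(ip)[ind_draw[i, ]])
  )
}

#' Read or write a database specification as YAML
#'
#' Round-trips the [study_like_spec()] tibble through a plain YAML file
#' (one block per group), so specifications can be edited outside R.
#'
#' @param spec Specification tibble.
#' @param path YAML file path.
#' @return `read_spec_yaml()` returns the specification tibble;
#'   `write_spec_yaml()` returns `path` invisibly.
#' @export
write_spec_yaml <- function(spec, path) {
  blocks <- lapply(seq_len(nrow(spec)), function(i) {
    grp <- spec[i, ]
    nut <- grp$nutrients[[1]]
    list(
      category = grp$category, origin = grp$origin, n = grp$n,
      basis = grp$basis,
      nutrients = stats::setNames(lapply(seq_len(nrow(nut)), function(j) {
        list(
          median = na_null(nut$median[j]), q1 = na_null(nut$q1[j]),
          q3 = na_null(nut$q3[j]), missing_rate = nut$missing_rate[j]
        )
      }), nut$nutrient),
      matrix_probs = as.list(grp$matrix_probs[[1]]),
      claim_probs = as.list(grp$claim_probs[[1]]),
      indicator_probs = as.list(grp$indicator_probs[[1]])
    )
  })
  yaml::write_yaml(blocks, path, precision = 15)
  invisible(path)
}

na_null <- function(x) if (is.na(x)) NULL else x

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  blocks <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(blocks, function(b) {
    nut_names <- names(b$nutrients)
    num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    tibble::tibble(
      category = b$category, origin = b$origin, n = as.integer(b$n),
      basis = b$basis,
      nutrients = list(tibble::tibble(
        nutrient = nut_names,
        median = vapply(b$nutrients, function(x) num_or_na(x$median), 1,
          USE.NAMES = FALSE),
        q1 = vapply(b$nutrients, function(x) num_or_na(x$q1), 1,
          USE.NAMES = FALSE),
        q3 = vapply(b$nutrients, function(x) num_or_na(x$q3), 1,
          USE.NAMES = FALSE),
        missing_rate = vapply(b$nutrients, function(x) x$missing_rate, 1,
          USE.NAMES = FALSE)
      )),
      matrix_probs = list(unlist(b$matrix_probs)),
      claim_probs = list(unlist(b$claim_probs)),
      indicator_probs = list(unlist(b$indicator_probs))
    )
  }))
}
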