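# FSAm-NPS scoring engine: component point ladders, the overall score and the
# Nutri-Score grade bands, including the conditional protein rule and the
# cheese exception.

#' Component point ladders of the FSAm-NPS model
#'
#' Threshold ladders of the (pre-2023) FSAm-NPS nutrient profiling model.
#' Negative components (energy in kJ, total sugars, saturated fatty acids,
#' sodium) are awarded 0--10 points; positive components (fibre, protein)
#' 0--5 points. A component's points equal the number of ladder thresholds
#' *strictly* exceeded by its value, so e.g. fibre at exactly 1.9 g scores
#' 1 point, not 2. The fibre ladder is the AOAC ladder.
#'
#' @format A named list of strictly increasing numeric vectors, one per
#'   component: `energy_kj`, `sugars_g`, `sfa_g`, `sodium_mg` (10 thresholds
#'   each), `fiber_g`, `protein_g` (5 thresholds each).
#' @export
nps_ladders <- list(
  energy_kj = c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350),
  sugars_g  = c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45),
  sfa_g     = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
  sodium_mg = c(90, 180, 270, 360, 450, 540, 630, 720, 810, 900),
  fiber_g   = c(0.9, 1.9, 2.8, 3.7, 4.7),
  protein_g = c(1.6, 3.2, 4.8, 6.4, 8.0)
)

#' FV% points ladder
#'
#' Points awarded for the fruit/vegetable/pulse/nut/specific-oil percentage:
#' 0 points for FV% <= 40, 1 for > 40, 2 for > 60 and 5 for > 80.
#'
#' @format Numeric thresholds (`fv_ladder`) and the matching point values
#'   (`fv_ladder_points`, one longer than the thresholds).
#' @export
fv_ladder <- c(40, 60, 80)

#' @rdname fv_ladder
#' @export
fv_ladder_points <- c(0L, 1L, 2L, 5L)

#' Unit conversions used before ladder lookup
#'
#' Nutrition declarations carry energy in kcal and salt in g; the scoring
#' model consumes energy in kJ and sodium in mg. `kcal_to_kj()` applies the
#' thermochemical factor 4.184 kJ/kcal; `salt_to_sodium()` applies the EU
#' labelling convention salt = 2.5 x sodium, i.e. 400 mg sodium per g salt.
#'
#' @param energy_kcal,salt_g Non-negative numeric vectors (`NA` allowed and
#'   propagated).
#' @return Numeric vector of the same length (kJ, respectively mg sodium).
#' @examples
#' kcal_to_kj(283)      # 1184.07
#' salt_to_sodium(1.9)  # 760
#' @export
kcal_to_kj <- function(energy_kcal) {
  stopifnot(is.numeric(energy_kcal))
  if (any(energy_kcal < 0, na.rm = TRUE)) {
    stop("energy_kcal must be non-negative", call. = FALSE)
  }
  energy_kcal * 4.184
}

#' @rdname kcal_to_kj
#' @export
salt_to_sodium <- function(salt_g) {
  stopifnot(is.numeric(salt_g))
  if (any(salt_g < 0, na.rm = TRUE)) {
    stop("salt_g must be non-negative", call. = FALSE)
  }
  salt_g * 400
}

#' Points for a single FSAm-NPS component
#'
#' Counts the ladder thresholds strictly exceeded by `value`, capped at the
#' ladder length. Vectorised over `value`.
#'
#' @param component One of `names(nps_ladders)`.
#' @param value Non-negative numeric vector, in the component's ladder units
#'   (kJ for energy, mg for sodium, g otherwise).
#' @param ladders Ladder list, defaulting to [nps_ladders]; override to swap
#'   e.g. the fibre ladder.
#' @return Integer vector of points (0--10 for negatives, 0--5 for positives).
#' @examples
#' component_points("sfa_g", 20.5)        # 10 (capped)
#' component_points("energy_kj", 1184.07) # 3
#' @export
component_points <- function(component, value, ladders = nps_ladders) {
  if (!component %in% names(ladders)) {
    stop("unknown component: ", component, call. = FALSE)
  }
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE)) {
    stop("component values must be non-negative", call. = FALSE)
  }
  ladder <- ladders[[component]]
  pts <- rowSums(outer(value, ladder, ">"))
  as.integer(pts)
}

#' Points for FV% content
#'
#' @param fv_pct Numeric vector of FV percentages in \[0, 100\].
#' @return Integer points in `{0, 1, 2, 5}`.
#' @export
fv_points_from_pct <- function(fv_pct) {
  stopifnot(is.numeric(fv_pct), all(fv_pct >= 0 & fv_pct <= 100, na.rm = TRUE))
  fv_ladder_points[1L + rowSums(outer(fv_pct, fv_ladder, ">"))]
}

#' Nutri-Score grade from an FSAm-NPS score
#'
#' Solid-food bands: A for scores -15..-1, B for 0..2, C for 3..10,
#' D for 11..18, E for 19..40. Plant-based beverages are graded on the same
#' bands (they are treated as solid foods throughout). Vectorised.
#'
#' @param score Integer vector of FSAm-NPS scores, each in -15..40.
#' @return Factor with levels `A` to `E`.
#' @examples
#' nutri_grade(c(-15, -1, 0, 2, 3, 10, 11, 18, 19, 40))
#' @export
nutri_grade <- function(score) {
  stopifnot(is.numeric(score))
  if (any(score < -15 | score > 40, na.rm = TRUE)) {
    stop("FSAm-NPS score out of range [-15, 40]", call. = FALSE)
  }
  cut(score,
    breaks = c(-15.5, -0.5, 2.5, 10.5, 18.5, 40.5),
    labels = c("A", "B", "C", "D", "E")
  )
}

#' Compute the FSAm-NPS score and Nutri-Score grade
#'
#' The negative sum is the points for energy, sugars, SFA and sodium
#' (0--40). Protein points are counted only when the negative sum is below
#' 11, or the product has 5 FV points, or the product is a cheese. The score
#' is the negative sum minus the applied positive sum (fibre + FV +
#' conditionally protein) and lies in -15..40. All arguments are vectorised
#' and recycled to a common length.
#'
#' Inputs are the label declaration per 100 g (or 100 mL -- beverages are
#' scored unchanged, as solid foods): energy in kcal and salt in g are
#' converted internally via [kcal_to_kj()] and [salt_to_sodium()]. Missing
#' (`NA`) fibre or protein is imputed as zero; missing values in any of the
#' four negative components are an error -- such products must be excluded
#' upstream (see [scoring_eligibility()]).
#'
#' @param energy_kcal,sugars_g,sfa_g,salt_g Negative-component declarations
#'   per 100 g/mL.
#' @param fiber_g,protein_g Positive-component declarations (`NA` -> 0).
#' @param fv_points FV points in `{0, 1, 2, 5}`, usually from [estimate_fv()].
#' @param category Product category token; `"cheese"` triggers the cheese
#'   rule (protein always counted).
#' @param ladders Ladder list, defaulting to [nps_ladders].
#' @return A tibble with one row per product: the seven component point
#'   columns, `negative_sum`, `protein_included`, `positive_sum_applied`,
#'   `score` and `grade`.
#' @examples
#' # median plant-based imitation cheese: scores 20, grade E
#' fsam_nps_score(283, 0, 20.5, 1.9, fiber_g = 1.9, protein_g = 0.5,
#'                fv_points = 0, category = "cheese")
#' @export
fsam_nps_score <- function(energy_kcal, sugars_g, sfa_g, salt_g,
                           fiber_g = 0, protein_g = 0, fv_points = 0L,
                           category = "other", ladders = nps_ladders) {
  n <- max(
    length(energy_kcal), length(sugars_g), length(sfa_g), length(salt_g),
    length(fiber_g), length(protein_g), length(fv_points), length(category)
  )
  energy_kcal <- rep_len(energy_kcal, n)
  sugars_g <- rep_len(sugars_g, n)
  sfa_g <- rep_len(sfa_g, n)
  salt_g <- rep_len(salt_g, n)
  fiber_g <- rep_len(fiber_g, n)
  protein_g <- rep_len(protein_g, n)
  fv_points <- rep_len(as.integer(fv_points), n)
  category <- rep_len(category, n)

  if (anyNA(energy_kcal) || anyNA(sugars_g) || anyNA(sfa_g) || anyNA(salt_g)) {
    stop(
      "missing negative-component value: product is ineligible for scoring ",
      "and must be excluded (see scoring_eligibility())",
      call. = FALSE
    )
  }
  if (!all(fv_points %in% fv_ladder_points)) {
    stop("fv_points must be one of 0, 1, 2, 5", call. = FALSE)
  }
  fiber_g[is.na(fiber_g)] <- 0
  protein_g[is.na(protein_g)] <- 0

  p_energy <- component_points("energy_kj", kcal_to_kj(energy_kcal), ladders)
  p_sugars <- component_points("sugars_g", sugars_g, ladders)
  p_sfa <- component_points("sfa_g", sfa_g, ladders)
  p_sodium <- component_points("sodium_mg", salt_to_sodium(salt_g), ladders)
  p_fiber <- component_points("fiber_g", fiber_g, ladders)
  p_protein <- component_points("protein_g", protein_g, ladders)

  negative_sum <- p_energy + p_sugars + p_sfa + p_sodium
  protein_included <- negative_sum < 11L | fv_points == 5L | category == "cheese"
  positive_sum <- p_fiber + fv_points + ifelse(protein_included, p_protein, 0L)
  score <- negative_sum - positive_sum

  tibble::tibble(
    points_energy = p_energy,
    points_sugars = p_sugars,
    points_sfa = p_sfa,
    points_sodium = p_sodium,
    points_fiber = p_fiber,
    points_protein = p_protein,
    points_fv = fv_points,
    negative_sum = as.integer(negative_sum),
    protein_included = protein_included,
    positive_sum_applied = as.integer(positive_sum),
    score = as.integer(score),
    grade = nutri_grade(score)
  )
}

#' Brute-force search of the attainable FSAm-NPS score range
#'
#' Enumerates nutrient profiles on a grid spanning every component ladder
#' (zero, just above each threshold, and beyond the cap), crossed with all
#' FV point levels, and scores each profile through [fsam_nps_score()] for a
#' non-cheese category. Returns the attained minimum and maximum score and
#' the number of profiles enumerated. The model's design range is -15..40;
#' this search verifies both bounds are attained by concrete profiles.
#'
#' @param ladders Ladder list, defaulting to [nps_ladders].
#' @return A list with `min`, `max` (integers) and `n_profiles`.
#' @export
score_range_search <- function(ladders = nps_ladders) {
  eps <- 1e-6
  grid_vals <- function(component) c(0, ladders[[component]] + eps)
  g <- expand.grid(
    energy_kj = grid_vals("energy_kj"),
    sugars_g = grid_vals("sugars_g"),
    sfa_g = grid_vals("sfa_g"),
    sodium_mg = grid_vals("sodium_mg"),
    fiber_g = grid_vals("fiber_g"),
    protein_g = grid_vals("protein_g"),
    fv_points = fv_ladder_points,
    KEEP.OUT.ATTRS = FALSE
  )
  res <- fsam_nps_score(
    energy_kcal = g$energy_kj / 4.184,
    sugars_g = g$sugars_g,
    sfa_g = g$sfa_g,
    salt_g = g$sodium_mg / 400,
    fiber_g = g$fiber_g,
    protein_g = g$protein_g,
    fv_points = g$fv_points,
    category = "red_meat"
  )
  list(
    min = min(res$score),
    max = max(res$score),
    n_profiles = nrow(g)
  )
}

#' Negative-sum threshold of the protein exception
#'
#' For a non-cheese product with fewer than 5 FV points, protein points are
#' counted only while the negative-component sum is below 11. This sweep
#' holds protein at its 5-point level and FV at 0, raises sugars one ladder
#' step at a time, and reports the smallest negative sum at which the
#' returned score excludes the protein points.
#'
#' @param ladders Ladder list, defaulting to [nps_ladders].
#' @return A list with `threshold` (integer negative sum) and `n_steps`.
#' @export
protein_exception_threshold <- function(ladders = nps_ladders) {
  eps <- 1e-6
  sugar_steps <- c(0, ladders$sugars_g + eps)
  res <- fsam_nps_score(
    energy_kcal = 0, sugars_g = sugar_steps, sfa_g = 0,
    salt_g = (ladders$sodium_mg[1] + eps) / 400, # 1 sodium point baseline
    fiber_g = 0, protein_g = ladders$protein_g[5] + eps, # 5 protein points
    fv_points = 0L, category = "red_meat"
  )
  dropped <- !res$protein_included
  if (!any(dropped)) {
    stop("protein points were never excluded over the sweep", call. = FALSE)
  }
  list(
    threshold = res$negative_sum[which(dropped)[1]],
    n_steps = length(sugar_steps)
  )
}
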