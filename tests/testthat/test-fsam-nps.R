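test_that("unit conversions follow the labelling conventions", {
  expect_equal(kcal_to_kj(0), 0)
  expect_equal(kcal_to_kj(283), 1184.072)
  expect_equal(kcal_to_kj(100), 418.4)
  expect_equal(salt_to_sodium(0), 0)
  expect_equal(salt_to_sodium(1.9), 760)
  expect_equal(salt_to_sodium(0.1), 40)
  expect_error(kcal_to_kj(-1), "non-negative")
  expect_error(salt_to_sodium(-0.5), "non-negative")
})

test_that("component points count thresholds strictly exceeded, capped", {
  expect_equal(component_points("sfa_g", 20.5), 10L)
  expect_equal(component_points("energy_kj", 1184.07), 3L)
  expect_equal(component_points("protein_g", 0), 0L)
  # boundary: a value exactly on a threshold does not earn the next point
  expect_equal(component_points("fiber_g", 1.9), 1L)
  expect_equal(component_points("sugars_g", c(4.5, 4.51)), c(0L, 1L))
  expect_error(component_points("unobtainium", 1), "unknown component")
})

test_that("median cheese compositions score as in the worked examples", {
  plant <- fsam_nps_score(
    energy_kcal = 283.0, sugars_g = 0.0, sfa_g = 20.5, salt_g = 1.9,
    fiber_g = 1.9, protein_g = 0.5, fv_points = 0L, category = "cheese"
  )
  expect_equal(plant$negative_sum, 21L)
  expect_true(plant$protein_included)
  expect_equal(plant$score, 20L)
  expect_equal(as.character(plant$grade), "E")

  animal <- fsam_nps_score(
    energy_kcal = 302.5, sugars_g = 0.3, sfa_g = 16.0, salt_g = 1.8,
    fiber_g = 0.0, protein_g = 23.0, fv_points = 0L, category = "cheese"
  )
  expect_equal(animal$score, 15L)
  expect_equal(as.character(animal$grade), "D")

  zero <- fsam_nps_score(0, 0, 0, 0, 0, 0, 0L, "milk")
  expect_equal(zero$score, 0L)
  expect_true(zero$protein_included) # negative sum 0 < 11
  expect_equal(as.character(zero$grade), "B")
})

test_that("both milk median compositions land in the B band", {
  plant <- fsam_nps_score(46.0, 3.4, 0.2, 0.1, 0.6, 0.7, 0L, "milk")
  animal <- fsam_nps_score(63.0, 4.7, 1.1, 0.1, 0.4, 3.3, 0L, "milk")
  expect_equal(plant$score, 0L)
  expect_equal(animal$score, 0L)
  expect_equal(as.character(plant$grade), "B")
  expect_equal(as.character(animal$grade), "B")
})

test_that("grade bands match the printed solid-food cut-offs", {
  scores <- c(-15, -1, 0, 2, 3, 10, 11, 18, 19, 40)
  expect_equal(
    as.character(nutri_grade(scores)),
    c("A", "A", "B", "B", "C", "C", "D", "D", "E", "E")
  )
  expect_error(nutri_grade(41), "out of range")
  expect_error(nutri_grade(-16), "out of range")
})

test_that("missing negative components are refused by the engine", {
  expect_error(
    fsam_nps_score(NA, 0, 0, 0, 0, 0, 0L, "milk"),
    "ineligible"
  )
  # missing positives are imputed as zero, not refused
  res <- fsam_nps_score(100, 1, 1, 0.1, NA, NA, 0L, "milk")
  expect_equal(res$points_fiber, 0L)
  expect_equal(res$points_protein, 0L)
})

test_that("protein exception: counted below negative sum 11, dropped at 11, \
cheese and FV=5 override", {
  # sugars sweep with protein worth 5 points and FV 0
  res <- protein_exception_threshold()
  expect_equal(res$threshold, 11L)

  # direct check around the boundary: negative sums 10 and 11
  at10 <- fsam_nps_score(0, 40.5, 0, 0.226, 0, 10, 0L, "red_meat") # 9+1
  at11 <- fsam_nps_score(0, 45.5, 0, 0.226, 0, 10, 0L, "red_meat") # 10+1
  expect_equal(at10$negative_sum, 10L)
  expect_true(at10$protein_included)
  expect_equal(at11$negative_sum, 11L)
  expect_false(at11$protein_included)

  # cheese rule: toggling the negative sum across 11 never drops protein
  cheese10 <- fsam_nps_score(0, 40.5, 0, 0.226, 0, 10, 0L, "cheese")
  cheese11 <- fsam_nps_score(0, 45.5, 0, 0.226, 0, 10, 0L, "cheese")
  expect_true(cheese10$protein_included)
  expect_true(cheese11$protein_included)

  # FV = 5 override for a non-cheese product above the threshold
  fv5 <- fsam_nps_score(0, 45.5, 0, 0.226, 0, 10, 5L, "red_meat")
  expect_true(fv5$protein_included)
})

test_that("brute-force search attains the design score range -15..40", {
  s <- score_range_search()
  expect_equal(s$min, -15L)
  expect_equal(s$max, 40L)
})

test_that("engine agrees with the independent linear-scan oracle", {
  set.seed(42)
  profiles <- random_profiles(1000)
  engine <- fsam_nps_score(
    profiles$energy_kcal, profiles$sugars_g, profiles$sfa_g, profiles$salt_g,
    profiles$fiber_g, profiles$protein_g, profiles$fv_points,
    profiles$category
  )
  reference <- vapply(seq_len(nrow(profiles)), function(i) {
    oracle_score(
      profiles$energy_kcal[i], profiles$sugars_g[i], profiles$sfa_g[i],
      profiles$salt_g[i], profiles$fiber_g[i], profiles$protein_g[i],
      profiles$fv_points[i], profiles$category[i]
    )
  }, integer(1))
  expect_equal(engine$score, reference)
  expect_equal(
    as.character(engine$grade),
    vapply(reference, oracle_grade, character(1))
  )
})

test_that("score is monotone: negatives never decrease it, positives never \
increase it, across the protein-inclusion discontinuity", {
  set.seed(7)
  n <- 1000
  base <- random_profiles(n)
  score_of <- function(p) {
    fsam_nps_score(
      p$energy_kcal, p$sugars_g, p$sfa_g, p$salt_g,
      p$fiber_g, p$protein_g, p$fv_points, p$category
    )$score
  }
  s0 <- score_of(base)
  for (field in c("energy_kcal", "sugars_g", "sfa_g", "salt_g")) {
    up <- base
    up[[field]] <- up[[field]] + runif(n, 0, up[[field]] + 1)
    expect_true(all(score_of(up) >= s0), info = field)
  }
  for (field in c("fiber_g", "protein_g")) {
    up <- base
    up[[field]] <- up[[field]] + runif(n, 0, up[[field]] + 1)
    expect_true(all(score_of(up) <= s0), info = field)
  }
  up <- base
  up$fv_points <- vapply(
    base$fv_points,
    function(f) c(`0` = 1L, `1` = 2L, `2` = 5L, `5` = 5L)[[as.character(f)]],
    integer(1)
  )
  expect_true(all(score_of(up) <= s0), info = "fv_points")
})

test_that("per-100mL profiles score identically to per-100g (solid rules)", {
  prof <- list(e = 55, su = 4.8, sf = 1.2, sa = 0.12, fi = 0.5, pr = 3.4)
  a <- fsam_nps_score(prof$e, prof$su, prof$sf, prof$sa, prof$fi, prof$pr,
    0L, "milk"
  )
  b <- fsam_nps_score(prof$e, prof$su, prof$sf, prof$sa, prof$fi, prof$pr,
    0L, "yogurt"
  )
  expect_equal(a$score, b$score) # category only matters through the cheese rule
  # scoring a product table ignores the basis column entirely
  p <- fixture_products(4)
  p$basis <- "per_100g"
  s1 <- score_products(p)$scored$score
  p$basis <- "per_100mL"
  s2 <- score_products(p)$scored$score
  expect_equal(s1, s2)
})
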