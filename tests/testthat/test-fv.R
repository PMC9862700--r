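test_that("form-based eligibility: fresh/juice count, processed forms do not, \
coconut only fresh", {
  ing <- make_ingredients(
    list("chickpeas", "pulse", "fresh_or_whole"),
    list("apple juice", "fruit", "juice"),
    list("apple juice concentrate", "fruit", "concentrate"),
    list("onion powder", "vegetable", "powder"),
    list("candied orange", "fruit", "candied"),
    list("chickpea flour", "pulse", "flour"),
    list("raisins", "fruit", "dried"),
    list("olive oil", "eligible_oil", "oil"),
    list("sunflower oil", "other", "oil"),
    list("coconut", "fruit", "fresh_or_whole"),
    list("coconut powder", "fruit", "powder"),
    list("coconut oil", "fruit", "oil"),
    list("water", "other", "other_processed")
  )
  expect_equal(
    ingredient_eligible_fraction(ing),
    c(1, 1, 0, 0, 0, 0, 1, 1, 0, 1, 0, 0, 0)
  )
})

test_that("40% screen boundary uses declared percentages inclusively", {
  at40 <- make_ingredients(list("peas", "pulse", "fresh_or_whole", 40))
  at39 <- make_ingredients(list("peas", "pulse", "fresh_or_whole", 39))
  split45 <- make_ingredients(
    list("peas", "pulse", "fresh_or_whole", 25),
    list("lentils", "pulse", "fresh_or_whole", 20)
  )
  expect_true(screen_min_content(at40))
  expect_false(screen_min_content(at39))
  expect_true(screen_min_content(split45))
  expect_false(screen_min_content(empty_ingredients()))
})

test_that("FV quantification follows the 0/1/2/5 ladder on summed content", {
  fv_of <- function(...) estimate_fv(make_ingredients(...))
  none <- fv_of(
    list("water", "other", "other_processed"),
    list("starch", "other", "flour", 30)
  )
  expect_false(none$passed_screen)
  expect_equal(none$fv_points, 0L)
  expect_false(none$quantified)

  expect_equal(fv_of(list("peas", "pulse", "fresh_or_whole", 85))$fv_points, 5L)
  expect_equal(
    fv_of(
      list("peas", "pulse", "fresh_or_whole", 30),
      list("lentils", "pulse", "fresh_or_whole", 15)
    )$fv_points, 1L
  )
  expect_equal(fv_of(list("peas", "pulse", "fresh_or_whole", 70))$fv_points, 2L)
  # exactly 40% passes the screen but earns no points (ladder needs > 40)
  at40 <- fv_of(list("peas", "pulse", "fresh_or_whole", 40))
  expect_true(at40$passed_screen)
  expect_equal(at40$fv_points, 0L)
})

test_that("undeclared percentages are bounded by declaration order", {
  # undeclared eligible first ingredient: optimistic bound 100% passes screen
  ing <- make_ingredients(
    list("chickpeas", "pulse", "fresh_or_whole"),
    list("water", "other", "other_processed")
  )
  expect_true(screen_min_content(ing))
  res <- estimate_fv(ing)
  expect_equal(res$fv_pct, 50) # midpoint of [0, 100]

  # rank bound: third undeclared ingredient cannot exceed 100/3
  ing3 <- make_ingredients(
    list("water", "other", "other_processed"),
    list("starch", "other", "flour"),
    list("chickpeas", "pulse", "fresh_or_whole")
  )
  expect_false(screen_min_content(ing3)) # upper bound 33.3 < 40

  # a declared percentage above caps everything below it
  capped <- make_ingredients(
    list("water", "other", "other_processed"),
    list("starch", "other", "flour", 10),
    list("chickpeas", "pulse", "fresh_or_whole")
  )
  expect_false(screen_min_content(capped)) # bound min(100/3, 10) = 10
})

test_that("fv points never decrease with declared content and never increase \
when a form degrades to an excluded one", {
  set.seed(11)
  for (rep in 1:200) {
    pct <- runif(2, 5, 48)
    ing <- make_ingredients(
      list("peas", "pulse", "fresh_or_whole", pct[1]),
      list("lentils", "pulse", "fresh_or_whole", pct[2]),
      list("water", "other", "other_processed")
    )
    base <- estimate_fv(ing)
    bumped <- ing
    bumped$declared_pct[1] <- min(100 - pct[2], pct[1] + runif(1, 0, 20))
    expect_gte(estimate_fv(bumped)$fv_points, base$fv_points)
    degraded <- ing
    degraded$form[sample(1:2, 1)] <-
      sample(c("powder", "concentrate", "candied", "flour"), 1)
    expect_lte(estimate_fv(degraded)$fv_points, base$fv_points)
    expect_true(base$fv_points %in% c(0L, 1L, 2L, 5L))
    if (base$fv_points > 0) expect_true(base$passed_screen)
  }
})

test_that("the packaged lexicon classifies common ingredient names", {
  lex <- read_fv_lexicon()
  ing <- classify_ingredients(
    c("Water", "Soy protein isolate", "Chickpeas", "Coconut oil",
      "Almonds", "Olive oil", "Wheat flour", "Secret ingredient X"),
    lexicon = lex
  )
  expect_equal(
    ing$eligibility_class,
    c("other", "pulse", "pulse", "fruit", "nut", "eligible_oil", "other",
      "other")
  )
  expect_equal(ing$form[2], "powder") # isolate never counts as FV
  expect_equal(ing$form[8], "other_processed") # unmatched default
  # coconut oil classes as fruit but its form keeps it ineligible
  expect_equal(ingredient_eligible_fraction(ing[4, ]), 0)
})

test_that("study-like products never earn FV points", {
  p <- generate_products(study_like_spec(), seed = 3)
  fv <- estimate_fv_products(p)
  expect_true(all(fv$fv_points == 0L))
  # the eligible-injection hook exercises the positive path
  p2 <- generate_products(tiny_spec(10, 0), seed = 3, inject_eligible = TRUE)
  fv2 <- estimate_fv_products(p2)
  expect_true(all(fv2$fv_points[p2$origin == "plant"] >= 1L))
})
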