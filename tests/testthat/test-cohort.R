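test_that("summaries use linear-interpolation quartiles with pairwise \
deletion", {
  d <- tibble::tibble(
    category = "milk", origin = "plant",
    energy_kcal = c(1, 2, 3, 4, 5),
    protein_g = c(10, NA, NA, NA, NA),
    fat_g = NA_real_, sfa_g = NA_real_, carb_g = NA_real_,
    sugars_g = NA_real_, fiber_g = NA_real_, salt_g = NA_real_
  )
  s <- summarize_products(d)
  e <- s[s$variable == "energy_kcal", ]
  expect_equal(c(e$median, e$q1, e$q3), c(3, 2, 4))
  p <- s[s$variable == "protein_g", ]
  expect_equal(p$n, 1L)
  expect_equal(p$median, 10) # single value: median = q1 = q3
  expect_equal(p$q1, 10)
  fat <- s[s$variable == "fat_g", ]
  expect_equal(fat$n, 0L) # never declared: absent cell
  expect_true(is.na(fat$median))
  expect_equal(nrow(summarize_products(d[0, ])), 0)
})

test_that("normality check flags uniform data and passes normal data", {
  set.seed(1)
  expect_equal(normality_check(runif(200))$result, "non_normal")
  set.seed(2)
  calls <- vapply(1:100, function(i) {
    normality_check(rnorm(200))$result
  }, character(1))
  expect_gte(mean(calls == "normal"), 0.9) # size calibration at alpha 0.05
  expect_equal(normality_check(rep(5, 10))$result, "non_normal") # degenerate
  expect_error(normality_check(c(1, 2)), "at least 3")
})

test_that("two separated groups give the exact enumeration p-value", {
  d <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  got <- compare_groups(d, "v", "g")
  expect_equal(got$test, "mann_whitney_u_exact")
  expect_equal(unname(got$statistic), 0)
  expect_equal(got$p_value, 0.1) # 2/20 arrangements as extreme
  expect_false(got$significant) # at adjusted alpha 1e-4
  expect_true(compare_groups(d, "v", "g", alpha_adjusted = 0.2)$significant)
})

test_that("identical groups compare with p = 1 under tie handling", {
  d <- tibble::tibble(v = rep(5, 4), g = rep(c("a", "b"), each = 2))
  got <- compare_groups(d, "v", "g")
  expect_equal(got$p_value, 1)
  expect_false(got$significant)
})

test_that("p-values are label-symmetric and k>2 dispatches Kruskal-Wallis", {
  set.seed(3)
  d <- tibble::tibble(
    v = rnorm(60),
    g = sample(c("a", "b"), 60, replace = TRUE)
  )
  p1 <- compare_groups(d, "v", "g")$p_value
  d$g <- ifelse(d$g == "a", "b", "a")
  expect_equal(compare_groups(d, "v", "g")$p_value, p1)

  d3 <- tibble::tibble(v = rnorm(60), g = rep(c("a", "b", "c"), 20))
  got <- compare_groups(d3, "v", "g")
  expect_equal(got$test, "kruskal_wallis")
  expect_equal(
    got$p_value,
    stats::kruskal.test(d3$v, factor(d3$g))$p.value
  )
  expect_error(compare_groups(d3[d3$g == "a", ], "v", "g"), ">= 2 groups")
})

test_that("exact Mann-Whitney p equals full enumeration for all sizes <= 6", {
  set.seed(9)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      vals <- sample(seq_len(50), n1 + n2) # distinct: tie-free
      d <- tibble::tibble(
        v = as.numeric(vals),
        g = rep(c("a", "b"), c(n1, n2))
      )
      got <- compare_groups(d, "v", "g")
      expect_equal(
        got$p_value,
        oracle_mwu_exact_p(d$v[d$g == "a"], d$v[d$g == "b"]),
        info = paste(n1, n2)
      )
    }
  }
})

test_that("claim and indicator prevalences count per category with explicit \
zero cells", {
  p <- dplyr::bind_rows(lapply(1:18, function(i) {
    product_record(
      product_id = paste0("cc", i), name = "x", category = "cold_cuts",
      origin = "plant", matrix = "wheat",
      claims = if (i <= 5) "protein" else character()
    )
  }))
  pr <- prevalence(p)
  protein <- pr[pr$item == "protein", ]
  expect_equal(protein$count, 5L)
  expect_equal(protein$pct, 100 * 5 / 18, tolerance = 1e-12)
  expect_true(all(pr$count <= pr$category_n))
  expect_true(all(pr$pct <= 100))
  fat <- pr[pr$item == "fat", ]
  expect_equal(fat$count, 0L) # zero cells emitted, not dropped
  expect_equal(nrow(prevalence(p[0, ])), 0)
})

test_that("grade distributions are exhaustive and sum to 100 percent", {
  scored <- tibble::tibble(
    category = "cheese", origin = "plant",
    score = c(-15L, 0L, 3L, 11L, 19L)
  )
  scored$grade <- nutri_grade(scored$score)
  gd <- grade_distribution(scored)
  expect_equal(gd$grade, c("A", "B", "C", "D", "E"))
  expect_equal(gd$pct, rep(20, 5))
  expect_equal(sum(gd$pct), 100)
  expect_equal(gd$score_median[1], 3)

  all_e <- tibble::tibble(
    category = "cheese", origin = "plant", score = rep(19L, 4)
  )
  all_e$grade <- nutri_grade(all_e$score)
  gd_e <- grade_distribution(all_e)
  expect_equal(gd_e$pct[gd_e$grade == "E"], 100)
  expect_equal(sum(gd_e$pct), 100)
})
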