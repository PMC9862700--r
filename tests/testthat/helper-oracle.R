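# Independent reference implementations, deliberately written as plain
# scalar linear scans so they share no code path with the package.

# Reference FSAm-NPS scorer for one product.
oracle_score <- function(energy_kcal, sugars_g, sfa_g, salt_g,
                         fiber_g, protein_g, fv_points, category) {
  scan <- function(value, thresholds) {
    pts <- 0L
    for (t in thresholds) {
      if (value > t) pts <- pts + 1L
    }
    pts
  }
  if (is.na(fiber_g)) fiber_g <- 0
  if (is.na(protein_g)) protein_g <- 0
  p_energy <- scan(energy_kcal * 4.184,
                   c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350))
  p_sugars <- scan(sugars_g, c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45))
  p_sfa <- scan(sfa_g, 1:10)
  p_sodium <- scan(salt_g * 400,
                   c(90, 180, 270, 360, 450, 540, 630, 720, 810, 900))
  p_fiber <- scan(fiber_g, c(0.9, 1.9, 2.8, 3.7, 4.7))
  p_protein <- scan(protein_g, c(1.6, 3.2, 4.8, 6.4, 8.0))
  neg <- p_energy + p_sugars + p_sfa + p_sodium
  include_protein <- (neg < 11) || (fv_points == 5) || (category == "cheese")
  pos <- p_fiber + fv_points + if (include_protein) p_protein else 0L
  neg - pos
}

oracle_grade <- function(score) {
  if (score <= -1) "A"
  else if (score <= 2) "B"
  else if (score <= 10) "C"
  else if (score <= 18) "D"
  else "E"
}

# Random nutrient profiles spanning all ladders (beyond the caps included).
random_profiles <- function(n) {
  tibble::tibble(
    energy_kcal = round(runif(n, 0, 900), 1),
    sugars_g = round(runif(n, 0, 55), 1),
    sfa_g = round(runif(n, 0, 13), 1),
    salt_g = round(runif(n, 0, 2.8), 2),
    fiber_g = round(runif(n, 0, 6), 1),
    protein_g = round(runif(n, 0, 10), 1),
    fv_points = sample(c(0L, 1L, 2L, 5L), n, replace = TRUE),
    category = sample(c("cheese", "milk", "red_meat", "yogurt"), n,
      replace = TRUE
    )
  )
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mwu_exact_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_stat <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) # tie-free by construction
  }
  u_obs <- u_stat(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_stat)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}
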