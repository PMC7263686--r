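test_that("marker_interval and meiosis_model validate their inputs", {
  iv <- marker_interval("X", 2, 1e6, 5.2e6)
  expect_equal(interval_length_mb(iv), 4.2)
  expect_error(marker_interval("X", 6, 1, 2), "1..5")
  expect_error(marker_interval("X", 1, 5, 5), "differ")
  expect_error(marker_interval("X", 1, 1e6, 2e6, pos_mid = 3e6), "strictly")
  expect_silent(marker_interval("X", 1, 2e6, 1e6, pos_mid = 1.5e6))
  expect_error(meiosis_model(-1, 0.1), ">= 0")
  expect_error(meiosis_model(0.1, 0.1, nu_m = 0.5), ">= 1")
  expect_error(meiosis_model(0.1, 0.1, age_effect_m = c(1, 1)), "per age")
  m <- make_model(0.2, 0.1, age_effect_m = c(1, 1.1, 1.2, 1.3))
  expect_equal(model_lambda(m, "male", 50), 0.2 * 1.2)
  expect_error(model_lambda(m, "neuter", 40), "male")
  expect_error(model_lambda(m, "male", 42), "configured ages")
})

test_that("crossover-count distribution is Poisson without interference", {
  m0 <- make_model(0, 0)
  expect_equal(crossover_count_distribution(m0, "male", 40),
               c(`0` = 1))
  m <- make_model(0.25, 0.25)
  d <- crossover_count_distribution(m, "male", 40)
  k <- as.numeric(names(d))
  expect_equal(unname(d[1]), exp(-0.25), tolerance = 1e-9)
  expect_equal(unname(d), dpois(k, 0.25) / sum(dpois(k, 0.25)),
               tolerance = 1e-12)
  expect_lt(abs(sum(k * d) - 0.25), 1e-6)
})

test_that("interference thins the upper tail at equal mean", {
  lam <- 0.25
  m5 <- make_model(lam, lam, nu_m = 5, nu_f = 5)
  d5 <- crossover_count_distribution(m5, "male", 40)
  k <- as.numeric(names(d5))
  expect_lt(abs(sum(k * d5) - lam), 1e-6)  # renewal mean is exact
  p_ge2 <- sum(d5[k >= 2])
  p_ge2_pois <- ppois(1, lam, lower.tail = FALSE)
  expect_lt(p_ge2, p_ge2_pois)
  # Monte-Carlo oracle for the gamma-renewal + thinning process
  sim <- sim_crossover_positions(1e6, lam, 5, seed = 41)
  set.seed(42)
  gam <- rbinom(1e6, sim$counts, 0.5)
  p_hat <- mean(gam >= 2)
  se <- sqrt(p_ge2 * (1 - p_ge2) / 1e6)
  expect_lt(abs(p_hat - p_ge2), 3 * se)
})

test_that("gamete class probabilities: sum, symmetry, limits", {
  m0 <- make_model(0, 0)
  expect_equal(gamete_class_probs(m0, "female", 40),
               c(p_both = 0.5, p_none = 0.5, p_r_only = 0, p_g_only = 0))
  big <- make_model(30, 30)
  expect_equal(unname(gamete_class_probs(big, "male", 40)),
               rep(0.25, 4), tolerance = 1e-9)
  # property: sum to 1 and coupling symmetry over random models
  set.seed(7)
  for (i in 1:25) {
    m <- make_model(runif(1, 0, 1.5), runif(1, 0, 1.5),
                    nu_m = sample(c(1, 2, 3.5, 5), 1),
                    nu_f = sample(c(1, 2, 3.5, 5), 1))
    for (sx in c("male", "female")) {
      p <- gamete_class_probs(m, sx, 40)
      expect_lt(abs(sum(p) - 1), 1e-12)
      expect_identical(p[["p_r_only"]], p[["p_g_only"]])
      expect_identical(p[["p_both"]], p[["p_none"]])
    }
  }
})

test_that("class probabilities agree with exact count-enumeration oracle", {
  # P(recombinant) must equal sum over odd gamete counts of the count pmf
  for (nu in c(1, 2.5)) {
    for (lam in c(0.05, 0.25, 0.6)) {
      m <- make_model(lam, lam, nu_m = nu, nu_f = nu)
      d <- crossover_count_distribution(m, "male", 40, tail = 1e-12)
      k <- as.numeric(names(d))
      p_odd <- sum(d[k %% 2 == 1])
      p <- gamete_class_probs(m, "male", 40)
      expect_lt(abs((p[["p_r_only"]] + p[["p_g_only"]]) - p_odd), 1e-9)
    }
  }
})

test_that("lambda_for_p_rec inverts the recombination probability", {
  for (nu in c(1, 4)) {
    lam <- lambda_for_p_rec(0.18, nu = nu)
    m <- make_model(lam, lam, nu_m = nu, nu_f = nu)
    p <- gamete_class_probs(m, "male", 40)
    expect_equal(unname(p[["p_r_only"]] + p[["p_g_only"]]), 0.18,
                 tolerance = 1e-7)
  }
})

test_that("simulate_cross: counts, determinism, degenerate model", {
  iv <- marker_interval("X", 1, 1e6, 5e6)
  m0 <- make_model(0, 0)
  cr <- simulate_cross(m0, iv, "female_detector", 40, 100, seed = 1)
  expect_identical(cr$n_r + cr$n_g, 0L)
  expect_identical(cr$n_rg + cr$n_nfs, 100L)
  m <- make_model(0.3, 0.2)
  a <- simulate_cross(m, iv, "male_detector", 45, 2200, seed = 99)
  b <- simulate_cross(m, iv, "male_detector", 45, 2200, seed = 99)
  expect_identical(a, b)
  expect_identical(sum(a$n_r, a$n_g, a$n_rg, a$n_nfs), 2200L)
  expect_error(simulate_cross(m, iv, "male_detector", 45, 0), ">= 1")
})

test_that("simulated RFs recover the generating recombinant probability", {
  p <- 0.2
  m <- make_model(lambda_for_p_rec(p), lambda_for_p_rec(p))
  des <- study_design("X", roles = "male_detector", ages = 40L,
                      replicates = 200L)
  st <- simulate_study(des, m, n_seeds = 2200L, seed = 5)
  rf <- add_rf(st$crosses)$rf / 100
  se <- sqrt(p * (1 - p) / (200 * 2200))
  expect_lt(abs(mean(rf) - p), 3 * se)
  expect_equal(unique(st$truth$p_recombinant), p, tolerance = 1e-12)
})

test_that("simulate_study: cardinality, determinism, duplicate design", {
  lines <- paste0("L", 1:8)
  des <- study_design(lines, replicates = 3L)
  expect_identical(nrow(des), 8L * 2L * 4L * 3L)
  m <- make_model(0.2, 0.1)
  st1 <- simulate_study(des, m, n_seeds = 50L, seed = 12)
  st2 <- simulate_study(des, m, n_seeds = 50L, seed = 12)
  expect_identical(st1$crosses, st2$crosses)
  expect_identical(nrow(st1$crosses), nrow(des))
  expect_error(simulate_study(rbind(des, des[1, ]), m, seed = 1),
               "duplicate design cells")
})

test_that("three-marker simulation is consistent with the two-marker readout", {
  iv <- marker_interval("X", 1, 1e6, 6e6, pos_mid = 3e6)
  m0 <- make_model(0, 0)
  r0 <- simulate_three_marker_cross(m0, iv, "male_detector", 40, 500, seed = 2)
  expect_identical(r0$joint$count[r0$joint$rec_sub1 | r0$joint$rec_sub2],
                   c(0L, 0L, 0L))
  expect_identical(r0$collapsed$n_r + r0$collapsed$n_g, 0L)

  lam <- 0.2
  m <- make_model(lam, lam)
  n <- 1e5
  r <- simulate_three_marker_cross(m, iv, "male_detector", 40, n, seed = 31)
  expect_identical(sum(r$classes$count), as.integer(n))
  expect_identical(sum(r$joint$count), as.integer(n))
  # collapse matches the exact multinomial class probabilities
  p <- gamete_class_probs(m, "male", 40)
  p_rec <- p[["p_r_only"]] + p[["p_g_only"]]
  obs_rec <- (r$collapsed$n_r + r$collapsed$n_g) / n
  expect_lt(abs(obs_rec - p_rec), 3 * sqrt(p_rec * (1 - p_rec) / n))
  # without interference the two sub-intervals recombine independently
  f <- (3e6 - 1e6) / (6e6 - 1e6)
  p1 <- -expm1(-2 * lam * f) / 2
  p2 <- -expm1(-2 * lam * (1 - f)) / 2
  p_rr <- p1 * p2
  obs_rr <- r$joint$count[r$joint$rec_sub1 & r$joint$rec_sub2] / n
  expect_lt(abs(obs_rr - p_rr), 3 * sqrt(p_rr * (1 - p_rr) / n))
  expect_error(
    simulate_three_marker_cross(m, marker_interval("X", 1, 1e6, 6e6),
                                "male_detector", 40, 10),
    "pos_mid")
})

test_that("recombinant probability never exceeds the gamete crossover mean", {
  # the shortfall is the invisible even->=2 crossover mass and grows with lambda
  lams <- seq(0.05, 1.5, by = 0.145)
  for (nu in c(1, 3)) {
    gaps <- vapply(lams, function(l) {
      m <- make_model(l, l, nu_m = nu, nu_f = nu)
      p <- gamete_class_probs(m, "male", 40)
      l - (p[["p_r_only"]] + p[["p_g_only"]])
    }, numeric(1))
    expect_true(all(gaps >= 0))
    expect_true(all(diff(gaps) > 0))
  }
})
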