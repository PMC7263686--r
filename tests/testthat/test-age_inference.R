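test_that("group-model fit equals hand-computed OLS", {
  fit <- fit_group_model(c(10, 12, 20, 22), c("a", "a", "b", "b"))
  expect_equal(unname(fit$means), c(11, 21), tolerance = 1e-10)
  expect_equal(fit$s2, 2)
  expect_identical(fit$dof, 2L)
  expect_false(fit$degenerate)
  expect_error(fit_group_model(1:3, c("a", "a", "a")), ">= 2 groups")
  expect_error(fit_group_model(1:2, c("a", "b")), "degree")
})

test_that("fitted group means equal arithmetic means exactly", {
  set.seed(9)
  for (i in 1:20) {
    g <- sample(letters[1:4], 30, replace = TRUE)
    while (length(unique(g)) < 4 || min(table(g)) < 2) {
      g <- sample(letters[1:4], 30, replace = TRUE)
    }
    y <- rnorm(30, mean = match(g, letters) * 3)
    fit <- fit_group_model(y, g)
    expect_equal(fit$means[sort(unique(g))],
                 vapply(split(y, g), mean, numeric(1))[sort(unique(g))],
                 tolerance = 1e-10)
  }
})

test_that("degenerate fits are flagged and contrasts refuse them", {
  fit <- fit_group_model(c(5, 5, 5, 5), c("a", "a", "b", "b"))
  expect_true(fit$degenerate)
  expect_error(pairwise_contrasts(fit), "zero")
})

test_that("pairwise contrasts match hand computation and are antisymmetric", {
  fit <- fit_group_model(c(10, 12, 20, 22), c("a", "a", "b", "b"))
  con <- pairwise_contrasts(fit)
  expect_equal(con$estimate, 10)
  expect_equal(con$std_error, sqrt(2), tolerance = 1e-12)
  expect_equal(con$t_statistic, 10 / sqrt(2), tolerance = 1e-12)
  expect_equal(con$p_raw, 2 * pt(-10 / sqrt(2), 2), tolerance = 1e-12)
  rev <- pairwise_contrasts(fit, tibble::tibble(group_a = "b", group_b = "a"))
  expect_equal(rev$estimate, -con$estimate)
  expect_identical(rev$p_raw, con$p_raw)
  expect_error(pairwise_contrasts(
    fit, tibble::tibble(group_a = "a", group_b = "zz")), "unknown group")
  # equal group means: zero estimate, p = 1
  fit0 <- fit_group_model(c(1, 3, 1, 3), c("a", "a", "b", "b"))
  con0 <- pairwise_contrasts(fit0)
  expect_equal(con0$estimate, 0)
  expect_equal(con0$p_raw, 1)
})

test_that("a family of one adjusts to its own raw p value", {
  fit <- fit_group_model(c(10, 12, 20, 22), c("a", "a", "b", "b"))
  con <- pairwise_contrasts(fit)
  adj <- single_step_adjust(con, fit, mc_draws = 1e6, seed = 8)
  expect_lt(abs(adj$p_adjusted - adj$p_raw), 1e-3)
})

test_that("independent contrasts approach the Sidak adjustment", {
  # three contrasts on disjoint group pairs; large dof so the joint t is
  # nearly joint normal, where the max-|t| tail factorises
  set.seed(15)
  g <- rep(letters[1:6], each = 50)
  y <- rnorm(300) + (g %in% c("b", "d", "f")) * 0.25
  fit <- fit_group_model(y, g)
  pairs <- tibble::tibble(group_a = c("a", "c", "e"),
                          group_b = c("b", "d", "f"))
  con <- pairwise_contrasts(fit, pairs)
  adj <- single_step_adjust(con, fit, mc_draws = 5e5, seed = 16)
  sidak <- 1 - (1 - con$p_raw)^3
  expect_equal(adj$p_adjusted, sidak, tolerance = 0.02)
})

test_that("adjusted p values dominate raw p and are monotone in |t|", {
  set.seed(23)
  y <- rnorm(12, rep(c(0, 0.5, 2, 0.1), each = 3))
  fit <- fit_group_model(y, rep(c("40", "45", "50", "55"), each = 3))
  adj <- single_step_adjust(pairwise_contrasts(fit), fit,
                            mc_draws = 5e4, seed = 2)
  expect_true(all(adj$p_adjusted >= adj$p_raw))
  ord <- order(abs(adj$t_statistic))
  expect_true(all(diff(adj$p_adjusted[ord]) <= 0))
  expect_true(all(adj$p_adjusted >= 0 & adj$p_adjusted <= 1))
})

test_that("single-step adjustment agrees with an established implementation", {
  skip_if_not_installed("multcomp")
  set.seed(31)
  d <- data.frame(g = factor(rep(c("40", "45", "50", "55"), each = 4)))
  d$y <- rnorm(16, mean = as.integer(d$g))
  fit <- fit_group_model(d$y, as.character(d$g))
  ours <- single_step_adjust(pairwise_contrasts(fit), fit,
                             mc_draws = 5e5, seed = 32)
  gl <- multcomp::glht(stats::lm(y ~ g, data = d),
                       linfct = multcomp::mcp(g = "Tukey"))
  ref <- summary(gl, test = multcomp::adjusted("single-step"))
  ref_p <- as.numeric(ref$test$pvalues)
  # multcomp orders Tukey contrasts the same way: 45-40, 50-40, ...
  expect_equal(ours$p_adjusted, ref_p, tolerance = 0.01)
})

test_that("a duplicated contrast adds nothing to the family", {
  fit <- fit_group_model(c(10, 12, 20, 22, 29, 33),
                         c("a", "a", "b", "b", "c", "c"))
  pairs <- tibble::tibble(group_a = c("a", "a"), group_b = c("b", "b"))
  con <- pairwise_contrasts(fit, pairs)
  adj <- single_step_adjust(con, fit, mc_draws = 1e5, seed = 3)
  # the max over two identical statistics is the statistic itself, so the
  # duplicate family adjusts like the single contrast
  expect_identical(adj$p_adjusted[1], adj$p_adjusted[2])
  single <- single_step_adjust(con[1, ], fit, mc_draws = 1e5, seed = 3)
  expect_lt(abs(adj$p_adjusted[1] - single$p_adjusted), 1e-3)
  expect_true(all(is.finite(adj$p_adjusted)))
})

test_that("run_age_analysis is deterministic and reports the full family", {
  m <- make_model(0.25, 0.14)
  st <- simulate_study(study_design("L", replicates = 3L), m,
                       n_seeds = 2200L, seed = 44)
  a1 <- run_age_analysis(st$crosses, role = "female_detector",
                         mc_draws = 2e4, seed = 9)
  a2 <- run_age_analysis(st$crosses, role = "female_detector",
                         mc_draws = 2e4, seed = 9)
  expect_identical(a1$contrasts, a2$contrasts)
  expect_identical(nrow(a1$contrasts), 6L)  # all age pairs for 4 ages
  expect_identical(a1$any_significant, any(a1$contrasts$significant))
  expect_error(run_age_analysis(st$crosses, role = "female_detector",
                                line = "nope"), "no records")
})

test_that("an injected female age effect is detectable at study scale", {
  # ~8% relative rise in fCO from youngest to oldest age
  m <- meiosis_model(lambda_m = 0.25, lambda_f = 0.16,
                     age_effect_f = c(1, 1.027, 1.053, 1.08))
  hits <- 0L
  for (s in 1:20) {
    st <- simulate_study(study_design("L", roles = "female_detector",
                                      replicates = 6L),
                         m, n_seeds = 2200L, seed = 100 + s)
    a <- run_age_analysis(st$crosses, role = "female_detector",
                          mc_draws = 2e4, seed = 200 + s)
    hits <- hits + a$any_significant
  }
  # power is positive but modest at this effect size; report-style bound
  expect_gte(hits, 1L)
})
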