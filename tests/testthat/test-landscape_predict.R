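toy_landscape <- function() {
  landscape_table(chromosome = c(1L, 1L, 1L, 1L),
                  pos = c(1e6, 2e6, 3e6, 6e6),
                  male_rate = c(2, 2, 4, 9),
                  female_rate = c(1, 1, 1, 9))
}

test_that("landscape_table validates ordering and sign", {
  expect_error(landscape_table(1L, c(2e6, 1e6), c(1, 1), c(1, 1)), "sorted")
  expect_error(landscape_table(1L, 1e6, -1, 1), ">= 0")
})

test_that("predict_interval reproduces hand-computed products", {
  ls <- toy_landscape()
  # constant male rate over the interval
  iv_const <- marker_interval("const", 1, 1e6, 2.5e6)  # picks rates {2, 2}
  pr <- predict_interval(ls, iv_const)
  expect_equal(pr$predicted_m, 2 * 1.5)
  expect_identical(pr$n_points_used, 2L)
  # rates {2,4} male, {1,1} female over a 5-Mb interval: 15, 5, ratio 3
  iv <- marker_interval("toy", 1, 1.5e6, 6.5e6)
  p2 <- predict_interval(ls, iv)
  expect_equal(p2$predicted_m, mean(c(2, 4, 9)) * 5)
  iv2 <- marker_interval("toy2", 1, 1.5e6, 5.5e6)  # only {2, 4} / {1, 1}
  p3 <- predict_interval(ls, iv2)
  expect_equal(p3$predicted_m, 3 * 4)
  expect_equal(p3$predicted_f, 1 * 4)
  expect_equal(p3$predicted_ratio, 3)
  # equal male and female columns: ratio 1 everywhere
  eq <- landscape_table(1L, c(1e6, 2e6), c(2, 4), c(2, 4))
  expect_equal(predict_interval(eq, iv_const)$predicted_ratio, 1)
  # no points inside: error naming the interval
  far <- marker_interval("nowhere", 1, 20e6, 22e6)
  expect_error(predict_interval(ls, far), "nowhere")
})

test_that("a point exactly at an interval endpoint is included", {
  ls <- toy_landscape()
  iv <- marker_interval("edge", 1, 2e6, 3e6)
  expect_identical(predict_interval(ls, iv)$n_points_used, 2L)
})

test_that("the predicted ratio is invariant to interval length units", {
  # two intervals sharing the same in-interval points but different lengths
  ls <- toy_landscape()
  short <- marker_interval("s", 1, 0.9e6, 3.1e6)
  long <- marker_interval("l", 1, 0.5e6, 5e6)
  ps <- predict_interval(ls, short)
  pl <- predict_interval(ls, long)
  expect_identical(ps$n_points_used, pl$n_points_used)
  expect_equal(ps$predicted_ratio, pl$predicted_ratio)
  expect_false(isTRUE(all.equal(ps$predicted_m, pl$predicted_m)))
})

test_that("trapezoid averaging weights uneven spacing", {
  ls <- toy_landscape()
  iv <- marker_interval("toy", 1, 1e6, 6e6)
  pt <- predict_interval(ls, iv, method = "point")
  tr <- predict_interval(ls, iv, method = "trapezoid")
  expect_equal(pt$predicted_m, mean(c(2, 2, 4, 9)) * 5)
  # piecewise-linear average: (2*1 + 3*1 + 6.5*3) / 5
  expect_equal(tr$predicted_m, (2 + 3 + 19.5) / 5 * 5)
  expect_false(isTRUE(all.equal(pt$predicted_m, tr$predicted_m)))
})

test_that("zone overlap fractions and centromere spanning", {
  zm <- zone_map(
    tibble::tibble(chromosome = c(1L, 1L),
                   zone = c("subtelomeric", "pericentromeric"),
                   start = c(1, 15e6), end = c(4e6, 25e6)),
    tibble::tibble(chromosome = 1L, pos = 17e6))
  disjoint <- marker_interval("d", 1, 5e6, 10e6)
  ov <- zone_overlap(disjoint, zm)
  expect_equal(ov$subtelomeric, 0)
  expect_equal(ov$pericentromeric, 0)
  expect_false(ov$spans_centromere)
  ident <- marker_interval("i", 1, 1, 4e6)
  expect_equal(zone_overlap(ident, zm)$subtelomeric, 1)
  half <- marker_interval("h", 1, 10e6, 20e6)
  oh <- zone_overlap(half, zm)
  expect_equal(oh$pericentromeric, 0.5)
  expect_true(oh$spans_centromere)
  other <- marker_interval("o", 2, 1e6, 2e6)
  expect_error(zone_overlap(other, zm), "chromosome 2")
  expect_error(zone_map(
    tibble::tibble(chromosome = 1L, zone = "telomere", start = 1, end = 2),
    tibble::tibble(chromosome = 1L, pos = 1)), "subtelomeric")
  expect_error(zone_map(
    tibble::tibble(chromosome = c(1L, 1L), zone = "subtelomeric",
                   start = c(1, 3e6), end = c(4e6, 6e6)),
    tibble::tibble(chromosome = 1L, pos = 1)), "overlapping")
})

test_that("zone fractions over exclusive zones sum to at most 1", {
  zm <- default_zone_map()
  for (iv in default_intervals()) {
    ov <- zone_overlap(iv, zm)
    expect_lte(ov$subtelomeric + ov$pericentromeric, 1 + 1e-12)
  }
  # the long interval is the one spanning a centromere
  spans <- vapply(default_intervals(),
                  function(iv) zone_overlap(iv, zm)$spans_centromere,
                  logical(1))
  expect_identical(unname(which(spans)), 1L)
  expect_identical(names(which(spans)), "CTL1.2")
})

test_that("estimated-vs-predicted concordance and rank correlation", {
  est <- tibble::tibble(line = paste0("L", 1:8), ratio = c(1:8) / 2)
  same <- tibble::tibble(line = est$line, predicted_ratio = est$ratio * 3)
  cmp <- compare_estimated_predicted(est, same)
  expect_equal(cmp$spearman, 1)
  rev <- tibble::tibble(line = est$line, predicted_ratio = rev(est$ratio))
  expect_equal(compare_estimated_predicted(est, rev)$spearman, -1)
  # known permutation vs a by-hand Spearman on 8 items
  set.seed(77)
  perm <- sample(8)
  pred <- tibble::tibble(line = est$line, predicted_ratio = perm / 2)
  cmp2 <- compare_estimated_predicted(est, pred)
  dsq <- sum((rank(est$ratio) - rank(pred$predicted_ratio))^2)
  expect_equal(cmp2$spearman, 1 - 6 * dsq / (8 * (8^2 - 1)))
  # unmatched lines are reported, not dropped silently
  extra <- rbind(pred, tibble::tibble(line = "L9", predicted_ratio = 1))
  expect_identical(compare_estimated_predicted(est[1:7, ], extra)$unmatched,
                   c("L8", "L9"))
})

test_that("subtelomeric male hotspots raise predicted ratios of overlapping intervals", {
  zm <- default_zone_map()
  ls <- synth_landscape(zm, seed = 97)
  ivs <- default_intervals()
  pred <- do.call(rbind, lapply(ivs, predict_interval, landscape = ls))
  sub <- vapply(ivs, function(iv) zone_overlap(iv, zm)$subtelomeric,
                numeric(1))
  no_sub <- pred$predicted_ratio[sub == 0]
  high_sub <- pred$predicted_ratio[sub > 0.3]
  expect_gt(length(no_sub), 0)
  expect_gt(length(high_sub), 0)
  expect_lt(max(no_sub), min(high_sub))
})
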