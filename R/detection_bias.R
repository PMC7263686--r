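# ---------------------------------------------------------------------------
# Two-marker non-detection: even crossover numbers between the markers leave
# a parental fluorescence pattern, so crossovers beyond the first can be
# missed. These tools quantify that bias and its effect on mCO:fCO.

#' Crossover-class counts per sex
#'
#' Counts (or proportions) of meioses/gametes carrying exactly 0, 1, 2 or 3+
#' crossovers in the region of interest, one row per sex.
#'
#' @param sex Character vector of `"male"` / `"female"`.
#' @param n0,n1,n2,n3plus Non-negative counts (or proportions) per class; the
#'   `3+` class is treated as exactly 3 crossovers downstream.
#' @return Tibble of class counts.
#' @export
co_class_counts <- function(sex, n0, n1, n2, n3plus) {
  x <- tibble::tibble(sex = sex, n0 = n0, n1 = n1, n2 = n2, n3plus = n3plus)
  if (!all(x$sex %in% c("male", "female"))) {
    stop("'sex' entries must be \"male\" or \"female\"", call. = FALSE)
  }
  num <- as.matrix(x[, c("n0", "n1", "n2", "n3plus")])
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("class counts must be non-negative", call. = FALSE)
  }
  if (any(rowSums(num) <= 0)) {
    stop("per-sex class totals must be > 0", call. = FALSE)
  }
  x
}

.detected_total <- function(row, f) {
  # crossovers beyond the first go undetected with probability f:
  # a meiosis with k >= 1 crossovers contributes 1 + (k - 1) * (1 - f)
  row$n1 * 1 + row$n2 * (1 + (2 - 1) * (1 - f)) +
    row$n3plus * (1 + (3 - 1) * (1 - f))
}

.true_total <- function(row) row$n1 + 2 * row$n2 + 3 * row$n3plus

#' Adjust the heterochiasmy ratio for two-marker non-detection
#'
#' Formalises the rule "each crossover additional to the initial one goes
#' undetected with probability f": the expected detected crossover total per
#' sex is sum over k >= 1 of n_k * (1 + (k - 1) * (1 - f)). The ratio of
#' male to female detected totals is compared with the ratio of true totals.
#'
#' @param classes A [co_class_counts()] tibble with one `"male"` and one
#'   `"female"` row.
#' @param f Non-detection level in \[0, 1\] (the study's reference evaluation
#'   uses f = 0.10).
#' @return One-row tibble: `f`, `detected_total_m`, `detected_total_f`,
#'   `ratio_raw`, `ratio_adjusted`, `ratio_change_pct`, `ratio_defined`.
#'   At f = 0 the adjusted ratio equals the raw ratio exactly.
#' @export
nondetection_adjust <- function(classes, f) {
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1) {
    stop("'f' must be a single value in [0, 1]", call. = FALSE)
  }
  m <- classes[classes$sex == "male", ]
  fe <- classes[classes$sex == "female", ]
  if (nrow(m) != 1L || nrow(fe) != 1L) {
    stop("'classes' must contain exactly one male and one female row",
         call. = FALSE)
  }
  det_m <- .detected_total(m, f)
  det_f <- .detected_total(fe, f)
  true_m <- .true_total(m)
  true_f <- .true_total(fe)
  defined <- true_f > 0 && det_f > 0
  ratio_raw <- if (true_f > 0) true_m / true_f else NA_real_
  ratio_adj <- if (det_f > 0) det_m / det_f else NA_real_
  change <- if (defined && ratio_raw > 0) {
    100 * (ratio_adj - ratio_raw) / ratio_raw
  } else NA_real_
  tibble::tibble(f = f, detected_total_m = det_m, detected_total_f = det_f,
                 ratio_raw = ratio_raw, ratio_adjusted = ratio_adj,
                 ratio_change_pct = change, ratio_defined = defined)
}

#' Sweep the non-detection level and track the ratio change
#'
#' Generalises the single-level evaluation to a grid of f values.
#'
#' @inheritParams nondetection_adjust
#' @param f_grid Numeric vector of non-detection levels in \[0, 1\].
#' @return Tibble with one [nondetection_adjust()] row per f.
#' @export
ratio_sensitivity_sweep <- function(classes, f_grid) {
  stopifnot(is.numeric(f_grid), length(f_grid) >= 1L)
  do.call(rbind, lapply(f_grid, function(f) nondetection_adjust(classes, f)))
}

#' Shortfall of RF-based estimation relative to the per-gamete crossover mean
#'
#' A gamete's recombinant status only reports the parity of its crossover
#' count, so RF/100 estimates P(odd count), not the mean count lambda. For a
#' short interval the two nearly coincide (P(odd) ~ lambda as lambda -> 0);
#' the fractional gap (lambda - P(odd)) / lambda grows with lambda -- the
#' even-count (>= 2) mass the two-marker readout cannot see.
#'
#' @inheritParams model_lambda
#' @return One-row tibble: `lambda` (per-gamete mean crossovers, age effect
#'   applied), `p_rec` (probability of a recombinant gamete), `gap`
#'   (fractional undercount; 0 when lambda is 0).
#' @export
odd_even_gap <- function(model, sex, age_das) {
  lam <- model_lambda(model, sex, age_das)
  probs <- gamete_class_probs(model, sex, age_das)
  p_rec <- unname(probs[["p_r_only"]] + probs[["p_g_only"]])
  gap <- if (lam > 0) (lam - p_rec) / lam else 0
  tibble::tibble(lambda = lam, p_rec = p_rec, gap = gap)
}

#' Fraction of double crossovers closer than a physical distance
#'
#' Among simulated meioses with exactly two crossovers in the interval,
#' estimates the fraction whose two positions lie within `distance_mb` of
#' each other. Under nu = 1 positions are independent uniforms and the
#' closed form is 2d/L - (d/L)^2; interference (nu > 1) pushes crossovers
#' apart and lowers the fraction.
#'
#' @inheritParams model_lambda
#' @param distance_mb Physical distance threshold (Mb); must not exceed the
#'   interval length.
#' @param interval A [marker_interval()] supplying the physical length.
#' @param n_meioses Meioses to simulate.
#' @param seed Optional integer seed.
#' @return One-row tibble: `fraction_within`, `std_error`, `n_double`
#'   (double-crossover meioses observed), `n_meioses`, `estimable`. With no
#'   double-crossover meioses in the sample the estimate is flagged
#'   inestimable (NA) and the sample size reported.
#' @export
double_co_within <- function(model, sex, distance_mb, interval,
                             n_meioses = 1e5, seed = NULL) {
  stopifnot(inherits(interval, "marker_interval"))
  len_mb <- interval_length_mb(interval)
  if (!is.numeric(distance_mb) || distance_mb < 0 || distance_mb > len_mb) {
    stop(sprintf("'distance_mb' must be in [0, %.2f] (the interval length)",
                 len_mb), call. = FALSE)
  }
  lam <- model$lambda[[.check_sex(sex)]]  # placement question; no age effect
  nu <- model_nu(model, sex)
  sim <- sim_crossover_positions(n_meioses, lam, nu, seed = seed)
  idx <- which(sim$counts == 2L)
  n2 <- length(idx)
  if (n2 == 0L) {
    return(tibble::tibble(fraction_within = NA_real_, std_error = NA_real_,
                          n_double = 0L, n_meioses = as.integer(n_meioses),
                          estimable = FALSE))
  }
  d <- abs(sim$positions[idx, 1L] - sim$positions[idx, 2L]) * len_mb
  p <- mean(d <= distance_mb)
  tibble::tibble(fraction_within = p,
                 std_error = sqrt(p * (1 - p) / n2),
                 n_double = n2, n_meioses = as.integer(n_meioses),
                 estimable = TRUE)
}
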