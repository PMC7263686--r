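# ---------------------------------------------------------------------------
# Age / sex effects on recombination frequency: Gaussian linear model with
# single-step max-|t| multivariate-t family-wise adjustment

#' Fit a one-way Gaussian model of replicate recombination frequencies
#'
#' Replicate-level RFs (which are close to normal at the seed numbers used
#' here) are modelled with a Gaussian identity-link linear model whose only
#' predictor is the grouping factor (parental age, or detector sex). With
#' one-hot coding the fitted group means are exactly the arithmetic group
#' means; the pooled residual variance and degrees of freedom drive the
#' contrast t statistics.
#'
#' @param values Numeric response (replicate RFs, percent).
#' @param groups Grouping labels, same length as `values`.
#' @return Object of class `rf_group_fit`: `labels`, `means`, `n` (per
#'   group), `s2` (pooled residual variance), `dof` (residual degrees of
#'   freedom), `degenerate` (TRUE when the residual variance is zero).
#' @examples
#' fit_group_model(c(10, 12, 20, 22), c("a", "a", "b", "b"))
#' @export
fit_group_model <- function(values, groups) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  groups <- as.character(groups)
  labels <- unique(groups)
  if (length(labels) < 2L) {
    stop("need >= 2 groups to fit a group model", call. = FALSE)
  }
  n <- vapply(labels, function(g) sum(groups == g), integer(1))
  if (any(n == 0L)) {
    stop("group(s) with zero observations: ",
         paste(labels[n == 0L], collapse = ", "), call. = FALSE)
  }
  dof <- length(values) - length(labels)
  if (dof < 1L) {
    stop("need >= 1 residual degree of freedom (", dof, " available)",
         call. = FALSE)
  }
  fit <- stats::lm(values ~ 0 + factor(groups, levels = labels))
  means <- stats::setNames(unname(stats::coef(fit)), labels)
  s2 <- sum(stats::residuals(fit)^2) / dof
  # constant-within-group responses leave numerically-zero residuals
  # (~ eps^2 scale), not exact zeros
  tol <- .Machine$double.eps^2 * max(1, mean(values^2))
  structure(list(labels = labels, means = means, n = n, s2 = s2,
                 dof = dof, degenerate = s2 <= tol),
            class = "rf_group_fit")
}

#' @export
print.rf_group_fit <- function(x, ...) {
  cat("<rf_group_fit>", length(x$labels), "groups; residual variance",
      format(x$s2, digits = 4), "on", x$dof, "df\n")
  print(round(x$means, 4))
  invisible(x)
}

.all_pairs <- function(labels) {
  cmb <- utils::combn(labels, 2L)
  tibble::tibble(group_a = cmb[1L, ], group_b = cmb[2L, ])
}

#' Pairwise group contrasts with unadjusted two-sided p values
#'
#' Each contrast is the difference of two fitted group means, with standard
#' error from the pooled residual variance and a two-sided p value from the
#' t distribution at the fit's residual degrees of freedom.
#'
#' @param fit An [fit_group_model()] result.
#' @param pairs Optional tibble with columns `group_a`, `group_b`; defaults
#'   to all pairwise comparisons.
#' @return Tibble: `contrast`, `group_a`, `group_b`, `estimate`
#'   (mean_b - mean_a), `std_error`, `t_statistic`, `p_raw`.
#' @export
pairwise_contrasts <- function(fit, pairs = NULL) {
  stopifnot(inherits(fit, "rf_group_fit"))
  if (fit$degenerate) {
    stop("residual variance is zero; contrast t statistics are undefined",
         call. = FALSE)
  }
  if (is.null(pairs)) pairs <- .all_pairs(fit$labels)
  bad <- setdiff(unique(c(pairs$group_a, pairs$group_b)), fit$labels)
  if (length(bad)) {
    stop("contrast references unknown group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  est <- fit$means[pairs$group_b] - fit$means[pairs$group_a]
  se <- sqrt(fit$s2 * (1 / fit$n[pairs$group_a] + 1 / fit$n[pairs$group_b]))
  tstat <- est / se
  tibble::tibble(contrast = paste(pairs$group_b, "-", pairs$group_a),
                 group_a = pairs$group_a, group_b = pairs$group_b,
                 estimate = unname(est), std_error = unname(se),
                 t_statistic = unname(tstat),
                 p_raw = unname(2 * stats::pt(-abs(tstat), df = fit$dof)))
}

#' Single-step max-|t| family-wise adjustment of contrast p values
#'
#' Adjusts each contrast's two-sided p value against the joint central
#' multivariate t distribution of all test statistics in the family:
#' p_adj_j = P(max_k |T_k| >= |t_j|), with the correlation structure implied
#' by the design and the fit's residual degrees of freedom. The joint tail
#' is evaluated by Monte Carlo: null group means are drawn directly in group
#' space (Z_g ~ N(0, 1/n_g)), contrast statistics share one chi-square
#' denominator per draw. Sampling in group space realises the exact joint
#' law even though the contrast correlation matrix itself is rank-deficient
#' whenever all pairwise contrasts of three or more groups are tested.
#' Adjusted p values are clamped to be >= the raw p and monotone in |t|.
#'
#' @param contrasts A [pairwise_contrasts()] tibble.
#' @param fit The [fit_group_model()] the contrasts came from.
#' @param mc_draws Monte Carlo sample size (default 1e5).
#' @param seed Optional integer seed for the Monte Carlo draw.
#' @return The contrast tibble with `p_adjusted` added.
#' @export
single_step_adjust <- function(contrasts, fit, mc_draws = 1e5, seed = NULL) {
  stopifnot(inherits(fit, "rf_group_fit"), nrow(contrasts) >= 1L)
  k <- nrow(contrasts)
  p_adj <- .with_seed(seed, {
    zg <- matrix(stats::rnorm(mc_draws * length(fit$labels)), mc_draws,
                 dimnames = list(NULL, fit$labels))
    zg <- sweep(zg, 2L, sqrt(1 / fit$n[fit$labels]), "*")
    mx <- NULL
    for (j in seq_len(k)) {
      a <- contrasts$group_a[j]
      b <- contrasts$group_b[j]
      tj <- abs(zg[, b] - zg[, a]) / sqrt(1 / fit$n[[a]] + 1 / fit$n[[b]])
      mx <- if (is.null(mx)) tj else pmax(mx, tj)
    }
    maxt <- mx / sqrt(stats::rchisq(mc_draws, df = fit$dof) / fit$dof)
    vapply(abs(contrasts$t_statistic), function(t0) mean(maxt >= t0),
           numeric(1))
  })
  # max over the family dominates each member; clamp MC noise accordingly,
  # then enforce monotonicity in |t|
  p_adj <- pmax(p_adj, contrasts$p_raw)
  ord <- order(abs(contrasts$t_statistic), decreasing = TRUE)
  p_adj[ord] <- cummax(p_adj[ord])
  out <- contrasts
  out$p_adjusted <- pmin(p_adj, 1)
  out
}

#' Full parental-age analysis for one line and detector role
#'
#' Computes replicate RFs per age, fits the one-way Gaussian model, forms all
#' pairwise age contrasts, applies the single-step family-wise adjustment,
#' and marks contrasts significant at `alpha`. The family is the set of
#' pairwise age comparisons within one line x role (6 contrasts for 4 ages).
#'
#' @param crosses Cross table (one line, or filtered by `line`).
#' @param line Line to analyse (default: the single line present).
#' @param role Detector role to analyse.
#' @param alpha Family-wise significance level (default 0.05).
#' @param mc_draws,seed Passed to [single_step_adjust()].
#' @return List of class `age_analysis`: `line`, `role`, `group_means`
#'   (per-age mean RFs), `contrasts` (tibble with `p_adjusted` and
#'   `significant`), `alpha`, `any_significant`.
#' @export
run_age_analysis <- function(crosses, line = NULL, role = "female_detector",
                             alpha = 0.05, mc_draws = 1e5, seed = NULL) {
  stopifnot(is.data.frame(crosses))
  if (is.null(line)) {
    line <- unique(crosses$line)
    if (length(line) != 1L) {
      stop("several lines present; pass 'line' explicitly", call. = FALSE)
    }
  }
  sub <- crosses[crosses$line == line & crosses$role == role, ]
  if (nrow(sub) == 0L) {
    stop(sprintf("no records for line %s, role %s", line, role),
         call. = FALSE)
  }
  if (length(unique(sub$age_das)) < 2L) {
    stop("need replicate RFs for >= 2 ages", call. = FALSE)
  }
  rf <- estimate_rf(sub$n_r, sub$n_g, sub$n_rg, sub$n_nfs)$value
  fit <- fit_group_model(rf, sub$age_das)
  con <- pairwise_contrasts(fit)
  con <- single_step_adjust(con, fit, mc_draws = mc_draws, seed = seed)
  con$significant <- con$p_adjusted < alpha
  structure(list(line = line, role = role, group_means = fit$means,
                 fit = fit, contrasts = con, alpha = alpha,
                 any_significant = any(con$significant)),
            class = "age_analysis")
}

#' @export
print.age_analysis <- function(x, ...) {
  cat(sprintf("<age_analysis> line %s, %s (alpha = %g)\n", x$line, x$role,
              x$alpha))
  print(round(x$group_means, 3))
  print(as.data.frame(x$contrasts[, c("contrast", "estimate", "t_statistic",
                                      "p_raw", "p_adjusted", "significant")]),
        digits = 4, row.names = FALSE)
  invisible(x)
}
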