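# ---------------------------------------------------------------------------
# Recombination-frequency estimation and heterochiasmy summaries

#' Recombination frequency from the four seed fluorescence classes
#'
#' RF = 100 * (R + G) / (R + G + RG + NFS): seeds fluorescing in only one
#' colour are the recombinants; double-fluorescent and non-fluorescent seeds
#' are parental. RF is a dimensionless estimator of relative crossover rate --
#' no map-distance (cM) conversion is applied.
#'
#' All four arguments are vectorised and recycled to a common length.
#'
#' @param n_r,n_g,n_rg,n_nfs Non-negative integer counts of dsRed-only,
#'   eGFP-only, double-fluorescent and non-fluorescent seeds.
#' @return Tibble with columns `value` (percent in \[0, 100\]), `n_total` and
#'   `n_recombinant`. A zero seed total is an error, not an RF of 0.
#' @examples
#' estimate_rf(110, 110, 990, 990)  # 10%
#' @export
estimate_rf <- function(n_r, n_g, n_rg, n_nfs) {
  k <- cbind(n_r = n_r, n_g = n_g, n_rg = n_rg, n_nfs = n_nfs)
  if (any(!is.finite(k)) || any(k < 0) || any(k != floor(k))) {
    stop("seed counts must be non-negative integers", call. = FALSE)
  }
  n_total <- rowSums(k)
  if (any(n_total == 0)) {
    stop("seed total is zero for row(s) ",
         paste(which(n_total == 0), collapse = ", "),
         "; RF is undefined there", call. = FALSE)
  }
  n_rec <- k[, "n_r"] + k[, "n_g"]
  tibble::tibble(value = unname(100 * n_rec / n_total),
                 n_total = as.integer(unname(n_total)),
                 n_recombinant = as.integer(unname(n_rec)))
}

#' Append a recombination-frequency column to a cross table
#'
#' @param crosses Cross table with columns `n_r`, `n_g`, `n_rg`, `n_nfs`.
#' @return The input tibble with `rf`, `n_total`, `n_recombinant` added.
#' @export
add_rf <- function(crosses) {
  rf <- estimate_rf(crosses$n_r, crosses$n_g, crosses$n_rg, crosses$n_nfs)
  out <- tibble::as_tibble(crosses)
  out$rf <- rf$value
  out$n_total <- rf$n_total
  out$n_recombinant <- rf$n_recombinant
  out
}

.aggregate_rf <- function(rows, aggregation) {
  if (aggregation == "seed_weighted") {
    100 * sum(rows$n_r + rows$n_g) / sum(rows$n_r + rows$n_g +
                                           rows$n_rg + rows$n_nfs)
  } else {
    mean(estimate_rf(rows$n_r, rows$n_g, rows$n_rg, rows$n_nfs)$value)
  }
}

#' Summarise one line's male and female crossover rates and their ratio
#'
#' Aggregates replicate RFs into mCO (male-detector crosses) and fCO
#' (female-detector crosses) and forms the heterochiasmy ratio mCO:fCO.
#' Two ratio conventions are provided because published per-line ratios are
#' not all consistent with a single one: `"ratio_of_means"` (default) divides
#' the aggregated rates; `"mean_of_ratios"` averages per-age ratios. The
#' convention and aggregation used are echoed in the output.
#'
#' @param crosses Cross table for a single line (columns `line`, `role`,
#'   `age_das`, `replicate`, and the four seed-class counts).
#' @param ratio_convention `"ratio_of_means"` or `"mean_of_ratios"`.
#' @param aggregation `"replicate_mean"` (unweighted mean of per-replicate
#'   RFs; matches a replicate-level linear model) or `"seed_weighted"`
#'   (pooled counts).
#' @return One-row tibble: `line`, `mCO`, `fCO`, `ratio`, `ratio_defined`,
#'   `convention`, `aggregation`. `ratio` is NA (flagged undefined) when
#'   fCO is 0.
#' @examples
#' # a line whose aggregate rates are 33.44% (male) and 28.24% (female)
#' tab <- tibble::tibble(
#'   line = "demo", role = c("male_detector", "female_detector"),
#'   age_das = 40L, replicate = 1L,
#'   n_r = c(1672L, 1412L), n_g = c(1672L, 1412L),
#'   n_rg = c(3328L, 3588L), n_nfs = c(3328L, 3588L))
#' summarize_line(tab)
#' @export
summarize_line <- function(crosses,
                           ratio_convention = c("ratio_of_means",
                                                "mean_of_ratios"),
                           aggregation = c("replicate_mean", "seed_weighted")) {
  ratio_convention <- match.arg(ratio_convention)
  aggregation <- match.arg(aggregation)
  stopifnot(is.data.frame(crosses), nrow(crosses) >= 1L)
  line <- unique(crosses$line)
  if (length(line) != 1L) {
    stop("summarize_line() expects records from a single line; got: ",
         paste(line, collapse = ", "), call. = FALSE)
  }
  for (role in c("male_detector", "female_detector")) {
    if (!any(crosses$role == role)) {
      stop(sprintf("no records with role \"%s\" for line %s", role, line),
           call. = FALSE)
    }
  }
  mco <- .aggregate_rf(crosses[crosses$role == "male_detector", ], aggregation)
  fco <- .aggregate_rf(crosses[crosses$role == "female_detector", ],
                       aggregation)
  if (ratio_convention == "ratio_of_means") {
    ratio <- if (fco > 0) mco / fco else NA_real_
  } else {
    per_age <- per_age_ratios(crosses, ages = sort(unique(crosses$age_das)),
                              strict = FALSE, aggregation = aggregation)
    ratio <- mean(per_age$ratio[!is.na(per_age$ratio)])
    if (!is.finite(ratio)) ratio <- NA_real_
  }
  tibble::tibble(line = line, mCO = mco, fCO = fco, ratio = ratio,
                 ratio_defined = !is.na(ratio),
                 convention = ratio_convention, aggregation = aggregation)
}

#' Per-age male and female rates and ratios for one line
#'
#' One row per age with the aggregated mCO, fCO and their ratio -- the
#' per-age-bracket breakdown used when testing for a parental-age effect.
#' Missing line x role x age cells are reported as explicit NA rows (strict =
#' FALSE) or are an error (strict = TRUE); they are never silently dropped.
#'
#' @inheritParams summarize_line
#' @param ages Ages expected in the design; defaults to the ages present in
#'   the data.
#' @param strict Require every age x role cell to be present.
#' @return Tibble: `line`, `age_das`, `mCO`, `fCO`, `ratio`, `complete`.
#' @export
per_age_ratios <- function(crosses, ages = NULL, strict = TRUE,
                           aggregation = c("replicate_mean", "seed_weighted")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.data.frame(crosses), nrow(crosses) >= 1L)
  line <- unique(crosses$line)
  if (length(line) != 1L) {
    stop("per_age_ratios() expects records from a single line", call. = FALSE)
  }
  if (is.null(ages)) ages <- sort(unique(crosses$age_das))
  rows <- lapply(ages, function(a) {
    m_rows <- crosses[crosses$role == "male_detector" &
                        crosses$age_das == a, ]
    f_rows <- crosses[crosses$role == "female_detector" &
                        crosses$age_das == a, ]
    complete <- nrow(m_rows) > 0 && nrow(f_rows) > 0
    if (!complete && strict) {
      stop(sprintf("line %s, age %d: missing %s records", line, a,
                   if (nrow(m_rows) == 0) "male_detector"
                   else "female_detector"), call. = FALSE)
    }
    mco <- if (nrow(m_rows)) .aggregate_rf(m_rows, aggregation) else NA_real_
    fco <- if (nrow(f_rows)) .aggregate_rf(f_rows, aggregation) else NA_real_
    ratio <- if (complete && fco > 0) mco / fco else NA_real_
    tibble::tibble(line = line, age_das = as.integer(a), mCO = mco, fCO = fco,
                   ratio = ratio, complete = complete)
  })
  do.call(rbind, rows)
}

#' Summarise every line in a cross table
#'
#' @inheritParams summarize_line
#' @param crosses Cross table possibly spanning several lines.
#' @return Tibble with one [summarize_line()] row per line.
#' @export
summarize_study <- function(crosses,
                            ratio_convention = c("ratio_of_means",
                                                 "mean_of_ratios"),
                            aggregation = c("replicate_mean",
                                            "seed_weighted")) {
  ratio_convention <- match.arg(ratio_convention)
  aggregation <- match.arg(aggregation)
  rows <- lapply(split(tibble::as_tibble(crosses), crosses$line),
                 summarize_line, ratio_convention = ratio_convention,
                 aggregation = aggregation)
  out <- do.call(rbind, rows)
  out[order(out$line), ]
}
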