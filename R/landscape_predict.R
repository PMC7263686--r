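# ---------------------------------------------------------------------------
# Interval-level prediction from location-based sex-specific crossover-rate
# landscapes, and overlap with subtelomeric / pericentromeric zones.

#' Assemble a location-based crossover-rate landscape
#'
#' @param chromosome Integer chromosome per point.
#' @param pos Physical position (bp), sorted within chromosome.
#' @param male_rate,female_rate Local crossover rates (cM/Mb-like units),
#'   >= 0.
#' @return Tibble of class-checked landscape points.
#' @export
landscape_table <- function(chromosome, pos, male_rate, female_rate) {
  x <- tibble::tibble(chromosome = as.integer(chromosome), pos = pos,
                      male_rate = male_rate, female_rate = female_rate)
  if (any(x$male_rate < 0) || any(x$female_rate < 0)) {
    stop("landscape rates must be >= 0", call. = FALSE)
  }
  for (ch in unique(x$chromosome)) {
    if (is.unsorted(x$pos[x$chromosome == ch])) {
      stop("positions must be sorted within chromosome ", ch, call. = FALSE)
    }
  }
  x
}

#' Build a zone map of subtelomeric / pericentromeric ranges
#'
#' @param zones Tibble with columns `chromosome`, `zone`
#'   (`"subtelomeric"` or `"pericentromeric"`), `start`, `end` (bp, closed
#'   ranges); ranges of the same class must not overlap within a chromosome.
#' @param centromeres Tibble with columns `chromosome`, `pos` (bp).
#' @return List of class `zone_map`.
#' @export
zone_map <- function(zones, centromeres) {
  stopifnot(is.data.frame(zones), is.data.frame(centromeres))
  if (!all(zones$zone %in% c("subtelomeric", "pericentromeric"))) {
    stop("zone classes must be \"subtelomeric\" or \"pericentromeric\"",
         call. = FALSE)
  }
  if (any(zones$end < zones$start)) {
    stop("zone ranges must have end >= start", call. = FALSE)
  }
  for (ch in unique(zones$chromosome)) {
    for (cl in unique(zones$zone)) {
      z <- zones[zones$chromosome == ch & zones$zone == cl, ]
      if (nrow(z) > 1L) {
        z <- z[order(z$start), ]
        if (any(z$start[-1L] <= z$end[-nrow(z)])) {
          stop(sprintf("overlapping %s ranges on chromosome %s", cl, ch),
               call. = FALSE)
        }
      }
    }
  }
  structure(list(zones = tibble::as_tibble(zones),
                 centromeres = tibble::as_tibble(centromeres)),
            class = "zone_map")
}

#' Predict interval-level sex-specific rates from a landscape
#'
#' The predicted rate per sex is the average of the landscape's local rates
#' at the points falling inside the interval (closed: points exactly at a
#' marker position are included), multiplied by the interval length in Mb.
#' Lengths cancel in the male:female ratio, so the ratio is invariant to
#' length units. `method = "trapezoid"` replaces the unweighted point average
#' with a length-weighted trapezoidal average over the in-interval points, an
#' alternative for unevenly spaced landscapes.
#'
#' @param landscape A [landscape_table()].
#' @param interval A [marker_interval()].
#' @param method `"point"` (unweighted average; default) or `"trapezoid"`.
#' @return One-row tibble: `line`, `predicted_m`, `predicted_f`,
#'   `predicted_ratio`, `n_points_used`, `method`. An interval containing no
#'   landscape point is an error naming the interval (no extrapolation).
#' @export
predict_interval <- function(landscape, interval,
                             method = c("point", "trapezoid")) {
  method <- match.arg(method)
  stopifnot(inherits(interval, "marker_interval"))
  lo <- min(interval$pos_egfp, interval$pos_dsred)
  hi <- max(interval$pos_egfp, interval$pos_dsred)
  pts <- landscape[landscape$chromosome == interval$chromosome &
                     landscape$pos >= lo & landscape$pos <= hi, ]
  if (nrow(pts) == 0L) {
    stop(sprintf("no landscape points inside interval %s (chr%d %.0f-%.0f)",
                 interval$line_name, interval$chromosome, lo, hi),
         call. = FALSE)
  }
  len_mb <- interval_length_mb(interval)
  if (method == "point" || nrow(pts) == 1L) {
    avg_m <- mean(pts$male_rate)
    avg_f <- mean(pts$female_rate)
  } else {
    x <- pts$pos
    w <- diff(x)
    trap <- function(y) sum(w * (y[-1L] + y[-length(y)]) / 2) / sum(w)
    avg_m <- trap(pts$male_rate)
    avg_f <- trap(pts$female_rate)
  }
  tibble::tibble(line = interval$line_name,
                 predicted_m = avg_m * len_mb,
                 predicted_f = avg_f * len_mb,
                 predicted_ratio = if (avg_f > 0) avg_m / avg_f else NA_real_,
                 n_points_used = nrow(pts), method = method)
}

#' Overlap of an interval with subtelomeric and pericentromeric zones
#'
#' Overlaps are computed on closed physical ranges and reported as fractions
#' of the interval length; an interval is flagged as spanning the centromere
#' when the centromere position lies inside it.
#'
#' @param interval A [marker_interval()].
#' @param zones A [zone_map()].
#' @return One-row tibble: `line`, `subtelomeric`, `pericentromeric`
#'   (overlap fractions in \[0, 1\]), `spans_centromere`.
#' @export
zone_overlap <- function(interval, zones) {
  stopifnot(inherits(interval, "marker_interval"), inherits(zones, "zone_map"))
  lo <- min(interval$pos_egfp, interval$pos_dsred)
  hi <- max(interval$pos_egfp, interval$pos_dsred)
  known <- union(zones$zones$chromosome, zones$centromeres$chromosome)
  if (!interval$chromosome %in% known) {
    stop(sprintf("zone map has no entries for chromosome %d",
                 interval$chromosome), call. = FALSE)
  }
  z <- zones$zones[zones$zones$chromosome == interval$chromosome, ]
  frac <- function(class) {
    r <- z[z$zone == class, ]
    if (nrow(r) == 0L) return(0)
    ov <- pmax(0, pmin(hi, r$end) - pmax(lo, r$start))
    sum(ov) / (hi - lo)
  }
  cen <- zones$centromeres[zones$centromeres$chromosome ==
                             interval$chromosome, ]
  spans <- nrow(cen) > 0L && any(cen$pos > lo & cen$pos < hi)
  tibble::tibble(line = interval$line_name,
                 subtelomeric = frac("subtelomeric"),
                 pericentromeric = frac("pericentromeric"),
                 spans_centromere = spans)
}

#' Compare estimated and landscape-predicted heterochiasmy ratios
#'
#' Pairs per-line estimated summaries with landscape predictions and reports
#' a Spearman rank correlation between the two ratio columns -- descriptive
#' concordance, with no threshold applied.
#'
#' @param summaries Tibble with columns `line` and `ratio` (e.g. from
#'   [summarize_study()]).
#' @param predictions Tibble with columns `line` and `predicted_ratio` (rows
#'   from [predict_interval()]).
#' @return List: `table` (paired tibble), `spearman` (rank correlation of the
#'   ratios), `unmatched` (line names present on only one side; never
#'   silently dropped).
#' @export
compare_estimated_predicted <- function(summaries, predictions) {
  stopifnot(is.data.frame(summaries), is.data.frame(predictions))
  unmatched <- union(setdiff(summaries$line, predictions$line),
                     setdiff(predictions$line, summaries$line))
  common <- intersect(summaries$line, predictions$line)
  if (length(common) < 2L) {
    stop("need >= 2 matched lines to compare", call. = FALSE)
  }
  tab <- tibble::tibble(
    line = common,
    estimated_ratio = summaries$ratio[match(common, summaries$line)],
    predicted_ratio = predictions$predicted_ratio[match(common,
                                                        predictions$line)])
  rho <- stats::cor(tab$estimated_ratio, tab$predicted_ratio,
                    method = "spearman")
  list(table = tab, spearman = rho, unmatched = unmatched)
}
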