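# ---------------------------------------------------------------------------
# Synthetic default study configuration. Marker positions and zone boundaries
# are illustrative stand-ins (the real assay's physical coordinates are not
# bundled): they respect the study geometry -- one long interval spanning the
# chromosome-1 centromere (10.5 Mb), seven shorter intervals of 4.71 Mb, and
# the published association between subtelomeric overlap and high mCO:fCO --
# but must not be read as the lines' true insertion sites.

# Approximate A. thaliana chromosome lengths and centromere midpoints (Mb).
.CHR_MB <- c(`1` = 30.43, `2` = 19.70, `3` = 23.46, `4` = 18.59, `5` = 26.98)
.CEN_MB <- c(`1` = 15.10, `2` = 3.60, `3` = 13.80, `4` = 4.00, `5` = 11.20)

#' Synthetic default marker intervals for the eight detector lines
#'
#' Eight two-marker intervals covering all five chromosomes: one long
#' interval (CTL1.2, 10.5 Mb, spanning the chromosome-1 centromere) and seven
#' of 4.71 Mb. Coordinates are synthetic placeholders chosen so that the
#' three lines with low heterochiasmy ratios (CTL1.2, CTL2.4, 3162) have no
#' subtelomeric overlap under [default_zone_map()], while the high-ratio
#' lines do.
#'
#' @return Named list of [marker_interval()] objects.
#' @export
default_intervals <- function() {
  mk <- function(line, chr, a_mb, b_mb) {
    marker_interval(line, chr, a_mb * 1e6, b_mb * 1e6)
  }
  list(
    CTL1.2 = mk("CTL1.2", 1, 10.00, 20.50),
    CTL1.18 = mk("CTL1.18", 1, 25.50, 30.21),
    CTL2.4 = mk("CTL2.4", 2, 6.50, 11.21),
    `Col3-4/20` = mk("Col3-4/20", 3, 0.80, 5.51),
    `3158` = mk("3158", 3, 18.60, 23.31),
    CTL4.7 = mk("CTL4.7", 4, 13.70, 18.41),
    `3162` = mk("3162", 5, 6.00, 10.71),
    CTL5.17 = mk("CTL5.17", 5, 22.10, 26.81)
  )
}

#' Synthetic default zone map
#'
#' Placeholder subtelomeric (outer 4 Mb of each chromosome arm) and
#' pericentromeric (centromere +/- 2.5 Mb) ranges with approximate centromere
#' midpoints. Real studies should supply their own boundaries; these defaults
#' exist so the pipeline runs end to end and the zone-overlap logic is
#' exercised.
#'
#' @param subtel_mb Width of each subtelomeric zone (Mb).
#' @param pericen_mb Half-width of each pericentromeric zone (Mb).
#' @return A [zone_map()].
#' @export
default_zone_map <- function(subtel_mb = 4, pericen_mb = 2.5) {
  rows <- lapply(1:5, function(ch) {
    len <- .CHR_MB[[as.character(ch)]] * 1e6
    cen <- .CEN_MB[[as.character(ch)]] * 1e6
    tibble::tibble(
      chromosome = ch,
      zone = c("subtelomeric", "subtelomeric", "pericentromeric"),
      start = c(1, len - subtel_mb * 1e6, max(1, cen - pericen_mb * 1e6)),
      end = c(subtel_mb * 1e6, len, min(len, cen + pericen_mb * 1e6)))
  })
  cens <- tibble::tibble(chromosome = 1:5,
                         pos = unname(.CEN_MB[as.character(1:5)]) * 1e6)
  zone_map(do.call(rbind, rows), cens)
}

# Target per-gamete recombinant probabilities per line (male, female), on the
# 16-34% / 5-28% RF scale typical of seed-based FTL assays of these lines.
.DEFAULT_P_REC <- list(
  CTL1.2 = c(m = 0.3344, f = 0.2824),
  CTL1.18 = c(m = 0.1795, f = 0.0781),
  CTL2.4 = c(m = 0.1784, f = 0.1341),
  `Col3-4/20` = c(m = 0.2404, f = 0.0890),
  `3158` = c(m = 0.2566, f = 0.1088),
  CTL4.7 = c(m = 0.2317, f = 0.0867),
  `3162` = c(m = 0.1933, f = 0.1473),
  CTL5.17 = c(m = 0.1662, f = 0.0521)
)

#' Default per-line meiosis models
#'
#' One [meiosis_model()] per detector line, with lambda calibrated (by
#' inverting the gamete recombination probability at the given interference
#' shape) so that expected RFs sit at the scale observed for these lines, and
#' no age effect -- the null configuration in which parental age leaves
#' crossover rates unchanged. Interference is stronger in female meiosis by
#' default (`nu_f = 2 * nu_m`).
#'
#' @param nu_m,nu_f Interference shapes for male / female meiosis.
#' @param ages Ages (DAS) the models cover.
#' @return Named list of [meiosis_model()] objects keyed by line name.
#' @export
default_models <- function(nu_m = 2.5, nu_f = 5, ages = c(40L, 45L, 50L, 55L)) {
  lapply(.DEFAULT_P_REC, function(p) {
    meiosis_model(lambda_m = lambda_for_p_rec(p[["m"]], nu_m),
                  lambda_f = lambda_for_p_rec(p[["f"]], nu_f),
                  nu_m = nu_m, nu_f = nu_f, ages = ages)
  })
}

#' Generate a synthetic sex-specific recombination landscape
#'
#' Emulates a location-based crossover-rate table: regularly spaced points
#' per chromosome whose male rate is elevated in subtelomeric zones and whose
#' female rate is elevated pericentromerically, plus multiplicative noise.
#' Both rates are suppressed at the centromere-containing pericentromeric
#' core for the male. This is the generator behind the zone-overlap
#' properties: intervals with high subtelomeric overlap acquire high
#' predicted mCO:fCO.
#'
#' @param zones A [zone_map()] (defaults to [default_zone_map()]).
#' @param points_per_chr Landscape points per chromosome.
#' @param base_rate Baseline local rate for both sexes (cM/Mb-like units).
#' @param male_subtel_boost Multiplier on the male rate inside subtelomeric
#'   zones.
#' @param female_pericen_boost Multiplier on the female rate inside
#'   pericentromeric zones.
#' @param noise_sd Standard deviation of lognormal multiplicative noise.
#' @param seed Optional integer seed.
#' @return A [landscape_table()].
#' @export
synth_landscape <- function(zones = default_zone_map(), points_per_chr = 30L,
                            base_rate = 3, male_subtel_boost = 3,
                            female_pericen_boost = 2, noise_sd = 0.15,
                            seed = NULL) {
  .with_seed(seed, {
    rows <- lapply(1:5, function(ch) {
      len <- .CHR_MB[[as.character(ch)]] * 1e6
      pos <- seq(len / (2 * points_per_chr), len - len / (2 * points_per_chr),
                 length.out = points_per_chr)
      z <- zones$zones[zones$zones$chromosome == ch, ]
      in_zone <- function(class) {
        r <- z[z$zone == class, ]
        vapply(pos, function(p) any(p >= r$start & p <= r$end), logical(1))
      }
      sub <- in_zone("subtelomeric")
      peri <- in_zone("pericentromeric")
      male <- base_rate * ifelse(sub, male_subtel_boost, 1) *
        ifelse(peri, 0.5, 1)
      female <- base_rate * ifelse(peri, female_pericen_boost, 1) *
        ifelse(sub, 0.75, 1)
      noise <- function(n) exp(stats::rnorm(n, 0, noise_sd))
      tibble::tibble(chromosome = ch, pos = pos,
                     male_rate = male * noise(points_per_chr),
                     female_rate = female * noise(points_per_chr))
    })
    x <- do.call(rbind, rows)
    landscape_table(x$chromosome, x$pos, x$male_rate, x$female_rate)
  })
}
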