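---
title: "Methods: sex-specific crossover rates from FTL seed counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific crossover rates from FTL seed counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftlchiasma)
```

This vignette records the model, the statistical methods, and the deliberate
conventions behind `ftlchiasma`. It is the place to look when a number the
package produces needs to be traced back to an assumption.

## The assay

A fluorescent tagged line (FTL) carries two linked seed-expressed transgenes
— dsRed and eGFP — in *cis* (coupling phase) on one chromosome. Crossing a
hemizygous FTL parent to wild type and scoring the seeds of the cross gives
four fluorescence classes:

* **R** (dsRed only) and **G** (eGFP only): recombinant gametes — an odd
  number of crossovers fell between the two markers;
* **RG** (both) and **NFS** (neither): parental gametes — zero or an even
  number of crossovers between the markers.

The recombination frequency is the recombinant fraction,

$$\mathrm{RF} = 100 \times \frac{R + G}{R + G + RG + NFS}\ (\%),$$

implemented in `estimate_rf()`. RF is used directly as a relative crossover
rate; no mapping-function conversion to centimorgans is applied anywhere in
the package. Whether the FTL parent is used as **male** (pollen donor;
`role = "male_detector"`) or **female** (`role = "female_detector"`)
determines whether male or female meiosis is being read out, and the per-line
ratio of the two aggregated rates, mCO:fCO, is the heterochiasmy summary
(`summarize_line()`).

## Meiosis model

### Crossover counts

`meiosis_model()` parameterises each sex by `lambda`, the **mean number of
crossovers per gamete** in the marker interval (i.e. the interval's genetic
length in Morgans), and an interference shape `nu`.

Internally, crossovers are placed at the **bivalent** (four-chromatid) level:
the bivalent crossover count has mean $2\lambda$, and each crossover involves
a given chromatid with probability 1/2 independently (no chromatid
interference). A transmitted chromatid therefore "thins" the bivalent process
by 1/2, which halves the mean back to $\lambda$ and yields the recombinant
probability

$$p_\mathrm{rec} = \frac{1 - P_0}{2},$$

where $P_0$ is the probability of zero crossovers on the bivalent (Mather's
formula). This holds for *any* count distribution, so it is how
`gamete_class_probs()` computes class probabilities at every interference
level.

### Interference

Crossover positions on the bivalent follow a **stationary gamma-renewal
process**: inter-crossover distances are Gamma with shape $\nu$ and rate
$\nu m$ (with $m = 2\lambda$ per unit interval), and the first event is drawn
from the equilibrium (length-biased) distribution so that the process has no
preferred origin. $\nu = 1$ recovers a Poisson process — no interference —
and larger $\nu$ regularises spacings. At $\nu = 1$,
$P_0 = e^{-2\lambda}$ and the recombinant probability reduces to Haldane's
mapping:

$$p_\mathrm{rec} = \frac{1 - e^{-2\lambda}}{2}.$$

```{r haldane}
m <- meiosis_model(lambda_m = 0.25, lambda_f = 0.25)  # nu = 1
p <- gamete_class_probs(m, "male", 40)
c(model = unname(p[["p_r_only"]] + p[["p_g_only"]]),
  haldane = (1 - exp(-0.5)) / 2)
```

Count probabilities under general $\nu$ are computed by numerical integration
of the renewal equations (`stats::integrate` on the equilibrium survival
function); positions are simulated by inverting the equilibrium first-event
CDF on a fine grid and then adding Gamma-distributed gaps.

`lambda_for_p_rec()` inverts $p_\mathrm{rec}(\lambda)$ — closed-form at
$\nu = 1$, `uniroot` otherwise — and is how the default models are calibrated
to a target RF scale.

### Age structure and study simulation

A model carries a vector of parental ages (days after sowing) and optional
additive per-age effects on `lambda`; the default effect is zero (the null).
`simulate_study()` draws each cross's four seed-class counts from a single
multinomial with the model-implied class probabilities, for every
line × role × age × replicate cell of a `study_design()`. Default design
sizes — 4 ages, 3 replicates, 2200 seeds per cross — are the package's own
choices of a realistic operating point for seed-based FTL assays.

## Ratio conventions

Published per-line mCO:fCO values are not all consistent with a single
aggregation rule, so `summarize_line()` makes the convention explicit:

* `ratio_of_means` (default): aggregate male RFs, aggregate female RFs,
  divide;
* `mean_of_ratios`: form the per-age ratio first, then average.

Aggregation over replicates is likewise explicit: `replicate_mean`
(unweighted, matching the replicate-level linear model) or `seed_weighted`
(pooled counts). With no age effect the two ratio conventions agree closely;
they diverge when rates trend with age.

## Parental-age inference

For one line × role, replicate RFs are modelled as a one-way Gaussian layout
on age bracket (`fit_group_model()`, equivalent to `lm(rf ~ 0 + factor(age))`
with a pooled residual variance). All pairwise age differences
(`pairwise_contrasts()`; 6 contrasts for 4 ages) form the family.

Family-wise error is controlled by the **single-step max-|t| adjustment**
(`single_step_adjust()`), implemented directly in the package:

$$p^{\mathrm{adj}}_j = P\Big(\max_k |T_k| \ge |t_j|\Big),$$

where $(T_1,\dots,T_K)$ is central multivariate $t$ with the
design-implied contrast correlation and the fit's residual degrees of
freedom. The probability is evaluated by Monte Carlo with a shared
chi-square denominator (default `mc_draws = 1e5`). The null draws are made
in **group space** — $Z_g \sim N(0, 1/n_g)$ per group, contrasts formed from
them — because the contrast correlation matrix itself is rank-deficient
whenever all pairwise contrasts of three or more groups are tested, so a
Cholesky factorisation of it would fail; group-space sampling realises the
exact joint law regardless. Adjusted p-values are clamped to be at least the
raw p-value and monotone in $|t|$. The test suite cross-checks the
adjustment against `multcomp::glht(..., test = adjusted("single-step"))`.

Calibration: with normally distributed responses the procedure is exact
(simulated family-wise error 5.0% at $\alpha = 0.05$ over 20,000 null
studies). With binomial seed-count responses at the default design (2200
seeds per cross) the rate is very slightly inflated by non-normality, ~5.2%
over 5,000 null studies. A 1000-study estimate of this rate carries
Monte-Carlo spread of roughly ±1.4 percentage points (2 SD), so individual
1000-study replications scatter noticeably around that value.

```{r age, cache = FALSE}
models <- default_models()
st <- simulate_study(study_design("CTL1.18"), models["CTL1.18"],
                     n_seeds = 2200, seed = 42)
run_age_analysis(st$crosses, role = "female_detector", seed = 1)
```

## Two-marker non-detection bias

A two-marker readout scores only crossover-count *parity*: gametes with 2, 4,
… crossovers in the interval look parental. Two consequences are quantified:

* **Odd–even gap** (`odd_even_gap()`): the relative shortfall
  $(\lambda - p_\mathrm{rec})/\lambda$ of RF-based estimation against the true
  per-gamete crossover mean. At $\nu = 1$ and $\lambda = 0.5$ this gap is
  $e^{-1} \approx 0.368$. Because male `lambda` is larger, the gap is larger
  in male meiosis and raw RF ratios *understate* mCO:fCO.
* **Sensitivity of the ratio** (`nondetection_adjust()`,
  `ratio_sensitivity_sweep()`): given per-sex crossover-class proportions
  $(n_0, n_1, n_2, n_{3+})$ and a per-extra-crossover non-detection fraction
  $f$, the detected rate is $\sum_{k\ge1} n_k\,(1 + (k-1)(1-f))$, with the
  3+ class treated as exactly 3. At $f = 0$ the ratio is unchanged by
  construction; realistic multi-crossover proportions move the ratio by well
  under 5% at $f = 0.10$.

`double_co_within()` complements this with a positional view: among
simulated bivalents with exactly two crossovers in an interval, the fraction
whose crossovers fall within a given distance. On a 10.5-Mb interval the
no-interference closed form is $2d/L - (d/L)^2$; interference pushes the two
crossovers apart and lowers the fraction.

```{r spacing}
iv <- marker_interval("long", 1, 10e6, 20.5e6)
double_co_within(meiosis_model(0.4, 0.4), "male", 5, iv,
                 n_meioses = 2e4, seed = 7)$fraction_within
2 * (5 / 10.5) - (5 / 10.5)^2
```

## Landscape prediction

`predict_interval()` turns a location-based sex-specific rate table
(`landscape_table()`) into interval-level predictions: the unweighted mean of
in-interval point rates (closed interval, endpoints included) times interval
length in Mb, per sex, plus their ratio (`method = "trapezoid"` integrates
instead). `zone_overlap()` reports the fraction of an interval lying in
subtelomeric and pericentromeric zones of a `zone_map()` and whether it spans
a centromere. `compare_estimated_predicted()` pairs estimated and predicted
ratios and reports a Spearman rank correlation — descriptive concordance
only, no threshold.

## Synthetic defaults — scope

`default_intervals()`, `default_zone_map()`, `default_models()` and
`synth_landscape()` are **synthetic placeholders**. The intervals respect the
study geometry (one 10.5-Mb interval spanning the chromosome-1 centromere,
seven 4.71-Mb intervals across all five chromosomes) and the published
association of high mCO:fCO with subtelomeric placement, but the coordinates
are not the lines' true insertion sites, and the landscape generator builds
in the very subtelomeric-male / pericentromeric-female structure it is used
to illustrate. Tests passing on these defaults demonstrate that the
machinery is self-consistent — not that real Arabidopsis landscapes have been
validated. Real analyses should supply their own interval, zone and
landscape tables through the `read_*_table()` readers or the
`run_pipeline()` config.

## Numerical choices

* Renewal-count integrals: `stats::integrate` with default tolerances; count
  pmfs truncated when the tail falls below $10^{-9}$.
* Equilibrium-CDF inversion for position simulation: 4097-point trapezoidal
  grid.
* max-|t| Monte Carlo: $10^5$ draws by default; p-value resolution is then
  $\sim10^{-5}$ with binomial noise $\sqrt{p(1-p)/10^5}$.
* All simulators accept an integer `seed` and restore the caller's RNG state.

## Limitations

* No chromatid interference; obligate crossover is not enforced.
* Gaussian inference on replicate RFs relies on large per-cross seed counts;
  at a few hundred seeds per cross, exact binomial methods would be
  preferable.
* The non-detection adjustment treats the 3+ class as exactly three
  crossovers.
* Per-age effects enter `lambda` additively and deterministically; there is
  no between-replicate biological variance component beyond multinomial
  sampling.
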