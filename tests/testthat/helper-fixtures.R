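# Shared fixture builders (all data generated in code; nothing on disk).

# A plain no-interference model with equal or unequal sex rates.
make_model <- function(lambda_m = 0.25, lambda_f = 0.25, nu_m = 1, nu_f = 1,
                       ...) {
  meiosis_model(lambda_m = lambda_m, lambda_f = lambda_f,
                nu_m = nu_m, nu_f = nu_f, ...)
}

# One cross record with an exact RF: rf_pct must have at most 2 decimals.
cross_with_rf <- function(rf_pct, role, line = "L", age_das = 40L,
                          replicate = 1L, n_total = 10000L) {
  n_rec <- round(rf_pct / 100 * n_total)
  stopifnot(abs(n_rec - rf_pct / 100 * n_total) < 1e-9)
  half_rec <- n_rec %/% 2
  half_par <- (n_total - n_rec) %/% 2
  tibble::tibble(line = line, role = role, age_das = as.integer(age_das),
                 replicate = as.integer(replicate),
                 n_r = half_rec, n_g = n_rec - half_rec,
                 n_rg = half_par, n_nfs = n_total - n_rec - half_par)
}

# Records whose role-wise mean RFs equal the given percentages exactly.
line_with_rates <- function(mco, fco, line = "L") {
  rbind(cross_with_rf(mco, "male_detector", line = line),
        cross_with_rf(fco, "female_detector", line = line))
}

# Gamete recombination fraction implied by a bivalent-level simulation:
# thin counts to one chromatid and take the parity.
mc_gamete_parity <- function(n, lambda, nu, seed) {
  sim <- sim_crossover_positions(n, lambda, nu, seed = seed)
  withr::with_seed(seed + 1, {
    gam <- stats::rbinom(n, sim$counts, 0.5)
    mean(gam %% 2 == 1)
  })
}
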