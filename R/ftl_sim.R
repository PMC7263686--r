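# ---------------------------------------------------------------------------
# RNG helper: run expr under a fixed seed without disturbing the session RNG.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# ---------------------------------------------------------------------------
# Domain types

#' Define a two-marker (optionally three-marker) FTL detector interval
#'
#' A detector line carries two linked seed-expressed fluorescent transgenes
#' (eGFP and dsRed) in coupling phase; recombination between their insertion
#' sites during meiosis in the doubly heterozygous F1 is read out from seed
#' fluorescence. `pos_mid` marks an optional third marker splitting the
#' interval into two sub-intervals for double-crossover counting.
#'
#' @param line_name Character label for the detector line.
#' @param chromosome Integer chromosome number (1--5).
#' @param pos_egfp,pos_dsred 1-based physical positions (bp) of the two
#'   markers; must differ.
#' @param pos_mid Optional 1-based position (bp) of a third marker, strictly
#'   between the outer two.
#' @return An object of class `marker_interval`.
#' @examples
#' iv <- marker_interval("CTL-demo", 1, 1e6, 5.5e6)
#' interval_length_mb(iv)
#' @export
marker_interval <- function(line_name, chromosome, pos_egfp, pos_dsred,
                            pos_mid = NULL) {
  stopifnot(is.character(line_name), length(line_name) == 1L, nzchar(line_name))
  chromosome <- as.integer(chromosome)
  if (is.na(chromosome) || chromosome < 1L || chromosome > 5L) {
    stop("'chromosome' must be an integer in 1..5", call. = FALSE)
  }
  for (p in list(pos_egfp, pos_dsred)) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 1) {
      stop("marker positions must be 1-based positive base-pair coordinates",
           call. = FALSE)
    }
  }
  if (pos_egfp == pos_dsred) {
    stop("'pos_egfp' and 'pos_dsred' must differ (interval length must be > 0)",
         call. = FALSE)
  }
  if (!is.null(pos_mid)) {
    lo <- min(pos_egfp, pos_dsred)
    hi <- max(pos_egfp, pos_dsred)
    if (!is.numeric(pos_mid) || length(pos_mid) != 1L ||
        pos_mid <= lo || pos_mid >= hi) {
      stop("'pos_mid' must lie strictly between the two outer markers",
           call. = FALSE)
    }
  }
  structure(
    list(line_name = line_name, chromosome = chromosome,
         pos_egfp = as.numeric(pos_egfp), pos_dsred = as.numeric(pos_dsred),
         pos_mid = if (is.null(pos_mid)) NULL else as.numeric(pos_mid)),
    class = "marker_interval"
  )
}

#' @rdname marker_interval
#' @param interval A `marker_interval`.
#' @export
interval_length_mb <- function(interval) {
  stopifnot(inherits(interval, "marker_interval"))
  abs(interval$pos_dsred - interval$pos_egfp) / 1e6
}

#' @export
print.marker_interval <- function(x, ...) {
  cat(sprintf("<marker_interval> %s chr%d: eGFP %.0f, dsRed %.0f (%.2f Mb)%s\n",
              x$line_name, x$chromosome, x$pos_egfp, x$pos_dsred,
              interval_length_mb(x),
              if (is.null(x$pos_mid)) "" else sprintf(", mid %.0f", x$pos_mid)))
  invisible(x)
}

#' Generative model of meiosis in an FTL interval
#'
#' Parameterises the crossover process in one marker interval. `lambda_m` and
#' `lambda_f` are the mean numbers of crossovers transmitted *per gamete* in
#' the interval (i.e. the genetic length in Morgans) for male and female
#' meiosis. Crossovers are simulated at the bivalent level -- a stationary
#' gamma-renewal process along the interval with shape `nu` (nu = 1 is a
#' Poisson process, i.e. no interference; larger nu spaces crossovers more
#' evenly) and mean count `2*lambda` -- then thinned to a single gamete
#' chromatid with probability 1/2 per crossover (no chromatid interference).
#' Under nu = 1 this recovers Haldane's mapping function,
#' P(recombinant) = (1 - exp(-2*lambda)) / 2.
#'
#' Age effects are multiplicative factors on lambda per sex; the default of
#' 1 at every age encodes a crossover rate that does not change with parental
#' age.
#'
#' @param lambda_m,lambda_f Mean crossovers per gamete in the interval for
#'   male / female meiosis (>= 0).
#' @param nu_m,nu_f Gamma-renewal interference shape per sex (>= 1).
#' @param ages Integer vector of parental ages (days after sowing) the model
#'   is defined for.
#' @param age_effect_m,age_effect_f Positive multiplicative factors on lambda,
#'   one per entry of `ages`.
#' @return An object of class `meiosis_model`.
#' @examples
#' m <- meiosis_model(lambda_m = 0.25, lambda_f = 0.14)
#' model_lambda(m, "male", 40)
#' @export
meiosis_model <- function(lambda_m, lambda_f, nu_m = 1, nu_f = 1,
                          ages = c(40L, 45L, 50L, 55L),
                          age_effect_m = rep(1, length(ages)),
                          age_effect_f = rep(1, length(ages))) {
  stopifnot(is.numeric(lambda_m), lambda_m >= 0,
            is.numeric(lambda_f), lambda_f >= 0,
            is.numeric(nu_m), nu_m >= 1,
            is.numeric(nu_f), nu_f >= 1)
  ages <- as.integer(ages)
  if (anyDuplicated(ages)) stop("'ages' must be distinct", call. = FALSE)
  if (length(age_effect_m) != length(ages) ||
      length(age_effect_f) != length(ages)) {
    stop("age effect vectors must have one entry per age", call. = FALSE)
  }
  if (any(age_effect_m <= 0) || any(age_effect_f <= 0)) {
    stop("age effect factors must be > 0", call. = FALSE)
  }
  structure(
    list(lambda = c(male = lambda_m, female = lambda_f),
         nu = c(male = nu_m, female = nu_f),
         ages = ages,
         age_effect = list(male = stats::setNames(age_effect_m, ages),
                           female = stats::setNames(age_effect_f, ages))),
    class = "meiosis_model"
  )
}

.check_sex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1L ||
      !sex %in% c("male", "female")) {
    stop("'sex' must be \"male\" or \"female\"", call. = FALSE)
  }
  sex
}

#' @rdname meiosis_model
#' @param model A `meiosis_model`.
#' @param sex `"male"` or `"female"` (the sex of meiosis in the detector
#'   parent).
#' @param age_das Parental age in days after sowing; must be one of the
#'   model's configured ages.
#' @export
model_lambda <- function(model, sex, age_das) {
  stopifnot(inherits(model, "meiosis_model"))
  .check_sex(sex)
  age_das <- as.integer(age_das)
  if (length(age_das) != 1L || !age_das %in% model$ages) {
    stop(sprintf("age %s is not in the model's configured ages (%s)",
                 age_das, paste(model$ages, collapse = ", ")), call. = FALSE)
  }
  unname(model$lambda[[sex]] * model$age_effect[[sex]][[as.character(age_das)]])
}

#' @rdname meiosis_model
#' @export
model_nu <- function(model, sex) {
  stopifnot(inherits(model, "meiosis_model"))
  unname(model$nu[[.check_sex(sex)]])
}

.role_sex <- function(detector_role) {
  if (!is.character(detector_role) || length(detector_role) != 1L ||
      !detector_role %in% c("female_detector", "male_detector")) {
    stop("'detector_role' must be \"female_detector\" or \"male_detector\"",
         call. = FALSE)
  }
  # female_detector: the FTL line is emasculated and pollinated by wild type,
  # so its megaspores (female meiosis) are scored; male_detector conversely.
  c(female_detector = "female", male_detector = "male")[[detector_role]]
}

# ---------------------------------------------------------------------------
# Renewal-process machinery (bivalent level, unit interval, mean count 2*lambda)

.biv_pmf <- function(lambda, nu, tail = 1e-10) {
  m <- 2 * lambda
  if (m <= 0) return(1)
  if (nu == 1) {
    kmax <- 0L
    while (stats::ppois(kmax, m, lower.tail = FALSE) > tail) kmax <- kmax + 1L
    p <- stats::dpois(0:kmax, m)
    return(p / sum(p))
  }
  beta <- nu * m
  surv <- function(u) stats::pgamma(u, shape = nu, rate = beta,
                                    lower.tail = FALSE)
  p_ge <- m * stats::integrate(surv, 0, 1, rel.tol = 1e-12,
                               abs.tol = 1e-14)$value
  k <- 1L
  while (p_ge[k] > tail && k < 500L) {
    k <- k + 1L
    kk <- k  # freeze for the closure
    p_ge[k] <- m * stats::integrate(
      function(u) surv(u) * stats::pgamma(1 - u, shape = (kk - 1L) * nu,
                                          rate = beta),
      0, 1, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
  pmf <- -diff(c(1, p_ge, 0))
  pmf[pmf < 0] <- 0
  pmf / sum(pmf)
}

# P(no crossover on the bivalent) -- all the class-probability math needs.
.biv_p0 <- function(lambda, nu) {
  m <- 2 * lambda
  if (m <= 0) return(1)
  if (nu == 1) return(exp(-m))
  beta <- nu * m
  f_e1 <- m * stats::integrate(
    function(u) stats::pgamma(u, shape = nu, rate = beta, lower.tail = FALSE),
    0, 1, rel.tol = 1e-12, abs.tol = 1e-14)$value
  max(0, 1 - f_e1)
}

#' Simulate bivalent-level crossover positions in an interval
#'
#' Draws `n` meioses from the stationary gamma-renewal crossover process on
#' the unit interval (bivalent level, mean count `2*lambda`, interference
#' shape `nu`). Positions are in interval-fraction units; multiply by the
#' physical length to get Mb.
#'
#' @param n Number of meioses.
#' @param lambda Mean crossovers per gamete in the interval.
#' @param nu Interference shape (>= 1).
#' @param seed Optional integer seed (session RNG state is preserved).
#' @return A list with `counts` (integer vector, length `n`) and `positions`
#'   (numeric matrix, `n` rows, NA-padded columns).
#' @export
sim_crossover_positions <- function(n, lambda, nu = 1, seed = NULL) {
  stopifnot(n >= 1, lambda >= 0, nu >= 1)
  n <- as.integer(n)
  .with_seed(seed, {
    m <- 2 * lambda
    if (m == 0) {
      return(list(counts = integer(n),
                  positions = matrix(NA_real_, n, 0)))
    }
    if (nu == 1) {
      counts <- stats::rpois(n, m)
      total <- sum(counts)
      maxk <- max(counts, 1L)
      pos <- matrix(NA_real_, n, maxk)
      if (total > 0) {
        pos[cbind(rep.int(seq_len(n), counts), sequence(counts))] <-
          stats::runif(total)
      }
      return(list(counts = counts, positions = pos))
    }
    beta <- nu * m
    # first event: equilibrium (stationary-renewal) distribution, sampled by
    # numeric inversion of F_e(x) = m * int_0^x S(u) du on a dense grid
    grid <- seq(0, 1, length.out = 4097L)
    s <- stats::pgamma(grid, shape = nu, rate = beta, lower.tail = FALSE)
    h <- grid[2L]
    f_e <- m * c(0, cumsum((s[-length(s)] + s[-1L]) / 2) * h)
    u <- stats::runif(n)
    cur <- rep(NA_real_, n)
    hit <- u < f_e[length(f_e)]
    if (any(hit)) {
      cur[hit] <- stats::approx(f_e, grid, xout = u[hit], ties = "ordered")$y
    }
    counts <- integer(n)
    cols <- list()
    repeat {
      act <- which(!is.na(cur) & cur <= 1)
      if (!length(act)) break
      counts[act] <- counts[act] + 1L
      col <- rep(NA_real_, n)
      col[act] <- cur[act]
      cols[[length(cols) + 1L]] <- col
      cur[act] <- cur[act] + stats::rgamma(length(act), shape = nu, rate = beta)
    }
    pos <- if (length(cols)) do.call(cbind, cols) else matrix(NA_real_, n, 0)
    list(counts = counts, positions = pos)
  })
}

# Thin bivalent crossovers to one gamete chromatid (each kept w.p. 1/2).
.thin_to_gamete <- function(sim) {
  pos <- sim$positions
  if (ncol(pos) == 0) {
    return(list(counts = integer(length(sim$counts)), positions = pos))
  }
  keep <- !is.na(pos) & matrix(stats::runif(length(pos)), nrow(pos)) < 0.5
  pos[!keep] <- NA_real_
  list(counts = as.integer(rowSums(keep)), positions = pos)
}

# ---------------------------------------------------------------------------
# Distributions and class probabilities

#' Distribution of crossover counts transmitted to a gamete
#'
#' Probability mass function of the number of crossovers a single gamete
#' chromatid carries in the interval, under the bivalent gamma-renewal model
#' thinned 1/2 per crossover. For `nu = 1` this is exactly Poisson with mean
#' `lambda * age_effect(age)`.
#'
#' @inheritParams model_lambda
#' @param tail Truncation point: the returned support covers all counts with
#'   total tail mass below `tail`.
#' @return Named numeric vector of probabilities over counts `0..k_max`.
#' @export
crossover_count_distribution <- function(model, sex, age_das, tail = 1e-9) {
  lam <- model_lambda(model, sex, age_das)
  nu <- model_nu(model, sex)
  if (lam == 0) return(c(`0` = 1))
  if (nu == 1) {
    kmax <- 0L
    while (stats::ppois(kmax, lam, lower.tail = FALSE) > tail) kmax <- kmax + 1L
    p <- stats::dpois(0:kmax, lam)
    return(stats::setNames(p / sum(p), 0:kmax))
  }
  biv <- .biv_pmf(lam, nu, tail = tail / 10)
  kb <- length(biv) - 1L
  gam <- vapply(0:kb, function(j) {
    sum(biv[(j:kb) + 1L] * stats::dbinom(j, j:kb, 0.5))
  }, numeric(1))
  keep <- max(which(rev(cumsum(rev(gam))) > tail), 1L)
  gam <- gam[seq_len(keep)]
  stats::setNames(gam / sum(gam), seq_along(gam) - 1L)
}

#' Gamete fluorescence-class probabilities for a two-marker interval
#'
#' In coupling phase a gamete is recombinant -- carrying exactly one of the
#' two markers -- iff it received an odd number of crossovers between them.
#' Under bivalent simulation with 1/2 thinning, P(recombinant) equals
#' `(1 - P(no crossover on the bivalent)) / 2` (at nu = 1, Haldane's
#' `(1 - exp(-2*lambda)) / 2`). The four classes are the seed phenotypes:
#' both markers, neither, dsRed only, eGFP only.
#'
#' @inheritParams model_lambda
#' @return Named numeric vector `c(p_both, p_none, p_r_only, p_g_only)`
#'   summing to 1, with `p_r_only == p_g_only` and `p_both == p_none`
#'   (coupling symmetry).
#' @export
gamete_class_probs <- function(model, sex, age_das) {
  lam <- model_lambda(model, sex, age_das)
  nu <- model_nu(model, sex)
  p_rec <- if (nu == 1) -expm1(-2 * lam) / 2 else (1 - .biv_p0(lam, nu)) / 2
  c(p_both = (1 - p_rec) / 2, p_none = (1 - p_rec) / 2,
    p_r_only = p_rec / 2, p_g_only = p_rec / 2)
}

#' Invert the gamete recombination probability to a model lambda
#'
#' @param p_rec Target probability that a gamete is recombinant (0 <= p < 0.5).
#' @param nu Interference shape.
#' @return The `lambda` (mean crossovers per gamete) whose
#'   [gamete_class_probs()] recombinant probability equals `p_rec`.
#' @export
lambda_for_p_rec <- function(p_rec, nu = 1) {
  stopifnot(p_rec >= 0, p_rec < 0.5, nu >= 1)
  if (p_rec == 0) return(0)
  if (nu == 1) return(-log1p(-2 * p_rec) / 2)
  f <- function(l) (1 - .biv_p0(l, nu)) / 2 - p_rec
  stats::uniroot(f, c(1e-8, 20), tol = 1e-10)$root
}

# ---------------------------------------------------------------------------
# Seed-count simulation

.cross_record <- function(line, role, age_das, replicate, counts) {
  tibble::tibble(line = line, role = role, age_das = as.integer(age_das),
                 replicate = as.integer(replicate),
                 n_r = as.integer(counts[["p_r_only"]]),
                 n_g = as.integer(counts[["p_g_only"]]),
                 n_rg = as.integer(counts[["p_both"]]),
                 n_nfs = as.integer(counts[["p_none"]]))
}

#' Simulate one scored cross (a seed-count record)
#'
#' Draws the four seed fluorescence-class counts for one cross replicate as a
#' multinomial sample over [gamete_class_probs()].
#'
#' @inheritParams model_lambda
#' @param interval A [marker_interval()].
#' @param detector_role `"female_detector"` (FTL line emasculated, scores
#'   female meiosis) or `"male_detector"` (FTL line as pollen donor, scores
#'   male meiosis).
#' @param n_seeds Seeds scored (>= 1).
#' @param replicate_id Replicate label.
#' @param seed Optional integer seed.
#' @return One-row tibble: `line`, `role`, `age_das`, `replicate`, `n_r`,
#'   `n_g`, `n_rg`, `n_nfs`.
#' @export
simulate_cross <- function(model, interval, detector_role, age_das, n_seeds,
                           replicate_id = 1L, seed = NULL) {
  if (!is.numeric(n_seeds) || n_seeds < 1) {
    stop("'n_seeds' must be >= 1", call. = FALSE)
  }
  sex <- .role_sex(detector_role)
  probs <- gamete_class_probs(model, sex, age_das)
  .with_seed(seed, {
    x <- stats::rmultinom(1, size = as.integer(n_seeds), prob = probs)[, 1]
    names(x) <- names(probs)
    .cross_record(interval$line_name, detector_role, age_das, replicate_id, x)
  })
}

#' Build a fully crossed study design
#'
#' @param lines Character vector of line names.
#' @param roles Detector roles to include.
#' @param ages Parental ages (DAS).
#' @param replicates Number of replicates per cell, or an explicit vector of
#'   replicate ids.
#' @return Tibble with one row per line x role x age x replicate.
#' @export
study_design <- function(lines, roles = c("female_detector", "male_detector"),
                         ages = c(40L, 45L, 50L, 55L), replicates = 3L) {
  rep_ids <- if (length(replicates) == 1L) seq_len(replicates) else replicates
  d <- expand.grid(replicate = as.integer(rep_ids), age_das = as.integer(ages),
                   role = roles, line = lines,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(d[, c("line", "role", "age_das", "replicate")])
}

#' Simulate a full FTL crossing study
#'
#' Generates seed-class counts for every design cell and returns, alongside
#' the cross table, a truth table with the generating parameters per cell --
#' the basis for parameter-recovery tests.
#'
#' @param design Tibble as from [study_design()]; duplicate
#'   (line, role, age, replicate) cells are an error.
#' @param models A single [meiosis_model()] applied to all lines, or a named
#'   list of models keyed by line name.
#' @param n_seeds Seeds scored per cross (default 2200, the study's per-cell
#'   scale), a single number or one per design row.
#' @param seed Optional integer seed; the whole study is reproducible from it.
#' @return List of class `ftl_study`: `crosses` (seed-count tibble) and
#'   `truth` (line, role, age_das, lambda, nu, p_recombinant).
#' @export
simulate_study <- function(design, models, n_seeds = 2200L, seed = NULL) {
  stopifnot(is.data.frame(design), nrow(design) >= 1L)
  key <- paste(design$line, design$role, design$age_das, design$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate design cells: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  if (inherits(models, "meiosis_model")) {
    models <- stats::setNames(rep(list(models), length(unique(design$line))),
                              unique(design$line))
  }
  missing_models <- setdiff(unique(design$line), names(models))
  if (length(missing_models)) {
    stop("no model for line(s): ", paste(missing_models, collapse = ", "),
         call. = FALSE)
  }
  n_seeds <- rep_len(as.integer(n_seeds), nrow(design))
  cells <- unique(design[, c("line", "role", "age_das")])
  cells$sex <- vapply(cells$role, .role_sex, character(1))
  cells$lambda <- mapply(function(l, s, a) model_lambda(models[[l]], s, a),
                         cells$line, cells$sex, cells$age_das)
  cells$nu <- mapply(function(l, s) model_nu(models[[l]], s),
                     cells$line, cells$sex)
  probs <- mapply(function(l, s, a) gamete_class_probs(models[[l]], s, a),
                  cells$line, cells$sex, cells$age_das, SIMPLIFY = FALSE)
  cells$p_recombinant <- vapply(probs, function(p) {
    unname(p[["p_r_only"]] + p[["p_g_only"]])
  }, numeric(1))
  cell_key <- paste(cells$line, cells$role, cells$age_das)
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      j <- match(paste(design$line[i], design$role[i], design$age_das[i]),
                 cell_key)
      x <- stats::rmultinom(1, size = n_seeds[i], prob = probs[[j]])[, 1]
      names(x) <- names(probs[[j]])
      .cross_record(design$line[i], design$role[i], design$age_das[i],
                    design$replicate[i], x)
    })
    truth <- tibble::as_tibble(
      cells[, c("line", "role", "age_das", "lambda", "nu", "p_recombinant")])
    structure(list(crosses = do.call(rbind, rows), truth = truth),
              class = "ftl_study")
  })
}

#' Simulate a three-marker cross with per-sub-interval recombination status
#'
#' With a third marker at `pos_mid` the interval splits into two
#' sub-intervals, and a seed's fluorescence pattern (8 classes) reveals the
#' recombination status of each sub-interval jointly -- so double crossovers
#' spanning the two sub-intervals are countable directly, unlike in the
#' two-marker readout where even crossover numbers look parental.
#'
#' @inheritParams simulate_cross
#' @return List with `classes` (tibble of the 8 fluorescence patterns and
#'   counts), `joint` (counts by (sub-interval 1, sub-interval 2) recombinant
#'   status), and `collapsed` (the two-outer-marker seed-count collapse, same
#'   schema as [simulate_cross()]).
#' @export
simulate_three_marker_cross <- function(model, interval, detector_role,
                                        age_das, n_seeds, replicate_id = 1L,
                                        seed = NULL) {
  if (is.null(interval$pos_mid)) {
    stop("interval has no 'pos_mid'; three-marker simulation needs one",
         call. = FALSE)
  }
  if (!is.numeric(n_seeds) || n_seeds < 1) {
    stop("'n_seeds' must be >= 1", call. = FALSE)
  }
  sex <- .role_sex(detector_role)
  lam <- model_lambda(model, sex, age_das)
  nu <- model_nu(model, sex)
  f_mid <- (interval$pos_mid - interval$pos_egfp) /
    (interval$pos_dsred - interval$pos_egfp)
  n_seeds <- as.integer(n_seeds)
  .with_seed(seed, {
    biv <- sim_crossover_positions(n_seeds, lam, nu)
    gam <- .thin_to_gamete(biv)
    pos <- gam$positions
    in1 <- !is.na(pos) & pos < f_mid
    in2 <- !is.na(pos) & pos >= f_mid
    r1 <- (if (ncol(pos)) rowSums(in1) else integer(n_seeds)) %% 2L == 1L
    r2 <- (if (ncol(pos)) rowSums(in2) else integer(n_seeds)) %% 2L == 1L
    # which homolog the gamete starts on at the eGFP end (detector carries all
    # three markers in cis)
    a <- stats::runif(n_seeds) < 0.5
    h_g <- a
    h_m <- xor(h_g, r1)
    h_r <- xor(h_m, r2)
    pat <- paste0(ifelse(h_g, "G", "-"), ifelse(h_m, "M", "-"),
                  ifelse(h_r, "R", "-"))
    all_pat <- c("---", "--R", "-M-", "-MR", "G--", "G-R", "GM-", "GMR")
    classes <- tibble::tibble(
      pattern = all_pat,
      count = as.integer(table(factor(pat, levels = all_pat))))
    joint <- tibble::tibble(
      rec_sub1 = c(FALSE, TRUE, FALSE, TRUE),
      rec_sub2 = c(FALSE, FALSE, TRUE, TRUE),
      count = c(sum(!r1 & !r2), sum(r1 & !r2), sum(!r1 & r2), sum(r1 & r2)))
    counts <- c(p_r_only = sum(!h_g & h_r), p_g_only = sum(h_g & !h_r),
                p_both = sum(h_g & h_r), p_none = sum(!h_g & !h_r))
    collapsed <- .cross_record(interval$line_name, detector_role, age_das,
                               replicate_id, counts)
    list(classes = classes, joint = joint, collapsed = collapsed)
  })
}
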