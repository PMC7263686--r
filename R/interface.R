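# ---------------------------------------------------------------------------
# I/O: tab-separated tables for cross records, intervals, landscapes, zones;
# YAML pipeline configuration; the staged pipeline driver.

.CROSS_COLS <- c("line", "role", "age_das", "replicate",
                 "n_r", "n_g", "n_rg", "n_nfs")

#' Read a seed-count cross table
#'
#' Tab-separated with header `line role age_das replicate n_r n_g n_rg n_nfs`.
#' Malformed rows -- negative or non-integer counts, unknown role labels,
#' duplicate (line, role, age, replicate) keys -- are hard errors that name
#' the offending data rows.
#'
#' @param path File path.
#' @return Tibble of cross records.
#' @export
read_cross_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.CROSS_COLS, names(x))
  if (length(missing)) {
    stop("cross table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x[, .CROSS_COLS])
  counts <- as.matrix(x[, c("n_r", "n_g", "n_rg", "n_nfs")])
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative or non-integer counts at data row(s): ",
         paste(sort(unique(bad[, 1L])), collapse = ", "), call. = FALSE)
  }
  bad_role <- which(!x$role %in% c("female_detector", "male_detector"))
  if (length(bad_role)) {
    stop("unknown role label at data row(s): ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  }
  key <- paste(x$line, x$role, x$age_das, x$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (line, role, age, replicate) key at data row(s): ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }
  x$age_das <- as.integer(x$age_das)
  x$replicate <- as.integer(x$replicate)
  x[, c("n_r", "n_g", "n_rg", "n_nfs")] <-
    lapply(x[, c("n_r", "n_g", "n_rg", "n_nfs")], as.integer)
  x
}

#' @rdname read_cross_table
#' @param crosses Cross-record tibble.
#' @export
write_cross_table <- function(crosses, path) {
  readr::write_tsv(crosses[, .CROSS_COLS], path, progress = FALSE)
  invisible(path)
}

#' Read marker-interval definitions
#'
#' BED-like tab-separated text with header columns `chromosome`, `pos_egfp`,
#' `pos_dsred`, optional `pos_mid`, and `line_name`.
#'
#' @param path File path.
#' @return Named list of [marker_interval()] objects.
#' @export
read_interval_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chromosome", "pos_egfp", "pos_dsred", "line_name")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("interval table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  has_mid <- "pos_mid" %in% names(x)
  out <- lapply(seq_len(nrow(x)), function(i) {
    mid <- if (has_mid && !is.na(x$pos_mid[i])) x$pos_mid[i] else NULL
    marker_interval(x$line_name[i], x$chromosome[i], x$pos_egfp[i],
                    x$pos_dsred[i], pos_mid = mid)
  })
  stats::setNames(out, x$line_name)
}

#' @rdname read_interval_table
#' @param intervals Named list of [marker_interval()] objects.
#' @export
write_interval_table <- function(intervals, path) {
  rows <- lapply(intervals, function(iv) {
    tibble::tibble(chromosome = iv$chromosome, pos_egfp = iv$pos_egfp,
                   pos_dsred = iv$pos_dsred,
                   pos_mid = if (is.null(iv$pos_mid)) NA_real_ else iv$pos_mid,
                   line_name = iv$line_name)
  })
  readr::write_tsv(do.call(rbind, rows), path, progress = FALSE)
  invisible(path)
}

#' Read a location-based crossover-rate landscape
#'
#' Tab-separated with header `chromosome pos male_rate female_rate`.
#'
#' @param path File path.
#' @return A [landscape_table()].
#' @export
read_landscape_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  landscape_table(x$chromosome, x$pos, x$male_rate, x$female_rate)
}

#' Read a zone map from BED-like text
#'
#' Tab-separated with header `chromosome zone start end`; rows with zone
#' `"centromere"` carry the centromere midpoint in `start` (`end` ignored).
#'
#' @param path File path.
#' @return A [zone_map()].
#' @export
read_zone_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cen <- x[x$zone == "centromere", ]
  zone_map(x[x$zone != "centromere", c("chromosome", "zone", "start", "end")],
           tibble::tibble(chromosome = cen$chromosome, pos = cen$start))
}

#' Read a pipeline configuration
#'
#' YAML with fields: `seed`, `ages`, `replicates`, `n_seeds`, `alpha`,
#' `mc_draws`, `ratio_convention`, optional file paths (`intervals`,
#' `landscape`, `zones`, `crosses`) and optional per-line model parameters
#' (`models: {LINE: {lambda_m, lambda_f, nu_m, nu_f}}`). Referenced files
#' must exist at load time; ages must be strictly increasing; alpha in (0,1).
#'
#' @param path YAML file path.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, ages = c(40L, 45L, 50L, 55L), replicates = 3L,
                   n_seeds = 2200L, alpha = 0.05, mc_draws = 1e5,
                   ratio_convention = "ratio_of_means")
  cfg <- utils::modifyList(defaults, cfg)
  cfg$ages <- as.integer(cfg$ages)
  if (any(diff(cfg$ages) <= 0)) {
    stop("config 'ages' must be strictly increasing", call. = FALSE)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("config 'alpha' must be in (0, 1)", call. = FALSE)
  }
  for (f in c("intervals", "landscape", "zones", "crosses")) {
    if (!is.null(cfg[[f]])) {
      cfg[[f]] <- file.path(dirname(path), cfg[[f]])
      if (!file.exists(cfg[[f]])) {
        stop(sprintf("config '%s' file not found: %s", f, cfg[[f]]),
             call. = FALSE)
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

.config_models <- function(cfg, lines) {
  if (is.null(cfg$models)) {
    return(default_models(ages = cfg$ages)[lines])
  }
  out <- lapply(cfg$models, function(m) {
    meiosis_model(lambda_m = m$lambda_m, lambda_f = m$lambda_f,
                  nu_m = if (is.null(m$nu_m)) 1 else m$nu_m,
                  nu_f = if (is.null(m$nu_f)) 1 else m$nu_f,
                  ages = cfg$ages)
  })
  out[lines]
}

#' Run the full analysis pipeline
#'
#' Chains the stages simulate (or load) seed counts -> estimate RF and
#' heterochiasmy summaries -> test for age effects -> non-detection bias
#' sweep -> landscape prediction and zone overlap, writing each stage's
#' table under `out_dir` together with a run manifest carrying the seed and
#' a config hash. Deterministic for a fixed config and seed.
#'
#' @param config A [read_pipeline_config()] result or an equivalent list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage tables: `crosses`, `summaries`,
#'   `per_age`, `age_reports`, `bias`, `predictions`, `overlaps`,
#'   `concordance`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  intervals <- if (!is.null(cfg$intervals)) {
    read_interval_table(cfg$intervals)
  } else default_intervals()
  lines <- names(intervals)

  # stage: simulate (or load) seed counts
  if (!is.null(cfg$crosses)) {
    crosses <- read_cross_table(cfg$crosses)
    truth <- NULL
  } else {
    models <- .config_models(cfg, lines)
    design <- study_design(lines, ages = cfg$ages,
                           replicates = cfg$replicates)
    study <- simulate_study(design, models, n_seeds = cfg$n_seeds,
                            seed = cfg$seed)
    crosses <- study$crosses
    truth <- study$truth
    write_cross_table(crosses, file.path(out_dir, "crosses.tsv"))
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  }

  # stage: estimate
  summaries <- summarize_study(crosses, ratio_convention =
                                 cfg$ratio_convention)
  per_age <- do.call(rbind, lapply(split(crosses, crosses$line),
                                   per_age_ratios, ages = cfg$ages))
  readr::write_tsv(summaries, file.path(out_dir, "line_summaries.tsv"),
                   progress = FALSE)
  readr::write_tsv(per_age, file.path(out_dir, "per_age_ratios.tsv"),
                   progress = FALSE)

  # stage: test-age (both roles, per line; per-line families)
  grid <- expand.grid(line = unique(crosses$line),
                      role = c("female_detector", "male_detector"),
                      stringsAsFactors = FALSE)
  age_reports <- lapply(seq_len(nrow(grid)), function(i) {
    rep <- run_age_analysis(crosses, line = grid$line[i], role = grid$role[i],
                            alpha = cfg$alpha, mc_draws = cfg$mc_draws,
                            seed = cfg$seed + i)
    out <- rep$contrasts
    out$line <- rep$line
    out$role <- rep$role
    out[, c("line", "role", "contrast", "estimate", "std_error",
            "t_statistic", "p_raw", "p_adjusted", "significant")]
  })
  age_report <- do.call(rbind, age_reports)
  readr::write_tsv(age_report, file.path(out_dir, "age_contrasts.tsv"),
                   progress = FALSE)

  # stage: bias (non-detection sensitivity on representative class counts)
  classes <- co_class_counts(sex = c("male", "female"),
                             n0 = c(91, 99), n1 = c(5, 0.6),
                             n2 = c(3, 0.3), n3plus = c(1, 0.1))
  bias <- ratio_sensitivity_sweep(classes, f_grid = seq(0, 0.2, by = 0.05))
  readr::write_tsv(bias, file.path(out_dir, "nondetection_sweep.tsv"),
                   progress = FALSE)

  # stage: predict
  landscape <- if (!is.null(cfg$landscape)) {
    read_landscape_table(cfg$landscape)
  } else synth_landscape(seed = cfg$seed)
  zones <- if (!is.null(cfg$zones)) read_zone_table(cfg$zones)
    else default_zone_map()
  predictions <- do.call(rbind, lapply(intervals, predict_interval,
                                       landscape = landscape))
  overlaps <- do.call(rbind, lapply(intervals, zone_overlap, zones = zones))
  concordance <- compare_estimated_predicted(summaries, predictions)
  readr::write_tsv(predictions, file.path(out_dir, "interval_predictions.tsv"),
                   progress = FALSE)
  readr::write_tsv(overlaps, file.path(out_dir, "zone_overlaps.tsv"),
                   progress = FALSE)
  readr::write_tsv(concordance$table,
                   file.path(out_dir, "estimated_vs_predicted.tsv"),
                   progress = FALSE)

  cfg_plain <- unclass(cfg)
  cfg_file <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(cfg_plain, cfg_file)
  manifest <- tibble::tibble(
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_crosses = nrow(crosses),
    spearman_estimated_vs_predicted = concordance$spearman,
    any_age_contrast_significant = any(age_report$significant))
  readr::write_tsv(manifest, file.path(out_dir, "run_manifest.tsv"),
                   progress = FALSE)

  invisible(list(crosses = crosses, truth = truth, summaries = summaries,
                 per_age = per_age, age_contrasts = age_report, bias = bias,
                 predictions = predictions, overlaps = overlaps,
                 concordance = concordance, manifest = manifest))
}
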