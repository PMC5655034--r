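#' Read a key-value run configuration
#'
#' Configurations are plain YAML key-value files mirroring the fields of
#' [schedule_config()] plus the generating parameters (`phi` or `B` /
#' `Sigma_y`).
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    esmct_error(paste("config file not found:", path), "esmct_io")
  }
  yaml::read_yaml(path)
}

run_manifest <- function(config, seed, sub_seeds, outputs, t0) {
  list(config = config, master_seed = seed, derived_seeds = sub_seeds,
       package_version = as.character(utils::packageVersion("esmct")),
       started = format(t0), finished = format(Sys.time()),
       outputs = basename(outputs))
}

#' Simulate a schedule and series from a configuration file
#'
#' Reads a YAML configuration (fields of [schedule_config()] plus `phi`
#' or `B`/`Sigma_y`), generates the beep schedule and the CVAR(1) series,
#' and writes `schedule.csv`, `series.csv` and `manifest.yaml` to
#' `out_dir`. Identical configuration and seed reproduce identical files.
#'
#' @param config_path Path to the YAML configuration.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths of the written files.
#' @export
cli_simulate <- function(config_path, out_dir) {
  t0 <- Sys.time()
  cfg <- read_run_config(config_path)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  sc <- schedule_config(
    n_days = cfg$n_days %||% 10,
    beeps_per_day = cfg$beeps_per_day %||% 10,
    block_minutes = cfg$block_minutes %||% 90,
    min_interval_blocks = cfg$min_interval_blocks %||% 0,
    seed = derive_seed(seed, 1L))
  ct <- if (!is.null(cfg$phi)) {
    ct_params(log(cfg$phi), 1)
  } else if (!is.null(cfg$B)) {
    ct_params(matrix(unlist(cfg$B), length(cfg$B), byrow = TRUE),
              matrix(unlist(cfg$Sigma_y), length(cfg$Sigma_y), byrow = TRUE))
  } else {
    esmct_error("config must provide 'phi' or 'B' and 'Sigma_y'",
                "esmct_invalid_config")
  }
  sch <- generate_schedule(sc)
  ser <- simulate_cvar(ct, sch, seed = derive_seed(seed, 2L))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(out_dir, "schedule.csv")
  p2 <- file.path(out_dir, "series.csv")
  write_schedule_csv(sch, p1)
  write_series_csv(ser, p2)
  mf <- run_manifest(cfg, seed, c(schedule = derive_seed(seed, 1L),
                                  series = derive_seed(seed, 2L)),
                     c(p1, p2), t0)
  p3 <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(mf, p3)
  invisible(c(schedule = p1, series = p2, manifest = p3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a model to a series CSV and report the results
#'
#' Reads a long-format series CSV, fits the requested model
#' implementation, and reports the drift, stationary covariance, and the
#' autocorrelation with 95% CI at the requested lags. Lags may be given
#' in blocks, minutes or hours (converted through `block_minutes`).
#'
#' @param series_path Path to the series CSV.
#' @param mi Model implementation (`"MI1"`-`"MI4"`, or `"OLS"` for the
#'   least-squares baseline with nighttime masking).
#' @param deltas Lags at which to report the autocorrelation.
#' @param delta_unit Unit of `deltas` (`"blocks"`, `"minutes"`,
#'   `"hours"`).
#' @param block_minutes Block length in minutes for unit conversion.
#' @param overnight_delta MI2 overnight interval (blocks).
#' @param rounding_precision MI3 rounding grid (blocks).
#' @param out Optional path for a flat key-value report file.
#' @return Invisibly, a list with the fit and the `phi_estimate`s.
#' @export
cli_fit <- function(series_path, mi = "MI4", deltas = 1,
                    delta_unit = "blocks", block_minutes = 90,
                    overnight_delta = 7, rounding_precision = 1 / 6,
                    out = NULL) {
  series <- read_series_csv(series_path, block_minutes = block_minutes)
  deltas_blocks <- convert_time(deltas, from = delta_unit, to = "blocks",
                                block_minutes = block_minutes)
  lines <- c(sprintf("series: %s", series_path),
             sprintf("n_obs: %d", nrow(series)),
             sprintf("model: %s", mi))
  if (identical(mi, "OLS")) {
    fit <- fit_ar_ols(series)
    for (i in seq_len(fit$K)) for (j in seq_len(fit$K)) {
      lines <- c(lines, sprintf("phi[%d,%d]: %.6f ci: [%.6f, %.6f]", i, j,
                                fit$Phi_hat[i, j], fit$ci_low[i, j],
                                fit$ci_high[i, j]))
    }
    result <- list(fit = fit)
  } else {
    spec <- interval_spec(mi, rounding_precision = rounding_precision,
                          overnight_delta = overnight_delta)
    fit <- fit_ct_ml(series, spec)
    lines <- c(lines, sprintf("converged: %s", fit$converged))
    if (fit$converged) {
      lines <- c(lines, sprintf("loglik: %.6f", fit$loglik),
                 sprintf("B[%d,%d]: %.6f",
                         rep(seq_len(fit$K), fit$K),
                         rep(seq_len(fit$K), each = fit$K),
                         as.numeric(fit$B_hat)))
      phis <- lapply(deltas_blocks, function(d) phi_ci(fit, d))
      for (ph in phis) {
        for (i in seq_len(fit$K)) for (j in seq_len(fit$K)) {
          lines <- c(lines,
                     sprintf("phi[%d,%d](delta=%g): %.6f ci: [%.6f, %.6f]",
                             i, j, ph$delta, ph$phi[i, j], ph$ci_low[i, j],
                             ph$ci_high[i, j]))
        }
      }
      result <- list(fit = fit, phi = phis)
    } else {
      result <- list(fit = fit)
    }
  }
  if (!is.null(out)) writeLines(lines, out)
  invisible(result)
}

#' Run a bias study from a configuration file
#'
#' Reads a YAML grid configuration (`phis`, `n_days_long`,
#' `n_days_short`, `n_reps_short`, `min_intervals`, `modes`, `seed`,
#' optional `bivariate: true` for the bivariate reference truth) and runs
#' [run_full_study()], writing its tables and manifest to `out_dir`.
#'
#' @param config_path Path to the YAML configuration.
#' @param out_dir Output directory.
#' @return The `bias_table`, invisibly.
#' @export
cli_bias_study <- function(config_path, out_dir) {
  cfg <- read_run_config(config_path)
  biv <- NULL
  if (isTRUE(cfg$bivariate)) {
    biv <- ct_params(matrix(c(-1.0541, -0.2188, -0.1554, -1.3021), 2, 2),
                     matrix(c(1, -0.5155, -0.5155, 1), 2, 2))
  }
  tab <- run_full_study(
    phis = unlist(cfg$phis) %||% seq(0.1, 0.9, by = 0.1),
    n_days_long = cfg$n_days_long %||% 1000,
    n_days_short = cfg$n_days_short %||% 10,
    n_reps_short = cfg$n_reps_short %||% 1000,
    n_reps_long = cfg$n_reps_long %||% 1,
    min_intervals = unlist(cfg$min_intervals) %||% c(0, 1 / 6),
    bivariate_ct = biv,
    modes = unlist(cfg$modes) %||% c("MI1", "MI2", "MI3", "MI4"),
    seed = cfg$seed %||% 1,
    out_dir = out_dir,
    verbose = isTRUE(cfg$verbose))
  invisible(tab)
}
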