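#' A single cell of the bias simulation grid
#'
#' Bundles the data-generating truth, the design size and the model
#' implementations to compare. The default design mirrors the study
#' conditions used throughout the package: 10 beeps per day in
#' back-to-back 90-min blocks over a 15-h day.
#'
#' @param phi Univariate true autocorrelation at `delta = 1` (ignored when
#'   `ct` is given).
#' @param ct A [ct_params()] truth (takes precedence over `phi`).
#' @param n_days Days per simulated series (10 for short, 1000 for long).
#' @param n_reps Number of replicate series (1 for the long-series mode).
#' @param min_interval_blocks Minimum same-day interval (0 or 1/6).
#' @param modes Character vector of model implementations to fit.
#' @param overnight_delta Overnight interval assumed by MI2.
#' @param seed Condition master seed; replicate seeds are derived from it.
#' @return An object of class `bias_condition`.
#' @export
bias_condition <- function(phi = NULL, ct = NULL, n_days = 10, n_reps = 1,
                           min_interval_blocks = 0,
                           modes = c("MI1", "MI2", "MI3", "MI4"),
                           overnight_delta = 7, seed = 1) {
  if (is.null(ct)) {
    stopifnot(is.numeric(phi), phi > 0, phi < 1)
    ct <- ct_params(log(phi), 1)
  }
  stopifnot(n_reps >= 1, all(modes %in% c("MI1", "MI2", "MI3", "MI4")))
  structure(list(ct = ct, n_days = n_days, n_reps = n_reps,
                 min_interval_blocks = min_interval_blocks,
                 modes = modes, overnight_delta = overnight_delta,
                 seed = as.integer(seed)),
            class = "bias_condition")
}

#' Run all replicates of one bias condition
#'
#' For every replicate, a fresh schedule and series are generated from a
#' seed derived from the condition seed, all requested model
#' implementations are fit, and the implied `Phi` at `delta = 1` is
#' recorded per entry. Nonconverged fits are kept in the table with
#' `converged = FALSE` and excluded later by [summarize_bias()].
#'
#' @param cond A [bias_condition()].
#' @return A data frame with columns `rep`, `mi`, `row`, `col`,
#'   `estimate`, `converged`, carrying the condition as an attribute.
#' @export
run_condition <- function(cond) {
  stopifnot(inherits(cond, "bias_condition"))
  K <- cond$ct$K
  out <- vector("list", cond$n_reps * length(cond$modes))
  idx <- 0L
  any_conv <- FALSE
  for (r in seq_len(cond$n_reps)) {
    sseed <- derive_seed(cond$seed, 2L * r - 1L)
    yseed <- derive_seed(cond$seed, 2L * r)
    cfg <- schedule_config(n_days = cond$n_days,
                           min_interval_blocks = cond$min_interval_blocks,
                           seed = sseed)
    series <- simulate_cvar(cond$ct, generate_schedule(cfg), seed = yseed)
    for (mi in cond$modes) {
      spec <- interval_spec(mi, overnight_delta = cond$overnight_delta)
      fit <- fit_ct_ml(series, spec)
      Phi <- if (fit$converged) phi_of_delta(fit$B_hat, 1) else
        matrix(NA_real_, K, K)
      if (fit$converged) any_conv <- TRUE
      idx <- idx + 1L
      out[[idx]] <- data.frame(rep = r, mi = mi,
                               row = rep(seq_len(K), K),
                               col = rep(seq_len(K), each = K),
                               estimate = as.numeric(Phi),
                               converged = fit$converged)
    }
  }
  if (!any_conv) esmct_error("no replicate converged", "esmct_nonconverged")
  structure(do.call(rbind, out), condition = cond)
}

#' Summarize estimation bias per model implementation and Phi entry
#'
#' Computes, over converged replicates: the mean absolute bias
#' (mean estimate minus truth), the relative bias (absolute bias divided
#' by the absolute true value), and — meaningful when `n_reps > 1` — the
#' median estimation error and median relative error. For a single long
#' series the "bias" columns are a single-realization estimation error
#' and should be read as such.
#'
#' @param estimates Output of [run_condition()] (or a data frame with the
#'   same columns).
#' @param truth True `Phi` matrix at `delta = 1` (scalar allowed).
#' @return A `bias_table` data frame with one row per (mi, entry).
#' @export
summarize_bias <- function(estimates, truth) {
  truth <- as.matrix(truth)
  K <- nrow(truth)
  rows <- list()
  for (mi in unique(estimates$mi)) {
    for (i in seq_len(K)) for (j in seq_len(K)) {
      e <- estimates[estimates$mi == mi & estimates$row == i &
                       estimates$col == j & estimates$converged, "estimate"]
      tv <- truth[i, j]
      if (tv == 0) {
        esmct_error("relative bias undefined for a zero true entry",
                    "esmct_zero_truth")
      }
      err <- e - tv
      rows[[length(rows) + 1L]] <- data.frame(
        mi = mi, row = i, col = j, true_value = tv,
        mean_estimate = mean(e),
        absolute_bias = mean(e) - tv,
        relative_bias = (mean(e) - tv) / abs(tv),
        median_error = stats::median(err),
        median_relative_error = stats::median(err / abs(tv)),
        n_converged = length(e))
    }
  }
  structure(do.call(rbind, rows), class = c("bias_table", "data.frame"))
}

#' Run a full bias study grid
#'
#' Orchestrates the simulation grid: each univariate truth x series
#' length x minimum-interval setting (and optionally a bivariate truth)
#' is run through [run_condition()] and summarized. Per-truth tables, an
#' averaged-over-truths summary (mean of the absolute values of the
#' per-truth biases, and the signed mean, since either reading of
#' "averaged ignoring sign" may be wanted), and a run manifest are
#' written when `out_dir` is given.
#'
#' @param phis Univariate true autocorrelations at `delta = 1`.
#' @param n_days_long,n_days_short Series lengths in days.
#' @param n_reps_short Replicates for the short-series conditions.
#' @param n_reps_long Replicates for the long-series conditions (1
#'   reproduces the single-realization reading; more separates estimand
#'   bias from realization noise).
#' @param min_intervals Minimum-interval settings to cross with the grid.
#' @param bivariate_ct Optional [ct_params()] for a bivariate arm.
#' @param modes Model implementations to fit.
#' @param seed Master seed.
#' @param out_dir Optional output directory for TSV tables and manifest.
#' @param verbose Print per-condition progress.
#' @return A `bias_table` over all conditions (with condition columns
#'   `truth_label`, `n_days`, `n_reps`, `min_interval`).
#' @export
run_full_study <- function(phis = seq(0.1, 0.9, by = 0.1),
                           n_days_long = 1000, n_days_short = 10,
                           n_reps_short = 1000, n_reps_long = 1,
                           min_intervals = c(0, 1 / 6),
                           bivariate_ct = NULL,
                           modes = c("MI1", "MI2", "MI3", "MI4"),
                           seed = 1, out_dir = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  grid <- list()
  ci <- 0L
  all_rows <- list()
  add_arm <- function(label, ct, n_days, n_reps, minint, cseed) {
    cond <- bias_condition(ct = ct, n_days = n_days, n_reps = n_reps,
                           min_interval_blocks = minint, modes = modes,
                           seed = cseed)
    est <- run_condition(cond)
    tb <- summarize_bias(est, phi_of_delta(ct, 1))
    tb$truth_label <- label
    tb$n_days <- n_days
    tb$n_reps <- n_reps
    tb$min_interval <- minint
    tb
  }
  for (minint in min_intervals) {
    for (arm in c("long", "short")) {
      n_days <- if (arm == "long") n_days_long else n_days_short
      n_reps <- if (arm == "long") n_reps_long else n_reps_short
      for (phi in phis) {
        ci <- ci + 1L
        if (verbose) {
          message(sprintf("condition %d: phi=%.1f %s min=%g", ci, phi, arm,
                          minint))
        }
        all_rows[[length(all_rows) + 1L]] <-
          add_arm(sprintf("phi=%.1f", phi), ct_params(log(phi), 1),
                  n_days, n_reps, minint, derive_seed(seed, ci))
      }
      if (!is.null(bivariate_ct)) {
        ci <- ci + 1L
        if (verbose) message(sprintf("condition %d: bivariate %s min=%g",
                                     ci, arm, minint))
        all_rows[[length(all_rows) + 1L]] <-
          add_arm("bivariate", bivariate_ct, n_days, n_reps, minint,
                  derive_seed(seed, ci))
      }
    }
  }
  tab <- structure(do.call(rbind, all_rows),
                   class = c("bias_table", "data.frame"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    f <- file.path(out_dir, "bias_table.tsv")
    utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    # averaged-over-truths summaries per arm (both readings of the average)
    uni <- tab[tab$truth_label != "bivariate" & tab$row == 1 & tab$col == 1, ]
    if (nrow(uni)) {
      agg <- do.call(rbind, lapply(split(uni, list(uni$mi, uni$n_days,
                                                   uni$min_interval),
                                         drop = TRUE), function(g) {
        data.frame(mi = g$mi[1], n_days = g$n_days[1],
                   min_interval = g$min_interval[1],
                   mean_abs_bias = mean(abs(g$absolute_bias)),
                   mean_abs_relative_bias = mean(abs(g$relative_bias)),
                   mean_signed_bias = mean(g$absolute_bias),
                   mean_signed_relative_bias = mean(g$relative_bias))
      }))
      f <- file.path(out_dir, "bias_averaged_over_truths.tsv")
      utils::write.table(agg, f, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    manifest <- list(seed = seed, phis = phis,
                     n_days = c(long = n_days_long, short = n_days_short),
                     n_reps = c(long = n_reps_long, short = n_reps_short),
                     min_intervals = min_intervals, modes = modes,
                     package_version = as.character(utils::packageVersion("esmct")),
                     started = format(t0), finished = format(Sys.time()),
                     elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                       units = "secs")),
                     outputs = basename(files))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  tab
}
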