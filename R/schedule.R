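#' Configuration of a signal-contingent beep schedule
#'
#' Describes a measurement design in which each waking day is divided into
#' `beeps_per_day` back-to-back blocks of `block_minutes` each, and one
#' beep is placed uniformly at random within every block. Optionally a
#' minimum interval (as a fraction of a block) is enforced between
#' consecutive beeps on the same day; overnight gaps are always long and
#' never restricted.
#'
#' @param n_days Number of measurement days.
#' @param beeps_per_day Number of beeps (= blocks) per day.
#' @param block_minutes Block length in minutes (90 by default).
#' @param day_start_hour Clock hour at which the first block starts.
#' @param day_end_hour Clock hour at which the last block ends; derived
#'   from the block structure when `NULL`.
#' @param min_interval_blocks Minimum allowed same-day interval, as a
#'   fraction of one block (0 = unrestricted; 1/6 = the 15-min rule for
#'   90-min blocks). Must be < 1.
#' @param seed Integer seed from which all schedule randomness derives.
#' @return An object of class `schedule_config`.
#' @export
#' @examples
#' cfg <- schedule_config(n_days = 10, seed = 1)
#' sch <- generate_schedule(cfg)
#' head(as.data.frame(sch))
schedule_config <- function(n_days = 10, beeps_per_day = 10,
                            block_minutes = 90, day_start_hour = 9,
                            day_end_hour = NULL, min_interval_blocks = 0,
                            seed = 1) {
  stopifnot(n_days >= 1, beeps_per_day >= 1, block_minutes > 0,
            min_interval_blocks >= 0)
  if (min_interval_blocks >= 1) {
    esmct_error("minimum interval must be shorter than one block",
                "esmct_infeasible_schedule")
  }
  span_hours <- beeps_per_day * block_minutes / 60
  if (is.null(day_end_hour)) day_end_hour <- day_start_hour + span_hours
  if (span_hours > (day_end_hour - day_start_hour) + 1e-9) {
    esmct_error("blocks do not fit into the waking day",
                "esmct_infeasible_schedule")
  }
  structure(list(n_days = n_days, beeps_per_day = beeps_per_day,
                 block_minutes = block_minutes,
                 day_start_hour = day_start_hour,
                 day_end_hour = day_end_hour,
                 min_interval_blocks = min_interval_blocks,
                 seed = as.integer(seed)),
            class = "schedule_config")
}

new_beep_schedule <- function(df, config) {
  stopifnot(all(diff(df$time_blocks) > 0))
  structure(df, config = config, class = c("beep_schedule", "data.frame"))
}

#' Generate a signal-contingent beep schedule
#'
#' Places one uniform beep per block per day, in block time units
#' (`delta = 1` is one block; `t = 0` is the start of day 1's first block).
#' A full 24-h day spans `24 * 60 / block_minutes` block units, so the
#' unobserved nighttime plus within-day remainders appear as long
#' overnight gaps between the last beep of one day and the first beep of
#' the next. When a minimum same-day interval is requested, the later beep
#' of any offending pair is redrawn within its block until the constraint
#' holds (rejection sampling), preserving per-block uniformity conditional
#' on feasibility.
#'
#' @param config A [schedule_config()].
#' @return A `beep_schedule`: a data frame with columns `day`,
#'   `beep_index`, `time_blocks` and `is_day_first`, plus the config as an
#'   attribute.
#' @export
generate_schedule <- function(config) {
  stopifnot(inherits(config, "schedule_config"))
  n_days <- config$n_days
  bpd <- config$beeps_per_day
  minint <- config$min_interval_blocks
  day_len <- 24 * 60 / config$block_minutes  # one calendar day in blocks
  set.seed(config$seed)
  times <- numeric(n_days * bpd)
  k <- 0L
  for (d in seq_len(n_days)) {
    u <- stats::runif(bpd)
    if (minint > 0 && bpd > 1L) {
      for (j in 2:bpd) {
        # same-day gap is 1 + u[j] - u[j-1]; redraw the later beep only
        while (1 + u[j] - u[j - 1] < minint) u[j] <- stats::runif(1)
      }
    }
    times[k + seq_len(bpd)] <- (d - 1) * day_len + (seq_len(bpd) - 1) + u
    k <- k + bpd
  }
  df <- data.frame(day = rep(seq_len(n_days), each = bpd),
                   beep_index = rep(seq_len(bpd), n_days),
                   time_blocks = times,
                   is_day_first = rep(c(TRUE, rep(FALSE, bpd - 1L)), n_days))
  new_beep_schedule(df, config)
}

#' Generate an empirical-style response schedule
#'
#' Emulates a week-long adolescent ESM design: 7 days with up to 8
#' prompts between 8 AM and 10 PM — one morning prompt in 8–10 AM, six
#' prompts in back-to-back blocks between 10 AM and 8 PM, and one evening
#' prompt in 8–10 PM. Participants may answer with a delay, bounded by the
#' per-block response window (2 h for the morning prompt, 1.5 h during the
#' day, 4 h in the evening), and may miss prompts entirely, so recorded
#' times are response times, not beep times, and short realized intervals
#' occur. Times are returned in block units of `block_minutes` (105 min by
#' default, the design's intended mean interval).
#'
#' @param n_days Number of days (7 by default).
#' @param block_minutes Time unit used for `time_blocks` (105 by default).
#' @param delay_config List with elements `dist` (only `"exponential"` is
#'   implemented) and `mean_minutes` (mean response delay before window
#'   truncation); the delay distribution of real participants is unknown,
#'   so it is exposed as configuration rather than asserted.
#' @param nonresponse_prob Per-beep probability of no response.
#' @param seed Integer seed.
#' @return A `beep_schedule` of response times (block units), with columns
#'   as in [generate_schedule()].
#' @export
#' @examples
#' sch <- generate_empirical_schedule(seed = 3)
#' mean(diff(sch$time_blocks)[diff(sch$day) == 0]) * 105  # mean interval, min
generate_empirical_schedule <- function(n_days = 7, block_minutes = 105,
                                        delay_config = list(dist = "exponential",
                                                            mean_minutes = 15),
                                        nonresponse_prob = 0.1,
                                        seed = 1) {
  stopifnot(n_days >= 1, nonresponse_prob >= 0, nonresponse_prob < 1)
  if (!identical(delay_config$dist, "exponential")) {
    esmct_error("only exponential response delays are implemented",
                "esmct_invalid_config")
  }
  # block starts/ends and response windows, minutes after midnight
  day_blocks <- cbind(start = 600 + (0:5) * 100, end = 600 + (1:6) * 100)
  blocks <- rbind(c(480, 600), day_blocks, c(1200, 1320))
  windows <- c(120, rep(90, 6), 240)
  mean_delay <- delay_config$mean_minutes
  if (mean_delay < 0 || mean_delay > min(windows)) {
    esmct_error("mean response delay exceeds the shortest response window",
                "esmct_invalid_config")
  }
  set.seed(as.integer(seed))
  rows <- list()
  prev_resp <- -Inf
  for (d in seq_len(n_days)) {
    day0 <- (d - 1) * 24 * 60  # minutes since study start at midnight day 1
    for (b in seq_len(nrow(blocks))) {
      if (stats::runif(1) < nonresponse_prob) next
      beep <- day0 + stats::runif(1, blocks[b, 1], blocks[b, 2])
      resp <- NA_real_
      for (try in 1:50) {
        delay <- stats::rexp(1, rate = 1 / mean_delay)
        if (delay <= windows[b] && beep + delay > prev_resp) {
          resp <- beep + delay
          break
        }
      }
      if (is.na(resp)) next  # window closed before the previous response; missed
      prev_resp <- resp
      rows[[length(rows) + 1L]] <- c(d, b, resp)
    }
  }
  m <- do.call(rbind, rows)
  df <- data.frame(day = as.integer(m[, 1]), beep_index = as.integer(m[, 2]),
                   time_blocks = m[, 3] / block_minutes)
  df$is_day_first <- c(TRUE, diff(df$day) != 0)
  cfg <- schedule_config(n_days = n_days, beeps_per_day = 8,
                         block_minutes = block_minutes, day_start_hour = 8,
                         day_end_hour = 22, seed = seed)
  cfg$delay_config <- delay_config
  cfg$nonresponse_prob <- nonresponse_prob
  new_beep_schedule(df, cfg)
}

#' @export
print.beep_schedule <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Beep schedule: %d beeps over %d day(s), block = %g min\n",
              nrow(x), length(unique(x$day)), cfg$block_minutes))
  gaps <- diff(x$time_blocks)[diff(x$day) == 0]
  if (length(gaps)) {
    cat(sprintf("  same-day gaps: mean %.3f, min %.3f, max %.3f (blocks)\n",
                mean(gaps), min(gaps), max(gaps)))
  }
  invisible(x)
}

#' Write or read a beep schedule as long-format CSV
#'
#' Columns: `person_id`, `day`, `beep_index`, `time_blocks`,
#' `time_minutes`.
#'
#' @param schedule A `beep_schedule`.
#' @param path Output file path.
#' @param person_id Identifier recorded in the CSV.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path, person_id = "p1") {
  cfg <- attr(schedule, "config")
  out <- data.frame(person_id = person_id,
                    day = schedule$day,
                    beep_index = schedule$beep_index,
                    time_blocks = schedule$time_blocks,
                    time_minutes = schedule$time_blocks * cfg$block_minutes)
  utils::write.csv(format(out, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
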