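#' Exact simulation of a CVAR(1) process at scheduled beep times
#'
#' Draws the first observation from the stationary distribution
#' `N(0, Sigma_y)` and every later observation from the exact transition
#' `y_i = expm(B * delta_i) y_{i-1} + eps_i`,
#' `eps_i ~ N(0, Sigma_y - expm(B delta_i) Sigma_y expm(B' delta_i))`,
#' where `delta_i` is the true elapsed interval between beeps — including
#' the long overnight gaps, so the process continues unobserved through
#' the night and consecutive days remain (weakly) connected. Because the
#' transition is the exact solution of the stochastic differential
#' equation, no discretization error is introduced at any interval length.
#'
#' @param ct A [ct_params()] object (stationary).
#' @param schedule A `beep_schedule` from [generate_schedule()] or
#'   [generate_empirical_schedule()].
#' @param seed Integer seed for the innovation draws.
#' @param person_id Identifier stored with the series.
#' @return An `esm_series`: a data frame with columns `person_id`, `day`,
#'   `time_blocks` and `y1` ... `yK`, carrying the generating parameters
#'   and seed as attributes.
#' @export
#' @examples
#' ct <- ct_params(log(0.4), 1)
#' sch <- generate_schedule(schedule_config(n_days = 5, seed = 1))
#' ser <- simulate_cvar(ct, sch, seed = 2)
#' nrow(ser)  # 50
simulate_cvar <- function(ct, schedule, seed, person_id = "p1") {
  stopifnot(inherits(ct, "ct_params"), inherits(schedule, "beep_schedule"))
  K <- ct$K
  times <- schedule$time_blocks
  n <- length(times)
  stopifnot(n >= 1)
  deltas <- diff(times)
  set.seed(as.integer(seed))
  Ly <- t(chol(ct$Sigma_y))
  Y <- matrix(0, n, K)
  Y[1, ] <- Ly %*% stats::rnorm(K)
  if (n > 1L) {
    # cache transition matrix and innovation Cholesky per unique interval
    key <- match(round(deltas, 12), unique(round(deltas, 12)))
    uniq <- unique(round(deltas, 12))
    trans <- lapply(uniq, function(d) {
      E <- phi_of_delta(ct, d)
      S <- make_psd(ct$Sigma_y - E %*% ct$Sigma_y %*% t(E))
      Lc <- if (K == 1L) matrix(sqrt(S[1, 1]), 1, 1) else {
        ce <- tryCatch(t(chol(S)), error = function(e) NULL)
        if (is.null(ce)) {
          ed <- eigen(S, symmetric = TRUE)
          ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), K)
        } else ce
      }
      list(E = E, L = Lc)
    })
    Z <- matrix(stats::rnorm((n - 1L) * K), n - 1L, K)
    for (i in 2:n) {
      tr <- trans[[key[i - 1L]]]
      Y[i, ] <- tr$E %*% Y[i - 1L, ] + tr$L %*% Z[i - 1L, ]
    }
  }
  df <- data.frame(person_id = person_id, day = schedule$day,
                   time_blocks = times)
  for (k in seq_len(K)) df[[paste0("y", k)]] <- Y[, k]
  structure(df, truth = ct, seed = as.integer(seed),
            config = attr(schedule, "config"),
            class = c("esm_series", "data.frame"))
}

#' @export
print.esm_series <- function(x, ...) {
  K <- sum(grepl("^y[0-9]+$", names(x)))
  cat(sprintf("ESM time series: %d observations, %d variable(s), %d day(s)\n",
              nrow(x), K, length(unique(x$day))))
  invisible(x)
}

series_values <- function(series) {
  as.matrix(series[, grep("^y[0-9]+$", names(series)), drop = FALSE])
}

#' Write a time series as long-format CSV
#'
#' Columns `person_id`, `day`, `time_blocks`, `y1` ... `yK`; values keep
#' 15 significant digits so a write/read round trip is lossless well
#' beyond 12 digits.
#'
#' @param series An `esm_series` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  cols <- c("person_id", "day", "time_blocks",
            grep("^y[0-9]+$", names(series), value = TRUE))
  out <- as.data.frame(series)[, cols]
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format time-series CSV
#'
#' Accepts a time column in block units (`time_blocks`), minutes
#' (`time_minutes`) or hours (`time_hours`); non-block units are converted
#' using `block_minutes`.
#'
#' @param path CSV path.
#' @param block_minutes Block length in minutes, used to convert minute or
#'   hour time columns to block units.
#' @return An `esm_series` data frame.
#' @export
read_series_csv <- function(path, block_minutes = 90) {
  if (!file.exists(path)) {
    esmct_error(paste("file not found:", path), "esmct_io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_blocks" %in% names(df)) {
    if ("time_minutes" %in% names(df)) {
      df$time_blocks <- df$time_minutes / block_minutes
    } else if ("time_hours" %in% names(df)) {
      df$time_blocks <- df$time_hours * 60 / block_minutes
    } else {
      esmct_error("no time column (time_blocks / time_minutes / time_hours)",
                  "esmct_io")
    }
  }
  if (!"day" %in% names(df)) df$day <- 1L
  if (!"person_id" %in% names(df)) df$person_id <- "p1"
  if (any(diff(df$time_blocks) <= 0)) {
    esmct_error("times must be strictly increasing", "esmct_nonmonotone")
  }
  structure(df, class = c("esm_series", "data.frame"))
}
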