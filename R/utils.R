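#' Derive a reproducible sub-stream seed
#'
#' Deterministically maps a master seed and a stream index to a new seed,
#' so that any replicate of a larger study can be reproduced in isolation.
#' The result is always a positive integer below 2^31.
#'
#' @param seed Master seed (single integer-valued number).
#' @param index Stream index (single non-negative integer-valued number).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 1)
#' derive_seed(1, 2)
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # affine hash in double precision; all intermediates < 2^53 so exact
  m <- 2147483647  # 2^31 - 1
  s <- (abs(seed) %% m)
  v <- (s * 48271 + index * 16807 + 1) %% m
  as.integer(v + 1)
}

#' Convert times between minutes, hours and block units
#'
#' The package's canonical internal time unit is the design block
#' (`delta = 1` is one block). I/O accepts minutes or hours and converts
#' given the block length.
#'
#' @param x Numeric vector of times or intervals.
#' @param from,to One of `"blocks"`, `"minutes"`, `"hours"`.
#' @param block_minutes Length of one block in minutes.
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' convert_time(1.75, from = "hours", to = "blocks", block_minutes = 105)
convert_time <- function(x, from = c("blocks", "minutes", "hours"),
                         to = c("blocks", "minutes", "hours"),
                         block_minutes = 90) {
  from <- match.arg(from)
  to <- match.arg(to)
  stopifnot(is.numeric(block_minutes), block_minutes > 0)
  mins <- switch(from,
    blocks = x * block_minutes,
    minutes = x,
    hours = x * 60)
  switch(to,
    blocks = mins / block_minutes,
    minutes = mins,
    hours = mins / 60)
}

# internal: error with a dedicated class so callers can condition on it
esmct_error <- function(msg, class) {
  stop(structure(class = c(class, "esmct_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# internal: symmetrize and clip tiny negative eigenvalues of a covariance
# matrix; negativity beyond `tol` is a genuine modeling error.
make_psd <- function(M, tol = 1e-10) {
  M <- (M + t(M)) / 2
  if (nrow(M) == 1L) {
    if (M[1, 1] < -tol) esmct_error("covariance is negative beyond tolerance",
                                    "esmct_not_psd")
    return(matrix(max(M[1, 1], 0), 1, 1))
  }
  e <- eigen(M, symmetric = TRUE)
  if (any(e$values < -tol)) {
    esmct_error("covariance has eigenvalues negative beyond tolerance",
                "esmct_not_psd")
  }
  v <- pmax(e$values, 0)
  M2 <- e$vectors %*% (v * t(e$vectors))
  (M2 + t(M2)) / 2
}
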