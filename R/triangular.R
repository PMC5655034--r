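#' Triangular law of between-beep intervals
#'
#' When one beep is placed uniformly at random inside each back-to-back
#' block of a signal-contingent schedule, the interval between two
#' consecutive beeps is the sum of two independent uniforms and therefore
#' follows a triangular distribution with lower bound 0, upper bound twice
#' the block length, and mode equal to the block length.
#'
#' @param lower,upper,mode Bounds and mode of the triangular distribution,
#'   in any time unit; must satisfy `lower <= mode <= upper`.
#' @return An object of class `triangular_law`.
#' @export
#' @examples
#' law <- triangular_law(0, 180, 90)   # 90-min blocks, interval in minutes
#' triangular_stats(law)
triangular_law <- function(lower, upper, mode) {
  stopifnot(is.numeric(lower), is.numeric(upper), is.numeric(mode),
            length(lower) == 1L, length(upper) == 1L, length(mode) == 1L)
  if (!(lower <= mode && mode <= upper)) {
    esmct_error("triangular law requires lower <= mode <= upper",
                "esmct_invalid_law")
  }
  structure(list(lower = lower, upper = upper, mode = mode),
            class = "triangular_law")
}

#' Triangular law implied by a block length
#'
#' @param block Block length (time units).
#' @return A `triangular_law` with bounds `(0, 2 * block)` and mode `block`.
#' @export
block_interval_law <- function(block) {
  triangular_law(0, 2 * block, block)
}

#' Mean and variance of a triangular interval law
#'
#' The mean is `(a + b + c) / 3` and the variance
#' `(a^2 + b^2 + c^2 - ab - ac - bc) / 18`; for the within-block design
#' these reduce to the block length and block^2 / 6.
#'
#' @param law A [triangular_law()].
#' @return A list with elements `mean` and `variance`.
#' @export
triangular_stats <- function(law) {
  stopifnot(inherits(law, "triangular_law"))
  a <- law$lower; b <- law$upper; c <- law$mode
  list(mean = (a + b + c) / 3,
       variance = (a^2 + b^2 + c^2 - a * b - a * c - b * c) / 18)
}

#' Triangular cumulative distribution function
#'
#' @param q Numeric vector of quantiles.
#' @param law A [triangular_law()].
#' @return `P(X <= q)` under the law.
#' @export
triangular_cdf <- function(q, law) {
  stopifnot(inherits(law, "triangular_law"))
  a <- law$lower; b <- law$upper; c <- law$mode
  if (a == b) return(as.numeric(q >= a))  # point mass
  p <- numeric(length(q))
  p[q >= b] <- 1
  i <- q > a & q <= c
  if (c > a) p[i] <- (q[i] - a)^2 / ((b - a) * (c - a))
  i <- q > c & q < b
  if (b > c) p[i] <- 1 - (b - q[i])^2 / ((b - a) * (b - c))
  p
}

#' @export
print.triangular_law <- function(x, ...) {
  st <- triangular_stats(x)
  cat(sprintf("Triangular interval law on [%g, %g], mode %g (mean %g, variance %g)\n",
              x$lower, x$upper, x$mode, st$mean, st$variance))
  invisible(x)
}
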