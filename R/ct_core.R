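#' Continuous-time (C)VAR(1) parameters
#'
#' Parameterizes the Ornstein-Uhlenbeck / CVAR(1) process by its drift
#' matrix `B` (per block unit) and stationary covariance `Sigma_y`.
#' Stationarity requires all eigenvalues of `B` to have negative real
#' part, and `Sigma_y` must be symmetric positive definite. The intercept
#' `a` is zero for the centered analyses the package performs, but is kept
#' for completeness.
#'
#' @param B Drift matrix (scalar for a univariate process).
#' @param Sigma_y Stationary covariance matrix (scalar variance allowed).
#' @param a Intercept vector (default zero).
#' @return An object of class `ct_params`.
#' @export
#' @examples
#' ct_params(B = log(0.4), Sigma_y = 1)                    # univariate
#' phi_of_delta(ct_params(log(0.4), 1), delta = 2)          # 0.4^2
ct_params <- function(B, Sigma_y, a = NULL) {
  B <- as.matrix(B)
  Sigma_y <- as.matrix(Sigma_y)
  K <- nrow(B)
  stopifnot(ncol(B) == K, all(dim(Sigma_y) == K))
  if (is.null(a)) a <- rep(0, K)
  ev <- eigen(B, only.values = TRUE)$values
  if (any(Re(ev) >= 0)) {
    esmct_error("drift matrix B must have eigenvalues with negative real part",
                "esmct_nonstationary")
  }
  if (max(abs(Sigma_y - t(Sigma_y))) > 1e-8 ||
      any(eigen((Sigma_y + t(Sigma_y)) / 2, symmetric = TRUE,
                only.values = TRUE)$values <= 0)) {
    esmct_error("Sigma_y must be symmetric positive definite",
                "esmct_invalid_covariance")
  }
  structure(list(K = K, B = B, Sigma_y = (Sigma_y + t(Sigma_y)) / 2,
                 a = as.numeric(a)),
            class = "ct_params")
}

#' Discrete-time (V)AR(1) parameters for a named interval
#'
#' @param Phi Autoregression matrix (scalar allowed) applying to interval
#'   `delta`.
#' @param c Intercept vector (default zero).
#' @param Sigma_eps Innovation covariance for interval `delta` (optional).
#' @param delta The interval `Phi` refers to, in block units.
#' @return An object of class `dt_params`.
#' @export
dt_params <- function(Phi, c = NULL, Sigma_eps = NULL, delta = 1) {
  Phi <- as.matrix(Phi)
  K <- nrow(Phi)
  stopifnot(ncol(Phi) == K, delta > 0)
  if (is.null(c)) c <- rep(0, K)
  if (max(abs(eigen(Phi, only.values = TRUE)$values)) >= 1) {
    esmct_error("Phi must have spectral radius below 1 for stationarity",
                "esmct_nonstationary")
  }
  if (!is.null(Sigma_eps)) {
    Sigma_eps <- make_psd(as.matrix(Sigma_eps))
    stopifnot(all(dim(Sigma_eps) == K))
  }
  structure(list(K = K, Phi = Phi, c = as.numeric(c),
                 Sigma_eps = Sigma_eps, delta = delta),
            class = "dt_params")
}

#' @export
print.ct_params <- function(x, ...) {
  cat(sprintf("CVAR(1) parameters (K = %d)\nDrift B:\n", x$K))
  print(round(x$B, 4))
  cat("Stationary covariance Sigma_y:\n")
  print(round(x$Sigma_y, 4))
  invisible(x)
}

as_drift <- function(object) {
  if (inherits(object, "ct_params")) object$B else as.matrix(object)
}

#' Autoregression matrix implied at an interval
#'
#' The continuous-time model implies, for any elapsed interval `delta`,
#' the regression matrix `Phi(delta) = expm(B * delta)`; in the univariate
#' case this is `exp(B * delta) = phi(1)^delta`, the lag-scaling rule.
#'
#' @param object A [ct_params()] object or a drift matrix/scalar `B`.
#' @param delta Non-negative interval in block units.
#' @return The K x K matrix `expm(B * delta)` (1 x 1 for univariate input).
#' @export
#' @examples
#' phi_of_delta(log(0.1), 0.5)   # 0.1^0.5 = 0.32 (2 dp)
phi_of_delta <- function(object, delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L)
  if (delta < 0) esmct_error("delta must be non-negative", "esmct_domain")
  B <- as_drift(object)
  if (nrow(B) == 1L) return(matrix(exp(B[1, 1] * delta), 1, 1))
  as.matrix(Matrix::expm(B * delta))
}

#' Drift matrix recovered from an autoregression matrix
#'
#' Inverts `Phi = expm(B * delta)` through the principal matrix
#' logarithm. This is only valid when `Phi` admits a real logarithm whose
#' spectrum has negative real part (univariate: `0 < phi < 1`); otherwise
#' the discrete-time parameters have no continuous-time representation
#' and an error of class `esmct_no_ct_representation` is raised.
#'
#' @param object A [dt_params()] object or an autoregression matrix /
#'   scalar.
#' @param delta Interval that `Phi` refers to (taken from a `dt_params`
#'   object when available).
#' @return The drift matrix `B = logm(Phi) / delta`.
#' @export
#' @examples
#' drift_of_phi(0.9)         # log(0.9) = -0.11 (2 dp)
drift_of_phi <- function(object, delta = NULL) {
  if (inherits(object, "dt_params")) {
    Phi <- object$Phi
    if (is.null(delta)) delta <- object$delta
  } else {
    Phi <- as.matrix(object)
    if (is.null(delta)) delta <- 1
  }
  stopifnot(delta > 0)
  if (nrow(Phi) == 1L) {
    phi <- Phi[1, 1]
    if (phi <= 0 || phi >= 1) {
      esmct_error("univariate phi must lie in (0, 1) to have a CT representation",
                  "esmct_no_ct_representation")
    }
    return(matrix(log(phi) / delta, 1, 1))
  }
  ev <- eigen(Phi, only.values = TRUE)$values
  if (any(Re(ev) <= 0 & abs(Im(ev)) < 1e-12)) {
    esmct_error("Phi has eigenvalues on the closed negative real axis; no real CT representation",
                "esmct_no_ct_representation")
  }
  L <- pracma::logm(Phi)
  if (is.complex(L)) {
    if (max(abs(Im(L))) > 1e-8) {
      esmct_error("principal matrix logarithm of Phi is not real",
                  "esmct_no_ct_representation")
    }
    L <- Re(L)
  }
  B <- L / delta
  if (any(Re(eigen(B, only.values = TRUE)$values) >= 0)) {
    esmct_error("recovered drift is not stationary; no CT representation",
                "esmct_no_ct_representation")
  }
  B
}

#' Interval-dependent innovation covariance of the CT model
#'
#' For an elapsed interval `delta`, the innovation covariance of the
#' CVAR(1) model is
#' `Sigma_eps(delta) = Sigma_y - expm(B delta) Sigma_y expm(B' delta)`.
#' It is zero at `delta = 0` and tends to `Sigma_y` as `delta` grows.
#'
#' @param ct A [ct_params()] object.
#' @param delta Non-negative interval in block units.
#' @return The K x K innovation covariance (symmetrized; eigenvalues below
#'   `-1e-10` raise an error).
#' @export
innovation_cov_ct <- function(ct, delta) {
  stopifnot(inherits(ct, "ct_params"))
  if (delta < 0) esmct_error("delta must be non-negative", "esmct_domain")
  E <- phi_of_delta(ct, delta)
  make_psd(ct$Sigma_y - E %*% ct$Sigma_y %*% t(E))
}

#' Unit-interval innovation covariance of the DT model
#'
#' `Sigma_eps = Sigma_y - Phi Sigma_y Phi'`, the discrete-time stationary
#' relation; it coincides with [innovation_cov_ct()] at `delta = 1` when
#' `Phi = expm(B)`.
#'
#' @param Phi Autoregression matrix (or `dt_params`).
#' @param Sigma_y Stationary covariance.
#' @return The K x K innovation covariance.
#' @export
innovation_cov_dt <- function(Phi, Sigma_y) {
  if (inherits(Phi, "dt_params")) Phi <- Phi$Phi
  Phi <- as.matrix(Phi)
  Sigma_y <- as.matrix(Sigma_y)
  if (max(abs(eigen(Phi, only.values = TRUE)$values)) >= 1) {
    esmct_error("Phi must have spectral radius below 1", "esmct_nonstationary")
  }
  make_psd(Sigma_y - Phi %*% Sigma_y %*% t(Phi))
}

#' Diffusion matrix implied by drift and stationary covariance
#'
#' Returns `GG'`, the diffusion (instantaneous innovation) covariance
#' solving the continuous Lyapunov equation
#' `B Sigma_y + Sigma_y B' + GG' = 0`. Used as a consistency check: the
#' pair `(B, Sigma_y)` describes a valid stationary process only when the
#' implied `GG'` is positive semidefinite.
#'
#' @param ct A [ct_params()] object.
#' @return The K x K matrix `GG'`.
#' @export
diffusion_of <- function(ct) {
  stopifnot(inherits(ct, "ct_params"))
  make_psd(-(ct$B %*% ct$Sigma_y + ct$Sigma_y %*% t(ct$B)))
}

#' Stationary mean of a (V)AR(1) process
#'
#' `mu = (I - Phi)^{-1} c`; zero intercept implies zero mean.
#'
#' @param c Intercept vector.
#' @param Phi Autoregression matrix.
#' @return The stationary mean vector.
#' @export
stationary_mean <- function(c, Phi) {
  Phi <- as.matrix(Phi)
  K <- nrow(Phi)
  A <- diag(K) - Phi
  if (abs(det(A)) < 1e-12) {
    esmct_error("I - Phi is singular; no stationary mean", "esmct_nonstationary")
  }
  as.numeric(solve(A, c))
}
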