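test_that("lag-scaling of the autocorrelation follows phi^delta", {
  expect_equal(phi_of_delta(log(0.1), 0.5)[1, 1], 0.1^0.5)
  expect_equal(round(phi_of_delta(log(0.1), 0.5)[1, 1], 2), 0.32)
  expect_equal(round(phi_of_delta(log(0.1), 1.5)[1, 1], 2), 0.03)
  # averaging the two implied autocorrelations (at reported 2-dp precision)
  # does not recover phi(1): 0.18 instead of 0.10
  avg <- mean(round(c(phi_of_delta(log(0.1), 0.5),
                      phi_of_delta(log(0.1), 1.5)), 2))
  expect_equal(floor(avg * 100 + 0.5 + 1e-9) / 100, 0.18)
  expect_equal(phi_of_delta(log(0.3), 0)[1, 1], 1)       # identity at delta 0
  expect_equal(unname(phi_of_delta(diag(-1, 2), 0)), diag(2))
  expect_error(phi_of_delta(log(0.3), -1), class = "esmct_domain")
})

test_that("drift and autoregression translate back and forth exactly", {
  expect_equal(drift_of_phi(0.1)[1, 1], log(0.1))
  expect_equal(round(drift_of_phi(0.1)[1, 1], 2), -2.30)
  expect_equal(round(drift_of_phi(0.9)[1, 1], 2), -0.11)
  expect_equal(drift_of_phi(diag(exp(-1), 2)), -diag(2), tolerance = 1e-10)
  # bivariate reference pair: re-exponentiating the recovered drift gives Phi back
  Phi <- matrix(c(0.3540, -0.0679, -0.0482, 0.2770), 2, 2)
  B <- drift_of_phi(Phi)
  expect_lt(max(abs(phi_of_delta(B, 1) - Phi)), 1e-10)
  expect_lt(max(abs(B - biv_truth()$B)), 1e-3)
  # no CT representation outside (0, 1)
  expect_error(drift_of_phi(-0.3), class = "esmct_no_ct_representation")
  expect_error(drift_of_phi(1.0), class = "esmct_no_ct_representation")
  expect_error(drift_of_phi(matrix(c(-0.5, 0, 0, 0.4), 2, 2)),
               class = "esmct_no_ct_representation")
})

test_that("matrix exponential semigroup and monotone decay hold", {
  set.seed(42)
  for (r in 1:20) {
    B <- matrix(rnorm(4), 2, 2) - diag(2) * (2 + abs(rnorm(1)))
    if (any(Re(eigen(B, only.values = TRUE)$values) >= 0)) next
    d1 <- runif(1, 0, 3); d2 <- runif(1, 0, 3)
    expect_lt(max(abs(phi_of_delta(B, d1 + d2) -
                        phi_of_delta(B, d1) %*% phi_of_delta(B, d2))), 1e-10)
  }
  phis <- sapply(seq(0.1, 3, by = 0.1),
                 function(d) phi_of_delta(log(0.6), d)[1, 1])
  expect_true(all(diff(phis) < 0))  # strictly decreasing in delta
  expect_true(all(phis > 0))        # never negative
})

test_that("interval-dependent innovation covariance matches the stationary relation", {
  ct1 <- uni_truth(0.5)
  expect_equal(innovation_cov_ct(ct1, 1)[1, 1], 1 - 0.5^2)
  expect_equal(innovation_cov_ct(ct1, 0)[1, 1], 0)
  biv <- biv_truth()
  expect_equal(unname(innovation_cov_ct(biv, 0)), matrix(0, 2, 2))
  # asymptotically the innovation covariance is the stationary covariance
  expect_lt(max(abs(innovation_cov_ct(biv, 50) - biv$Sigma_y)), 1e-6)
  # DT relation at delta = 1 coincides with the CT one when Phi = expm(B)
  Phi <- phi_of_delta(biv, 1)
  expect_lt(max(abs(innovation_cov_dt(Phi, biv$Sigma_y) -
                      innovation_cov_ct(biv, 1))), 1e-12)
  # fixed-point oracle: Sigma_y = Phi Sigma_y Phi' + Sigma_eps
  Se <- innovation_cov_dt(Phi, biv$Sigma_y)
  S <- diag(2)
  for (i in 1:500) S <- Phi %*% S %*% t(Phi) + Se
  expect_lt(max(abs(S - biv$Sigma_y)), 1e-10)
  expect_equal(innovation_cov_dt(0, 1)[1, 1], 1)
})

test_that("implied diffusion solves the continuous Lyapunov equation", {
  ct1 <- ct_params(-0.7, 1)
  expect_equal(diffusion_of(ct1)[1, 1], 1.4)  # -2b for unit variance
  biv <- biv_truth()
  GG <- diffusion_of(biv)
  resid <- biv$B %*% biv$Sigma_y + biv$Sigma_y %*% t(biv$B) + GG
  expect_lt(max(abs(resid)), 1e-10)
  expect_true(all(eigen(GG, symmetric = TRUE)$values >= -1e-12))
  # linear in Sigma_y
  ct4 <- ct_params(biv$B, 4 * biv$Sigma_y)
  expect_equal(diffusion_of(ct4), 4 * GG, tolerance = 1e-10)
})

test_that("stationary mean is (I - Phi)^(-1) c", {
  expect_equal(stationary_mean(0, 0.5), 0)
  expect_equal(stationary_mean(0.5, 0.5), 1.0)
  Phi <- matrix(c(0.3, 0.1, -0.2, 0.4), 2, 2)
  cc <- c(0.5, -1)
  mu <- stationary_mean(cc, Phi)
  # iteration oracle y <- c + Phi y
  y <- c(0, 0)
  for (i in 1:200) y <- cc + Phi %*% y
  expect_equal(mu, as.numeric(y), tolerance = 1e-10)
  expect_error(stationary_mean(1, 1), class = "esmct_nonstationary")
})

test_that("parameter containers validate stationarity and covariances", {
  expect_error(ct_params(0.1, 1), class = "esmct_nonstationary")
  expect_error(ct_params(-1, -1), class = "esmct_invalid_covariance")
  expect_error(dt_params(1.1), class = "esmct_nonstationary")
  ok <- dt_params(0.5, delta = 2)
  expect_equal(ok$delta, 2)
})
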