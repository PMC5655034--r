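# shared fixtures: small generating truths and a quick series factory

uni_truth <- function(phi) ct_params(log(phi), 1)

biv_truth <- function() {
  ct_params(B = matrix(c(-1.0541, -0.2188, -0.1554, -1.3021), 2, 2),
            Sigma_y = matrix(c(1, -0.5155, -0.5155, 1), 2, 2))
}

quick_series <- function(phi = 0.4, n_days = 10, seed = 1,
                         min_interval = 0) {
  cfg <- schedule_config(n_days = n_days, min_interval_blocks = min_interval,
                         seed = derive_seed(seed, 1))
  simulate_cvar(uni_truth(phi), generate_schedule(cfg),
                seed = derive_seed(seed, 2))
}

# equally spaced single-day series (all deltas exactly 1)
equispaced_series <- function(phi = 0.5, n = 1000, seed = 1) {
  set.seed(seed)
  y <- numeric(n)
  y[1] <- rnorm(1)
  for (i in 2:n) y[i] <- phi * y[i - 1] + rnorm(1, sd = sqrt(1 - phi^2))
  structure(data.frame(person_id = "p1", day = 1L,
                       time_blocks = as.numeric(seq_len(n)), y1 = y),
            class = c("esm_series", "data.frame"))
}
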