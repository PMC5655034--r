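test_that("triangular interval law has the closed-form mean and variance", {
  law <- triangular_law(0, 180, 90)  # 90-min blocks, interval in minutes
  st <- triangular_stats(law)
  expect_equal(st$mean, 90)
  expect_equal(st$variance, 1350)
  # block-unit version: mean one block, variance 1/6 block^2
  stb <- triangular_stats(block_interval_law(1))
  expect_equal(stb$mean, 1)
  expect_equal(stb$variance, 1 / 6)
  # degenerate point mass
  st0 <- triangular_stats(triangular_law(0, 0, 0))
  expect_equal(st0$mean, 0)
  expect_equal(st0$variance, 0)
  expect_error(triangular_law(1, 0, 0.5), class = "esmct_invalid_law")
})

test_that("same-day gaps follow the triangular law of summed uniforms", {
  # pooled gaps across many days; KS distance against the analytic CDF
  sch <- generate_schedule(schedule_config(n_days = 12000, seed = 11))
  gaps <- diff(sch$time_blocks)[diff(sch$day) == 0]
  expect_gte(length(gaps), 1e5)
  gaps <- gaps[seq_len(1e5)]
  st <- triangular_stats(block_interval_law(1))
  se_mean <- sqrt(st$variance / length(gaps))
  expect_lt(abs(mean(gaps) - st$mean), 3 * se_mean)
  expect_lt(abs(var(gaps) - st$variance), 0.01)
  grid <- sort(gaps)
  ks <- max(abs(seq_along(grid) / length(grid) -
                  triangular_cdf(grid, block_interval_law(1))))
  expect_lt(ks, 0.02)
})

test_that("each beep stays in its block and schedules are reproducible", {
  cfg <- schedule_config(n_days = 10, seed = 7)
  sch <- generate_schedule(cfg)
  expect_equal(nrow(sch), 100)
  within_day <- sch$time_blocks - (sch$day - 1) * 16
  expect_true(all(within_day >= sch$beep_index - 1))
  expect_true(all(within_day < sch$beep_index))
  expect_identical(generate_schedule(cfg)$time_blocks, sch$time_blocks)
})

test_that("overnight gaps average seven blocks for the 15-h, 10-block day", {
  sch <- generate_schedule(schedule_config(n_days = 2000, seed = 3))
  over <- diff(sch$time_blocks)[diff(sch$day) != 0]
  # night = 6 blocks plus two half-block remainders in expectation
  expect_lt(abs(mean(over) - 7), 3 * sqrt(2 / 12) / sqrt(length(over)) + 0.02)
  expect_true(all(over > 6))
})

test_that("minimum-interval rule truncates gaps, raising mean and cutting variance", {
  cfg <- schedule_config(n_days = 3000, min_interval_blocks = 1 / 6, seed = 5)
  sch <- generate_schedule(cfg)
  gaps <- diff(sch$time_blocks)[diff(sch$day) == 0]
  expect_gte(min(gaps), 1 / 6)
  st <- triangular_stats(block_interval_law(1))
  expect_gt(mean(gaps), st$mean)        # mean above the (untruncated) mode
  expect_lt(var(gaps), st$variance)     # variance reduced
  expect_error(schedule_config(min_interval_blocks = 1),
               class = "esmct_infeasible_schedule")
})

test_that("empirical-style schedule matches the week-long eight-beep design", {
  # zero delay, full compliance: 7 days x 8 beeps
  sch <- generate_empirical_schedule(
    delay_config = list(dist = "exponential", mean_minutes = 1e-9),
    nonresponse_prob = 0, seed = 2)
  expect_equal(nrow(sch), 56)
  expect_equal(as.integer(table(sch$day)), rep(8L, 7))
  expect_true(all(diff(sch$time_blocks) > 0))
  # realized mean within-day interval near 105 min under the default config
  gaps <- unlist(lapply(1:60, function(s) {
    x <- generate_empirical_schedule(seed = s)
    diff(x$time_blocks)[diff(x$day) == 0] * 105
  }))
  expect_lt(abs(mean(gaps) - 105), 10)
  # response delays generate short intervals (below one block)
  expect_gt(mean(gaps < 105 / 2), 0.01)
})
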