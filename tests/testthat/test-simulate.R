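test_that("profile construction places its mass at the configured peaks", {
  p <- build_profile(peaks = c(10, 18), widths = 2, trough_depth = 0.3,
                     baseline = 0.08)
  expect_setequal(order(p, decreasing = TRUE)[1:2] - 1, c(10, 18))
  expect_equal(mean(p), 1)
  expect_true(all(p >= 0))

  single <- build_profile(peaks = 6, widths = 2, baseline = 0)
  expect_lt(single[19], 1e-6)  # antipodal hour (18) is numerically zero

  expect_error(build_profile(peaks = 6, widths = 2, baseline = 0,
                             trough_depth = 100, trough_hour = 6,
                             amplitudes = 0), "zero")
})

test_that("shifting the peaks by 12 hours rotates the profile circularly", {
  base <- build_profile(peaks = c(10, 18), widths = 2, trough_depth = 0.2,
                        trough_hour = 14, baseline = 0.05)
  shifted <- build_profile(peaks = c(22, 6), widths = 2, trough_depth = 0.2,
                           trough_hour = 2, baseline = 0.05)
  expect_equal(shifted, rotate_profile(base, 12), tolerance = 1e-12)
  expect_equal(rotate_profile(base, 24), base)
  expect_equal(rotate_profile(rotate_profile(base, 5), -5), base)
})

test_that("simulated call volumes follow the configured Poisson rate", {
  cfg <- synthetic_config(n_egos = 1, months = 12, seed = 101,
                          median_yearly_out = 730, median_yearly_in = 730,
                          rate_sdlog = 0, peak_jitter_sd = 0)
  sim <- simulate_calls(cfg)
  n_out <- sum(sim$dataset$calls$direction == "outgoing")
  expect_lt(abs(n_out - 730), 3 * sqrt(730))
  # bookkeeping matches what was written
  expect_equal(sim$truth$egos$n_out, n_out)
})

test_that("simulation is deterministic given the seed and labels follow the config", {
  cfg <- synthetic_config(n_egos = 2, months = 3, n_periods = 3, seed = 7,
                          drift_hours = c(0, 8), desync_hours = c(6, 0))
  a <- simulate_calls(cfg)
  b <- simulate_calls(cfg)
  expect_identical(a$dataset$calls, b$dataset$calls)
  expect_identical(a$truth$egos, b$truth$egos)
  expect_equal(a$truth$egos$persistent, c(TRUE, FALSE))
  expect_equal(a$truth$egos$synchronized, c(FALSE, TRUE))

  c2 <- simulate_calls(synthetic_config(n_egos = 2, months = 3,
                                        n_periods = 3, seed = 8,
                                        drift_hours = c(0, 8),
                                        desync_hours = c(6, 0)))
  expect_false(identical(a$dataset$calls$start_time,
                         c2$dataset$calls$start_time))
})

test_that("empirical hourly fractions converge to the generating profile", {
  cfg <- synthetic_config(n_egos = 1, months = 12, seed = 55,
                          median_yearly_out = 110000,
                          median_yearly_in = 110000,
                          rate_sdlog = 0, peak_jitter_sd = 0,
                          evening_concentration = 1)
  sim <- simulate_calls(cfg)
  out_calls <- sim$dataset$calls[sim$dataset$calls$direction == "outgoing", ]
  expect_gt(nrow(out_calls), 1e5)
  emp <- bin_hourly(out_calls$start_time) / nrow(out_calls)
  expected <- sim$truth$profiles$ego01$outgoing[1, ]
  expected <- expected / sum(expected)
  expect_lt(max(abs(emp - expected)), 0.01)
})

test_that("the unanswered incoming fraction matches the config within binomial error", {
  cfg <- synthetic_config(n_egos = 3, months = 12, seed = 66,
                          unanswered_incoming = 0.25)
  sim <- simulate_calls(cfg)
  inc <- sim$dataset$calls[sim$dataset$calls$direction == "incoming", ]
  phat <- mean(!inc$answered)
  se <- sqrt(0.25 * 0.75 / nrow(inc))
  expect_lt(abs(phat - 0.25), 4 * se)
  expect_equal(sum(!inc$answered), sum(sim$truth$egos$n_unanswered_in))
})

test_that("self-distance of a stationary ego decreases with call volume", {
  mean_dself <- function(yearly) {
    sim <- simulate_calls(synthetic_config(n_egos = 3, months = 12,
                                           seed = 77, rate_sdlog = 0,
                                           median_yearly_out = yearly,
                                           median_yearly_in = yearly))
    prep <- list(partition = partition_periods(sim$dataset$window, 3))
    res <- run_persistence(sim$dataset, prep$partition, "outgoing")
    mean(res$results$mean_d_self)
  }
  expect_lt(mean_dself(4000), mean_dself(400))
})

test_that("silent-period egos are generated silent and fail the activity filter", {
  sim <- simulate_calls(synthetic_config(n_egos = 8, months = 12, seed = 88,
                                         n_silent = 3))
  tr <- sim$truth$egos
  silent <- tr$ego_id[!is.na(tr$silent_period)]
  expect_length(silent, 3)
  part <- sim$truth$partition
  for (e in silent) {
    p <- tr$silent_period[tr$ego_id == e]
    iv <- c(part$start[part$label == p], part$end[part$label == p])
    expect_equal(nrow(subset_calls(sim$dataset, e, "merged", iv)), 0)
  }
  f <- filter_active_egos(sim$dataset, part)
  expect_setequal(attr(f, "excluded_egos"), silent)
  expect_equal(length(egos_of(f)), 5)
})

test_that("the reference cohort lands near its calibrated yearly medians", {
  sim <- simulate_reference_cohort(seed = 12)
  expect_equal(nrow(sim$truth$egos), 21)
  s <- cohort_summary(sim$dataset)
  med_out <- s$median[s$direction == "outgoing"]
  med_in <- s$median[s$direction == "incoming"]
  expect_lt(abs(med_out - 710) / 710, 0.25)
  expect_lt(abs(med_in - 800) / 800, 0.25)
})
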