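test_that("observed occupancy fixture has the documented totals", {
  obs <- observed_occupancy()
  expect_equal(nrow(obs), 21)
  expect_equal(sum(obs$n_obs), 320)
  expect_equal(range(obs$dose_mg), c(80, 1400))
  r420 <- obs[obs$dose_mg == 420, ]
  expect_equal(r420$n_obs, 119)
  expect_equal(r420$pct_gt90, 77)
  # reconstructed responder counts are integral and within range
  expect_true(all(obs$responders == round(obs$responders)))
  expect_true(all(obs$responders >= 0 & obs$responders <= obs$n_obs))
  # overall responder rate reproduces the printed 82%
  expect_equal(round(100 * sum(obs$responders) / sum(obs$n_obs)), 82)
})

test_that("dose-group pooling conserves counts and pools proportions", {
  pooled <- pool_dose_groups()
  expect_equal(nrow(pooled), 5)
  expect_equal(sum(pooled$n), 320)
  # lowest group: 80 and 120 mg, n = 8 + 12, responders 4 + 8
  expect_equal(pooled$n[1], 20)
  expect_equal(pooled$prop_pct[1], 60)
  # exact binomial CI brackets the pooled proportion
  expect_true(all(pooled$ci_lo_pct <= pooled$prop_pct &
                  pooled$prop_pct <= pooled$ci_hi_pct))
})

test_that("pooling handles degenerate groups and bad records", {
  one <- data.frame(dose_mg = 420, n_obs = 119, pct_gt90 = 77,
                    responders = 92)
  pooled <- pool_dose_groups(one, boundaries = c(300, 500))
  expect_equal(pooled$prop_pct, 100 * 92 / 119)
  zero <- data.frame(dose_mg = 100, n_obs = 5, pct_gt90 = 0, responders = 0)
  p0 <- pool_dose_groups(zero, boundaries = c(80, 140))
  expect_equal(p0$ci_lo_pct, 0)  # exact CI lower bound at 0/5
  outside <- data.frame(dose_mg = 2000, n_obs = 5, pct_gt90 = 0,
                        responders = 0)
  expect_error(pool_dose_groups(outside), "outside")
})

test_that("residual variability is additive, centred and clipped", {
  occ <- rep(50, 20000)
  expect_identical(add_ruv(occ, variance = 0), occ)
  noisy <- add_ruv(occ, variance = 27.1, seed = 4)
  # centred: sample mean within 4 standard errors of zero
  expect_lt(abs(mean(noisy - occ)), 4 * sqrt(27.1 / length(occ)))
  expect_equal(sd(noisy - occ), sqrt(27.1), tolerance = 0.02)
  # clipping keeps values in range and biases boundary values inward
  high <- add_ruv(rep(99, 5000), variance = 27.1, seed = 5)
  expect_true(all(high <= 100))
  expect_lt(mean(high), 99)
  low <- add_ruv(rep(1, 5000), variance = 27.1, seed = 6)
  expect_true(all(low >= 0))
  expect_gt(mean(low), 1)
})

test_that("synthetic studies honour their design bookkeeping", {
  alloc <- data.frame(dose_mg = c(0, 140), n = c(3, 4))
  syn <- generate_synthetic_study(alloc, sampling_days = c(2, 8),
                                  ruv_variance = 0, seed = 20)
  expect_equal(nrow(syn), 14)  # 7 subjects x 2 days
  expect_equal(sort(unique(syn$day)), c(2, 8))
  expect_equal(syn$occupancy_pct[syn$dose_mg == 0], rep(0, 6))
  expect_true(all(syn$occupancy_pct[syn$dose_mg == 140 & syn$day == 8] > 0))
  # Table-2-sized allocation reproduces the 320 records per sampling day
  obs <- observed_occupancy()
  syn2 <- generate_synthetic_study(data.frame(dose_mg = obs$dose_mg,
                                              n = obs$n_obs),
                                   sampling_days = 8, seed = 21)
  expect_equal(nrow(syn2), 320)
})

test_that("the synthetic generator is self-consistent with the trial engine", {
  n <- 400
  syn <- generate_synthetic_study(data.frame(dose_mg = 420, n = n),
                                  sampling_days = 8, ruv_variance = 0,
                                  seed = 33)
  tr <- run_virtual_trial(420, n = n, days = 7, seed = 33)
  p_syn <- mean(syn$gt90)
  p_tr <- mean(tr$occupancy > 90)
  # same model, independent draws: agreement within binomial sampling error
  se <- sqrt(p_tr * (1 - p_tr) / n)
  expect_lt(abs(p_syn - p_tr), 4 * se + 0.01)
})

test_that("model predictions cover the pooled observed proportions", {
  obs <- observed_occupancy()
  grid <- uncertainty_grid(n = 2e4, seed = 40, percentiles = c(5, 50, 95))
  sw <- dose_response_sweep(doses_mg = sort(unique(obs$dose_mg)), n = 400,
                            grid = grid, seed = 41, ruv_variance = 27.1)
  cmp <- predicted_vs_observed(sw)
  expect_equal(nrow(cmp), 5)
  expect_true(all(is.finite(cmp$predicted_pct)))
  # observed proportions fall inside the 5th-95th uncertainty band
  expect_true(all(cmp$observed_pct >= cmp$pred_lo_pct &
                  cmp$observed_pct <= cmp$pred_hi_pct))
})

test_that("prediction requires the sweep to span the observed doses", {
  sw <- dose_response_sweep(doses_mg = c(80, 120), n = 20, seed = 50)
  expect_error(predicted_vs_observed(sw), "missing observed doses")
})
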