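test_that("a degenerate one-subject population reproduces the typical profile", {
  tr <- run_virtual_trial(420, n = 1, spec = degenerate_spec(), seed = 1)
  traj <- simulate_profile(typical_pk(), typical_pd(60), qd_regimen(420, 7),
                           t_out = c(0, 168))
  expect_equal(as.numeric(tr$occupancy),
               traj$occupancy_pct[traj$time_h == 168], tolerance = 1e-6)
})

test_that("zero dose gives zero occupancy for everyone", {
  tr <- run_virtual_trial(c(0, 140), n = 10, seed = 2)
  expect_equal(as.numeric(tr$occupancy[, "0"]), rep(0, 10))
  expect_true(all(tr$occupancy[, "140"] > 0))
})

test_that("virtual trials are bitwise reproducible under a fixed seed", {
  a <- run_virtual_trial(c(140, 420), n = 25, seed = 77)
  b <- run_virtual_trial(c(140, 420), n = 25, seed = 77)
  expect_identical(a$occupancy, b$occupancy)
})

test_that("common random numbers make occupancy per-subject monotone in dose", {
  tr <- run_virtual_trial(c(70, 140, 280, 560), n = 60, seed = 8)
  diffs <- t(apply(tr$occupancy, 1, diff))
  expect_true(all(diffs > -1e-9))
})

test_that("steady state is reached: day-6 and day-7 troughs nearly coincide", {
  traj <- simulate_profile(regimen = qd_regimen(420, 7), t_out = c(144, 168))
  occ <- traj$occupancy_pct
  expect_lt(abs(occ[2] - occ[1]), 0.5)
})

test_that("trial summaries match the quantile/count definitions", {
  tr <- run_virtual_trial(140, n = 30, seed = 12)
  s <- summary(tr)
  occ <- as.numeric(tr$occupancy)
  expect_equal(s$median, median(occ))
  expect_equal(s$prop_gt90, 100 * sum(occ > 90) / 30)
  expect_true(all(tr$occupancy >= 0 & tr$occupancy <= 100))
})

test_that("dose-response sweeps carry one curve per uncertainty pair", {
  g <- uncertainty_grid(n = 2e4, seed = 3,
                        percentiles = c(5, 50, 95))
  sw <- dose_response_sweep(doses_mg = c(35, 140, 560), n = 40, grid = g,
                            seed = 9)
  expect_equal(nrow(sw), 9)
  expect_true(all(sw$prop_gt90 >= 0 & sw$prop_gt90 <= 1))
  # higher kon (higher percentile) means more potent binding at every dose
  by_dose <- split(sw, sw$dose_mg)
  for (d in by_dose) {
    ord <- d[order(d$percentile), "prop_gt90"]
    expect_true(all(diff(ord) > -1e-9))
  }
  # the central curve is non-decreasing in dose (shared subjects)
  cc <- central_curve(sw)
  expect_true(all(diff(cc$prop_gt90) > -1e-9))
})

test_that("dose-reduction cycles hold steady when the dose does not change", {
  dr <- simulate_dose_reduction(cycles = data.frame(dose_mg = c(140, 140),
                                                    days = c(14, 14)),
                                n = 30, seed = 13)
  # same dose at steady state: the two cycle troughs coincide
  expect_lt(max(abs(dr$occupancy[, 1] - dr$occupancy[, 2])), 0.5)
})

test_that("a single reduction cycle matches the plain 7-day trial", {
  dr <- simulate_dose_reduction(cycles = data.frame(dose_mg = 420, days = 7),
                                n = 40, seed = 14)
  tr <- run_virtual_trial(420, n = 40, days = 7, seed = 14)
  expect_equal(as.numeric(dr$occupancy), as.numeric(tr$occupancy),
               tolerance = 1e-6)
})

test_that("typical-patient profile table enumerates all dose/half-life pairs", {
  tp <- typical_patient_profiles(doses_mg = c(140, 420), half_lives = c(24, 60),
                                 days = 3)
  expect_equal(nrow(tp), 4)
  # occupancy and free-BTK reduction agree up to the small conservation error
  expect_lt(max(abs(tp$occupancy_pct - tp$reduction_pct)), 1)
  # slower turnover holds occupancy higher at trough
  expect_true(all(tp$reduction_pct[tp$t_half_h == 60] >
                  tp$reduction_pct[tp$t_half_h == 24]))
})
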