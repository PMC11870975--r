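test_that("zero-dose simulation keeps free BTK at baseline and occupancy at 0", {
  traj <- simulate_profile(typical_pk(), typical_pd(), qd_regimen(0, 3),
                           t_out = seq(0, 72, by = 4))
  expect_equal(traj$btkf_nM, rep(1.04, nrow(traj)), tolerance = 1e-10)
  expect_equal(traj$occupancy_pct, rep(0, nrow(traj)))
  expect_equal(traj$c2free_nM, rep(0, nrow(traj)))
})

test_that("free BTK relaxes to baseline along the closed-form exponential", {
  pd <- typical_pd()
  x0 <- 0.2
  tt <- seq(0, 240, by = 8)
  traj <- simulate_profile(typical_pk(), pd, qd_regimen(0, 1), t_out = tt,
                           btkf_init = x0)
  expected <- pd$btk0 + (x0 - pd$btk0) * exp(-pd$kdeg * tt)
  expect_lt(max(abs(traj$btkf_nM - expected)), 1e-6)
})

test_that("free drug concentration is linear in dose", {
  tt <- seq(0, 72, by = 1)
  t1 <- simulate_profile(regimen = qd_regimen(100, 3), t_out = tt)
  t2 <- simulate_profile(regimen = qd_regimen(200, 3), t_out = tt)
  nz <- t1$c2free_nM > 0
  expect_lt(max(abs(t2$c2free_nM[nz] / t1$c2free_nM[nz] - 2)), 1e-6)
})

test_that("occupancy is invariant to the BTK baseline", {
  tt <- seq(0, 96, by = 2)
  lo <- simulate_profile(pd = pd_params(btk0 = 1.04),
                         regimen = qd_regimen(420, 4), t_out = tt)
  hi <- simulate_profile(pd = pd_params(btk0 = 2.08),
                         regimen = qd_regimen(420, 4), t_out = tt)
  expect_lt(max(abs(lo$occupancy_pct - hi$occupancy_pct)), 1e-8)
  # the three BTK states simply scale with the baseline
  expect_equal(hi$btkf_nM, 2 * lo$btkf_nM, tolerance = 1e-8)
})

test_that("states stay non-negative and occupancy stays in [0, 100]", {
  traj <- simulate_profile(regimen = qd_regimen(560, 7),
                           t_out = seq(0, 168, by = 0.5))
  expect_true(all(as.matrix(traj[, 2:7]) >= 0))
  expect_true(all(traj$occupancy_pct >= 0 & traj$occupancy_pct <= 100))
})

test_that("total BTK is nearly conserved once the complexes equilibrate", {
  traj <- simulate_profile(regimen = qd_regimen(420, 7),
                           t_out = seq(96, 168, by = 2))
  total <- traj$btkf_nM + traj$btkrc_nM + traj$btkcc_nM
  expect_lt(max(abs(total - 1.04) / 1.04), 0.02)
})

test_that("the compiled integrator agrees with a stiff reference solver", {
  tt <- c(24, 48, 71, 72)
  ref <- reference_trajectory(420, 3, t_half = 60, t_out = tt)
  traj <- simulate_profile(regimen = qd_regimen(420, 3), t_out = tt)
  ref_occ <- 100 * (ref[, 5] + ref[, 6]) / (ref[, 4] + ref[, 5] + ref[, 6])
  expect_lt(max(abs(traj$occupancy_pct - ref_occ)), 1e-3)
  expect_lt(max(abs(traj$btkf_nM - ref[, 4]) / ref[, 4]), 1e-4)
  expect_lt(max(abs(traj$a2_ug - ref[, 2]) / pmax(ref[, 2], 1)), 1e-4)
})

test_that("constant-infusion plateau matches the analytic steady state", {
  pd <- typical_pd()
  for (C in c(0.01, 0.1, 1, 10, 100)) {
    rhs <- function(t, y, p) {
      list(c(pd$ksyn - pd$kon * C * y[1] + pd$koff * y[2] - pd$kdeg * y[1],
             pd$kon * C * y[1] - (pd$koff + pd$kinact) * y[2],
             pd$kinact * y[2] - pd$kdegc * y[3]))
    }
    horizon <- 40 / pd$kdeg  # many turnover half-lives: plateau reached
    o <- deSolve::lsoda(c(pd$btk0, 0, 0), c(0, horizon), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
    y <- as.numeric(o[2, -1])
    numeric_occ <- occupancy_percent(y[1], y[2], y[3])
    expect_lt(abs(numeric_occ - steady_state_occupancy(C, pd)), 0.1)
  }
})

test_that("food and antacid covariates reshape the absorption input", {
  pk <- typical_pk()
  fed <- build_input_segments(qd_regimen(420, 1, fed = TRUE), pk,
                              t_out = c(0, 24))
  fasted <- build_input_segments(qd_regimen(420, 1, fed = FALSE), pk,
                                 t_out = c(0, 24))
  ant <- build_input_segments(qd_regimen(420, 1, fed = TRUE, antacid = TRUE),
                              pk, t_out = c(0, 24))
  dur <- function(s) diff(s$breaks)[s$rates > 0]
  expect_equal(dur(fed), 3.29)
  expect_equal(dur(fasted), 1.10)
  expect_equal(dur(ant), 3.29 * 1.61)
  # input starts after the lag in all cases
  expect_equal(s <- fed$breaks[which(fed$rates > 0)], 0.283)
  # total absorbed amount: F1 * dose
  expect_equal(max(dur(fed)) * fed$rates[fed$rates > 0], 1.0 * 420000)
  expect_equal(max(dur(fasted)) * fasted$rates[fasted$rates > 0],
               0.67 * 420000)
})

test_that("trajectory CSV round-trips through the tidy export", {
  traj <- simulate_profile(regimen = qd_regimen(140, 1),
                           t_out = seq(0, 24, by = 6))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- read.csv(f)
  expect_equal(names(back), c("time_h", "a1_ug", "a2_ug", "a3_ug", "btkf_nM",
                              "btkrc_nM", "btkcc_nM", "c2free_nM",
                              "occupancy_pct"))
  expect_equal(back$occupancy_pct, traj$occupancy_pct, tolerance = 1e-6)
})
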