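test_that("exponential sampler reproduces typical values and variability", {
  spec <- population_spec()
  ind <- sample_individuals(spec, 10000, seed = 101)
  # lognormal median/geometric mean equals the typical value
  gm <- exp(mean(log(ind$cl_f)))
  expect_lt(abs(gm / 1060 - 1), 0.02)
  expect_lt(abs(median(ind$v2_f) / 246 - 1), 0.05)
  # realized log-scale spread matches the requested omega
  expect_equal(sd(log(ind$cl_f)), cv_to_omega(21.9), tolerance = 0.03)
  expect_equal(sd(log(ind$v2_f)), cv_to_omega(153), tolerance = 0.03)
  # ka carries no between-subject variability
  expect_equal(unique(ind$ka), 0.463)
})

test_that("degenerate variability collapses the population to the typical subject", {
  spec <- degenerate_spec()
  ind <- sample_individuals(spec, 5, seed = 1)
  expect_equal(unique(ind$cl_f), 1060)
  expect_equal(unique(ind$f1), 1)
  expect_equal(unique(ind$d_zero), 3.29)
  expect_equal(unique(ind$t_half), 60)
})

test_that("sampling is reproducible under a fixed seed", {
  spec <- population_spec()
  a <- sample_individuals(spec, 50, seed = 99)
  b <- sample_individuals(spec, 50, seed = 99)
  expect_identical(a, b)
})

test_that("fasted and antacid populations shift absorption as specified", {
  spec <- population_spec(fed = FALSE, bsv = setNames(numeric(8),
                                                      names(default_bsv())))
  ind <- sample_individuals(spec, 3, seed = 1)
  expect_equal(unique(ind$f1), 0.67)
  expect_equal(unique(ind$d_zero), 1.10)
  spec2 <- population_spec(antacid = TRUE,
                           bsv = setNames(numeric(8), names(default_bsv())))
  ind2 <- sample_individuals(spec2, 3, seed = 1)
  expect_equal(unique(ind2$d_zero), 3.29 * 1.61)
})

test_that("unknown parameters in the variability table are rejected", {
  expect_error(population_spec(bsv = c(nonsense = 10)), "unknown parameter")
  expect_error(population_spec(bsv = c(cl_f = -5)), "non-negative")
})

test_that("half-life scenarios have the stated supports and centers", {
  hl <- sample_half_lives(half_life_scenario("uniform"), 20000, seed = 3)
  expect_true(all(hl >= 12 & hl <= 120))
  expect_equal(mean(hl), 66, tolerance = 0.02)  # mean of U(12, 120)
  slow <- sample_half_lives(half_life_scenario("slow", cv = 0), 10, seed = 4)
  expect_equal(unique(slow), 60)
  fast <- sample_half_lives(half_life_scenario("fast"), 20000, seed = 5)
  expect_lt(abs(median(fast) / 24 - 1), 0.02)
})

test_that("uncertainty grid percentiles are positive, monotone and centred", {
  g <- uncertainty_grid(n = 1e5, seed = 21)
  expect_equal(g$percentile, c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 95))
  expect_true(all(g$kon > 0) && all(g$kinact > 0))
  expect_true(all(diff(g$kon) > 0) && all(diff(g$kinact) > 0))
  # kon is barely truncated (P[X<0] ~ 0.2%): median stays at the mean
  expect_equal(g$kon[g$percentile == 50], 1.72, tolerance = 0.01)
  # closed-form 5th percentile of the truncated normal:
  # P(X <= q) = 0.05 on X | X > 0 with X ~ N(1.72, 0.6)
  p0 <- pnorm(0, 1.72, 0.6)
  q5 <- qnorm(p0 + 0.05 * (1 - p0), 1.72, 0.6)
  expect_equal(g$kon[g$percentile == 5], q5, tolerance = 0.01)
  # untruncated closed form 1.72 - 1.645 * 0.6 = 0.733 sits just below
  expect_lt(abs(g$kon[g$percentile == 5] - 0.733), 0.03)
})

test_that("occupancy distribution is invariant to BTK0 variability", {
  ind <- sample_individuals(population_spec(), 40, seed = 31)
  tr_on <- run_virtual_trial(140, individuals = ind)
  ind_off <- ind
  ind_off$btk0 <- 1.04  # flatten the baseline spread, keep everything else
  attr(ind_off, "spec") <- attr(ind, "spec")
  tr_off <- run_virtual_trial(140, individuals = ind_off)
  expect_lt(max(abs(tr_on$occupancy - tr_off$occupancy)), 1e-8)
})
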