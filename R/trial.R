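# Subject-level parameter matrix consumed by the compiled engines:
# 11 ODE rates, then btk0, tlag, d_zero, f1 (15 columns).
subject_par_matrix <- function(ind, spec, kon, kinact) {
  pk <- spec$pk
  pd <- spec$pd
  fwt <- (ind$weight / pk$ref_weight)^pk$wt_v_exp
  v2 <- ind$v2_f * fwt
  v3 <- ind$v3_f * fwt
  kdeg <- log(2) / ind$t_half
  cbind(ka = ind$ka, kel = ind$cl_f / v2, k23 = ind$q_f / v2,
        k32 = ind$q_f / v3, c2f = 1000 * pd$fu / (v2 * pd$mw),
        ksyn = ind$btk0 * kdeg, kdeg = kdeg, kon = kon, koff = pd$koff,
        kinact = kinact, kdegc = kdeg, btk0 = ind$btk0, tlag = ind$tlag,
        d_zero = ind$d_zero, f1 = ind$f1)
}

#' Run a virtual occupancy trial
#'
#' Simulates a virtual population under once-daily dosing for `days` days at
#' one or more dose levels and records the intrinsic BTK occupancy (no
#' residual error) at the steady-state trough, `trough_h` hours after the
#' last dose. The same virtual subjects are used at every dose (common random
#' numbers), which makes dose-response curves smooth and per-subject
#' monotone.
#'
#' @param doses_mg dose level(s) in mg.
#' @param n number of virtual subjects.
#' @param days number of once-daily doses.
#' @param scenario a [half_life_scenario()]; ignored when `spec` is supplied.
#' @param spec optional [population_spec()] overriding the default.
#' @param kon,kinact binding parameters shared by all subjects (central
#'   values by default; pass values from an [uncertainty_grid()] row for
#'   uncertainty scenarios).
#' @param seed integer seed for the population draw.
#' @param trough_h trough definition: hours after the last dose (default 24,
#'   i.e. the pre-dose sample of the next day).
#' @param dt_max maximum integration step (h).
#' @param individuals optional pre-sampled subject data frame from
#'   [sample_individuals()] (overrides `n` and `seed`).
#' @return An object of class `btk_trial` holding the `n x length(doses_mg)`
#'   occupancy matrix and the run metadata.
#' @examples
#' tr <- run_virtual_trial(c(140, 420), n = 50, seed = 1)
#' summary(tr)
#' @export
run_virtual_trial <- function(doses_mg, n = 10000, days = 7,
                              scenario = half_life_scenario("uniform"),
                              spec = NULL, kon = 1.72, kinact = 95.76,
                              seed = NULL, trough_h = 24, dt_max = 0.01,
                              individuals = NULL) {
  if (any(doses_mg < 0)) stop("doses must be non-negative")
  if (days < 1) stop("days must be >= 1")
  if (is.null(spec)) spec <- population_spec(scenario = scenario)
  if (is.null(individuals)) {
    individuals <- sample_individuals(spec, n, seed = seed)
  } else {
    n <- nrow(individuals)
    spec <- attr(individuals, "spec")
  }
  pars <- subject_par_matrix(individuals, spec, kon, kinact)
  eval_time <- 24 * (days - 1) + trough_h
  occ <- cpp_sweep_occupancy(pars, 24 * (seq_len(days) - 1),
                             as.numeric(doses_mg), eval_time, dt_max)
  colnames(occ) <- as.character(doses_mg)
  structure(list(occupancy = occ, doses_mg = doses_mg, n = n, days = days,
                 scenario = spec$scenario, kon = kon, kinact = kinact,
                 seed = seed, eval_time = eval_time,
                 individuals = individuals),
            class = "btk_trial")
}

#' @export
print.btk_trial <- function(x, ...) {
  cat(sprintf("Virtual occupancy trial: n = %d subjects, %d day(s) QD, trough at %g h\n",
              x$n, x$days, x$eval_time))
  print(summary(x))
  invisible(x)
}

#' Summarize a virtual trial as a dose-occupancy table
#'
#' @param object a `btk_trial`.
#' @param ... unused.
#' @return Data frame with one row per dose: median, 5th and 95th percentile
#'   occupancy (%), and the percentage of subjects above 90% occupancy.
#' @export
summary.btk_trial <- function(object, ...) {
  rows <- lapply(seq_along(object$doses_mg), function(j) {
    s <- summarize_occupancy(object$occupancy[, j])
    data.frame(dose_mg = object$doses_mg[j], n = object$n,
               median = s[["median"]], p5 = s[["p5"]], p95 = s[["p95"]],
               prop_gt90 = s[["prop_gt90"]])
  })
  do.call(rbind, rows)
}

#' Dose-response sweep of the proportion above 90% occupancy
#'
#' Runs [run_virtual_trial()] across a dose grid with shared subjects, for
#' the central binding parameters or for every kon/kinact pair of an
#' [uncertainty_grid()]. The proportion of subjects with intrinsic occupancy
#' strictly above 90% is recorded per dose; optionally the proportion after
#' adding residual unexplained variability (for comparison with observed
#' data) is recorded as well.
#'
#' @inheritParams run_virtual_trial
#' @param doses_mg dose grid (mg), at least two doses.
#' @param grid optional [uncertainty_grid()]; when `NULL` a single central
#'   curve is computed with `kon`/`kinact`.
#' @param ruv_variance optional residual error variance (percent^2 scale);
#'   when given, `prop_gt90_ruv` is added.
#' @param keep_occupancy keep the subject-level occupancy matrices (one per
#'   percentile) in the result.
#' @return An object of class `btk_dose_response`: a data frame with columns
#'   `percentile`, `dose_mg`, `prop_gt90` (fraction) and optionally
#'   `prop_gt90_ruv`.
#' @export
dose_response_sweep <- function(doses_mg = default_dose_grid(), n = 10000,
                                days = 7,
                                scenario = half_life_scenario("uniform"),
                                spec = NULL, grid = NULL, kon = 1.72,
                                kinact = 95.76, seed = NULL, trough_h = 24,
                                dt_max = 0.01, ruv_variance = NULL,
                                keep_occupancy = FALSE) {
  if (length(doses_mg) < 2) stop("need at least two doses")
  if (is.null(spec)) spec <- population_spec(scenario = scenario)
  if (!is.null(seed)) set.seed(seed)
  individuals <- sample_individuals(spec, n)
  pairs <- if (is.null(grid)) {
    data.frame(percentile = 50, kon = kon, kinact = kinact)
  } else {
    as.data.frame(grid)
  }
  eval_time <- 24 * (days - 1) + trough_h
  dose_times <- 24 * (seq_len(days) - 1)
  res <- vector("list", nrow(pairs))
  occs <- if (keep_occupancy) vector("list", nrow(pairs)) else NULL
  for (i in seq_len(nrow(pairs))) {
    pars <- subject_par_matrix(individuals, spec, pairs$kon[i],
                               pairs$kinact[i])
    occ <- cpp_sweep_occupancy(pars, dose_times, as.numeric(doses_mg),
                               eval_time, dt_max)
    row <- data.frame(percentile = pairs$percentile[i], dose_mg = doses_mg,
                      prop_gt90 = colMeans(occ > 90))
    if (!is.null(ruv_variance)) {
      noisy <- apply(occ, 2, function(col)
        pmin(100, pmax(0, col + rnorm(length(col), 0,
                                      sqrt(ruv_variance)))))
      row$prop_gt90_ruv <- colMeans(noisy > 90)
    }
    res[[i]] <- row
    if (keep_occupancy) {
      colnames(occ) <- as.character(doses_mg)
      occs[[i]] <- occ
    }
  }
  out <- do.call(rbind, res)
  structure(out, class = c("btk_dose_response", "data.frame"),
            scenario = spec$scenario, n = n, days = days, seed = seed,
            eval_time = eval_time, occupancy = occs)
}

#' Default dose grid for dose-response sweeps
#'
#' 1 mg, then 10-mg steps to 150 mg, 25-mg steps to 600 mg and 50-mg steps to
#' 1100 mg: dense where the curves rise, coarse on the plateau.
#' @return Numeric vector of doses (mg).
#' @export
default_dose_grid <- function() {
  c(1, seq(10, 150, by = 10), seq(175, 600, by = 25), seq(650, 1100, by = 50))
}

#' Extract the central curve of a dose-response sweep
#' @param x a `btk_dose_response`.
#' @return Data frame `dose_mg`, `prop_gt90` for the percentile closest to 50.
#' @export
central_curve <- function(x) {
  stopifnot(inherits(x, "btk_dose_response"))
  p <- unique(x$percentile)
  keep <- p[which.min(abs(p - 50))]
  out <- x[x$percentile == keep, c("dose_mg", "prop_gt90")]
  rownames(out) <- NULL
  out
}

#' Sequential dose-reduction simulation
#'
#' Simulates each subject continuously through consecutive once-daily cycles
#' (by default 420, 280 and 140 mg for 28 days each) and evaluates the
#' intrinsic occupancy at the final trough of every cycle.
#'
#' @inheritParams run_virtual_trial
#' @param cycles data frame with columns `dose_mg` and `days`.
#' @return An object of class `btk_dose_reduction` holding the
#'   `n x nrow(cycles)` occupancy matrix.
#' @export
simulate_dose_reduction <- function(cycles = data.frame(dose_mg = c(420, 280, 140),
                                                        days = c(28, 28, 28)),
                                    n = 10000,
                                    scenario = half_life_scenario("uniform"),
                                    spec = NULL, kon = 1.72, kinact = 95.76,
                                    seed = NULL, trough_h = 24,
                                    dt_max = 0.01) {
  stopifnot(all(c("dose_mg", "days") %in% names(cycles)))
  if (any(cycles$days < 1) || any(cycles$dose_mg < 0)) stop("invalid cycles")
  if (is.null(spec)) spec <- population_spec(scenario = scenario)
  individuals <- sample_individuals(spec, n, seed = seed)
  pars <- subject_par_matrix(individuals, spec, kon, kinact)
  total_days <- sum(cycles$days)
  dose_times <- 24 * (seq_len(total_days) - 1)
  amounts <- rep(cycles$dose_mg * 1000, cycles$days)
  eval_times <- 24 * (cumsum(cycles$days) - 1) + trough_h
  occ <- cpp_population_occupancy(pars, dose_times, amounts, eval_times,
                                  dt_max)
  colnames(occ) <- paste0("cycle", seq_len(nrow(cycles)))
  structure(list(occupancy = occ, cycles = cycles, n = n,
                 scenario = spec$scenario, kon = kon, kinact = kinact,
                 seed = seed, eval_times = eval_times),
            class = "btk_dose_reduction")
}

#' @export
print.btk_dose_reduction <- function(x, ...) {
  cat(sprintf("Dose-reduction simulation: n = %d subjects, %d cycle(s)\n",
              x$n, nrow(x$cycles)))
  print(summary(x))
  invisible(x)
}

#' Per-cycle occupancy summary of a dose-reduction run
#'
#' @param object a `btk_dose_reduction`.
#' @param ... unused.
#' @return Data frame with per-cycle median occupancy, 95% prediction
#'   interval (2.5th-97.5th percentiles) and percentage of subjects above 90%.
#' @export
summary.btk_dose_reduction <- function(object, ...) {
  rows <- lapply(seq_len(nrow(object$cycles)), function(j) {
    o <- object$occupancy[, j]
    data.frame(cycle = j, dose_mg = object$cycles$dose_mg[j],
               days = object$cycles$days[j],
               median = median(o),
               pi_lo = as.numeric(quantile(o, 0.025)),
               pi_hi = as.numeric(quantile(o, 0.975)),
               prop_gt90 = 100 * mean(o > 90))
  })
  do.call(rbind, rows)
}

#' Typical-patient trough profiles
#'
#' Deterministic 7-day once-daily simulations of the typical fed CLL patient
#' (no between-subject variability, 80.4 kg) across doses and BTK half-life
#' values. Reports the steady-state trough free drug and free BTK
#' concentrations, the percent reduction of free BTK from baseline, their
#' ratio, and the trough occupancy.
#'
#' @param doses_mg dose levels (mg).
#' @param half_lives BTK half-lives (h).
#' @param days number of once-daily doses.
#' @param pk,pd typical parameter sets.
#' @param trough_h hours after the last dose at which the trough is read.
#' @param dt_max maximum integration step (h).
#' @return Data frame with one row per dose/half-life combination.
#' @export
typical_patient_profiles <- function(doses_mg = c(140, 280, 420, 560),
                                     half_lives = c(24, 60), days = 7,
                                     pk = pk_params(), pd = pd_params(),
                                     trough_h = 24, dt_max = 0.005) {
  eval_time <- 24 * (days - 1) + trough_h
  combos <- expand.grid(dose_mg = doses_mg, t_half_h = half_lives)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    pdi <- pd_params(btk0 = pd$btk0, t_half_btk = combos$t_half_h[i],
                     kon = pd$kon, koff = pd$koff, kinact = pd$kinact,
                     fu = pd$fu, mw = pd$mw)
    traj <- simulate_profile(pk, pdi, qd_regimen(combos$dose_mg[i], days),
                             t_out = c(0, eval_time), dt_max = dt_max)
    last <- traj[nrow(traj), ]
    data.frame(dose_mg = combos$dose_mg[i], t_half_h = combos$t_half_h[i],
               c2_trough_nM = last$c2free_nM, btkf_trough_nM = last$btkf_nM,
               reduction_pct = 100 * (1 - last$btkf_nM / pdi$btk0),
               ratio_c2_btkf = last$c2free_nM / last$btkf_nM,
               occupancy_pct = last$occupancy_pct)
  })
  do.call(rbind, rows)
}
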