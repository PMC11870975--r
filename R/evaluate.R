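#' Observed BTK occupancy dataset
#'
#' Per-dose counts of pre-dose BTK occupancy measurements (days 2, 8, 15
#' and/or 29 of once-daily dosing, phase 1/2 studies in B-cell malignancies)
#' and the percentage of observations above 90% occupancy, for 21 dose levels
#' from 80 to 1400 mg (320 observations in total). Responder counts are
#' reconstructed from the printed percentages by rounding `pct * n / 100` to
#' the nearest integer.
#'
#' @return Data frame of class `btk_observed` with columns `dose_mg`,
#'   `n_obs`, `pct_gt90`, `responders`.
#' @examples
#' obs <- observed_occupancy()
#' sum(obs$n_obs)  # 320
#' @export
observed_occupancy <- function() {
  path <- system.file("extdata", "btk_occupancy_observed.csv",
                      package = "btksim", mustWork = TRUE)
  df <- read.csv(path)
  df$responders <- as.integer(round(df$pct_gt90 * df$n_obs / 100))
  structure(df, class = c("btk_observed", "data.frame"))
}

#' Default dose-group boundaries for pooling
#'
#' Five groups: 80-140, >140-300, >300-500, >500-800 and >800-1400 mg
#' (lower bound exclusive except for the first group, upper inclusive).
#' @return Numeric vector of boundaries (mg).
#' @export
default_dose_groups <- function() c(80, 140, 300, 500, 800, 1400)

#' Pool observed records into dose groups
#'
#' Sums observations and responders within dose groups and computes the
#' pooled proportion with an exact (Clopper-Pearson) 95% binomial confidence
#' interval.
#'
#' @param records observed records as returned by [observed_occupancy()].
#' @param boundaries group boundaries (mg) as in [default_dose_groups()].
#' @return Data frame with one row per group: `group`, `dose_lo`, `dose_hi`,
#'   `n`, `responders`, `prop_pct`, `ci_lo_pct`, `ci_hi_pct`.
#' @export
pool_dose_groups <- function(records = observed_occupancy(),
                             boundaries = default_dose_groups()) {
  stopifnot(all(c("dose_mg", "n_obs", "responders") %in% names(records)))
  if (any(records$dose_mg < boundaries[1] |
          records$dose_mg > boundaries[length(boundaries)]))
    stop("record dose outside all groups")
  idx <- findInterval(records$dose_mg, boundaries, left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[records$dose_mg == boundaries[1]] <- 1L  # first bound inclusive
  rows <- lapply(seq_len(length(boundaries) - 1), function(g) {
    sub <- records[idx == g, ]
    n <- sum(sub$n_obs)
    r <- sum(sub$responders)
    ci <- if (n > 0) binom.test(r, n)$conf.int else c(NA_real_, NA_real_)
    data.frame(group = sprintf("%s%g-%g mg", if (g == 1) "" else ">",
                               boundaries[g], boundaries[g + 1]),
               dose_lo = boundaries[g], dose_hi = boundaries[g + 1],
               n = n, responders = r,
               prop_pct = 100 * r / n,
               ci_lo_pct = 100 * ci[1], ci_hi_pct = 100 * ci[2])
  })
  do.call(rbind, rows)
}

#' Add residual unexplained variability to occupancy values
#'
#' Adds independent normal measurement noise (mean zero, given variance on
#' the percent scale) and clips the result to `[0, 100]`.
#'
#' @param occupancies occupancy values (percent).
#' @param variance residual error variance (percent^2); default 27.1.
#' @param seed optional integer seed.
#' @return Noisy occupancy values (percent).
#' @export
add_ruv <- function(occupancies, variance = 27.1, seed = NULL) {
  if (variance < 0) stop("variance must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (variance == 0) return(occupancies)
  pmin(100, pmax(0, occupancies + rnorm(length(occupancies), 0,
                                        sqrt(variance))))
}

#' Predicted vs observed proportions per dose group
#'
#' Compares pooled observed responder proportions with model predictions.
#' For each group, the predicted proportion under every uncertainty curve is
#' the average of the per-dose predictions at the group's member doses,
#' weighted by the observed number of measurements; the predicted band is the
#' range across curves. A group is flagged as covered when its observed
#' proportion and confidence interval lie within the band (reducing to a
#' point comparison on the observed proportion when only one curve is
#' present).
#'
#' @param sweep a `btk_dose_response` from [dose_response_sweep()] whose dose
#'   grid contains every observed dose, ideally run with
#'   `ruv_variance = 27.1` so predictions carry the same measurement noise
#'   as the data.
#' @param pooled pooled observed groups from [pool_dose_groups()].
#' @param records observed records from [observed_occupancy()].
#' @return Data frame with per-group observed proportion and CI, predicted
#'   median and band (percent), and a `covered` flag.
#' @export
predicted_vs_observed <- function(sweep, pooled = pool_dose_groups(),
                                  records = observed_occupancy()) {
  stopifnot(inherits(sweep, "btk_dose_response"))
  propcol <- if ("prop_gt90_ruv" %in% names(sweep)) "prop_gt90_ruv"
             else "prop_gt90"
  if (!all(records$dose_mg %in% sweep$dose_mg))
    stop("sweep is missing observed doses: ",
         paste(setdiff(records$dose_mg, sweep$dose_mg), collapse = ", "))
  percs <- unique(sweep$percentile)
  central <- percs[which.min(abs(percs - 50))]
  rows <- lapply(seq_len(nrow(pooled)), function(g) {
    in_group <- records$dose_mg > pooled$dose_lo[g] &
      records$dose_mg <= pooled$dose_hi[g]
    if (pooled$dose_lo[g] == min(pooled$dose_lo))
      in_group <- in_group | records$dose_mg == pooled$dose_lo[g]
    sub <- records[in_group, ]
    pred_by_curve <- vapply(percs, function(p) {
      cur <- sweep[sweep$percentile == p, ]
      pr <- cur[[propcol]][match(sub$dose_mg, cur$dose_mg)]
      100 * sum(pr * sub$n_obs) / sum(sub$n_obs)
    }, numeric(1))
    band <- range(pred_by_curve)
    covered <- if (length(percs) > 1) {
      pooled$prop_pct[g] >= band[1] && pooled$prop_pct[g] <= band[2] &&
        pooled$ci_lo_pct[g] >= band[1] && pooled$ci_hi_pct[g] <= band[2]
    } else {
      isTRUE(all.equal(pooled$prop_pct[g], pred_by_curve[1])) ||
        abs(pooled$prop_pct[g] - pred_by_curve[1]) < 1e-8
    }
    data.frame(group = pooled$group[g], n = pooled$n[g],
               observed_pct = pooled$prop_pct[g],
               ci_lo_pct = pooled$ci_lo_pct[g],
               ci_hi_pct = pooled$ci_hi_pct[g],
               predicted_pct = pred_by_curve[percs == central],
               pred_lo_pct = band[1], pred_hi_pct = band[2],
               covered = covered)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic observed occupancy study
#'
#' Emulates the design of the observed dataset: subjects are allocated to
#' once-daily dose cohorts, occupancy is evaluated pre-dose on the given
#' study days (`24 * (day - 1)` hours), and residual unexplained variability
#' is added to each measurement. The generator shares the mechanistic model
#' with the trial engine, so proportions computed from its records are
#' self-consistent with [dose_response_sweep()] predictions up to binomial
#' sampling error.
#'
#' @param allocation data frame with columns `dose_mg` and `n` (subjects per
#'   cohort); defaults to the observed per-dose sample sizes.
#' @param sampling_days study days of the pre-dose measurements.
#' @param scenario a [half_life_scenario()].
#' @param spec optional [population_spec()].
#' @param kon,kinact binding parameters.
#' @param ruv_variance residual error variance (percent^2).
#' @param seed integer seed.
#' @param dt_max maximum integration step (h).
#' @return Data frame with one row per measurement: `subject_id`, `dose_mg`,
#'   `day`, `occupancy_pct` (with residual error, clipped to `[0, 100]`) and
#'   `gt90`.
#' @export
generate_synthetic_study <- function(allocation = NULL,
                                     sampling_days = c(2, 8, 15, 29),
                                     scenario = half_life_scenario("uniform"),
                                     spec = NULL, kon = 1.72, kinact = 95.76,
                                     ruv_variance = 27.1, seed = NULL,
                                     dt_max = 0.01) {
  if (is.null(allocation)) {
    obs <- observed_occupancy()
    allocation <- data.frame(dose_mg = obs$dose_mg, n = obs$n_obs)
  }
  stopifnot(all(c("dose_mg", "n") %in% names(allocation)))
  if (any(sampling_days < 1)) stop("sampling days must be >= 1")
  if (is.null(spec)) spec <- population_spec(scenario = scenario)
  if (!is.null(seed)) set.seed(seed)
  days_dosing <- max(sampling_days) - 1
  eval_times <- 24 * (sampling_days - 1)
  dose_times <- 24 * (seq_len(max(days_dosing, 1)) - 1)
  out <- vector("list", nrow(allocation))
  next_id <- 1
  for (i in seq_len(nrow(allocation))) {
    n_i <- allocation$n[i]
    ind <- sample_individuals(spec, n_i)
    pars <- subject_par_matrix(ind, spec, kon, kinact)
    occ <- cpp_population_occupancy(pars, dose_times,
                                    rep(allocation$dose_mg[i] * 1000,
                                        length(dose_times)),
                                    eval_times, dt_max)
    noisy <- add_ruv(as.numeric(occ), variance = ruv_variance)
    out[[i]] <- data.frame(
      subject_id = rep(next_id:(next_id + n_i - 1), times = length(eval_times)),
      dose_mg = allocation$dose_mg[i],
      day = rep(sampling_days, each = n_i),
      occupancy_pct = noisy)
    next_id <- next_id + n_i
  }
  res <- do.call(rbind, out)
  res$gt90 <- res$occupancy_pct > 90
  res
}
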