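#' Summarize an occupancy distribution
#'
#' Empirical median, 5th and 95th percentiles (linear-interpolation
#' quantiles) and the percentage of values strictly above 90% occupancy.
#'
#' @param occ numeric vector of occupancy values (percent).
#' @return Named numeric vector: `median`, `p5`, `p95`, `prop_gt90` (all in
#'   percent).
#' @export
summarize_occupancy <- function(occ) {
  if (length(occ) == 0) stop("empty occupancy distribution")
  q <- quantile(occ, c(0.05, 0.5, 0.95), names = FALSE)
  c(median = q[2], p5 = q[1], p95 = q[3], prop_gt90 = 100 * mean(occ > 90))
}

#' ED90 of a dose-response curve
#'
#' Fits a sigmoid Emax (Hill) function
#' `p(d) = pmax * d^h / (d50^h + d^h)` to the proportion-above-90%-occupancy
#' curve by least squares and reports the dose at 90% of the fitted plateau,
#' `ED90 = d50 * 9^(1/h)`. For a multi-percentile sweep the ED90 is computed
#' per uncertainty curve; the central estimate comes from the median curve
#' and the interval from the extreme curves.
#'
#' @param curve a `btk_dose_response` or a data frame with columns `dose_mg`
#'   and `prop_gt90` (fraction in `[0, 1]`).
#' @return An object of class `btk_ed90` with fields `ed90`, `ci_low`,
#'   `ci_high` (mg; `NA` when only one curve is available) and the per-curve
#'   fit table.
#' @examples
#' d <- c(10, 30, 100, 300, 1000)
#' curve <- data.frame(dose_mg = d, prop_gt90 = d^2 / (100^2 + d^2))
#' estimate_ed90(curve)$ed90  # exactly 300
#' @export
estimate_ed90 <- function(curve) {
  df <- as.data.frame(curve)
  if (!all(c("dose_mg", "prop_gt90") %in% names(df)))
    stop("curve must have columns dose_mg and prop_gt90")
  if (!("percentile" %in% names(df))) df$percentile <- 50
  fits <- lapply(unique(df$percentile), function(p) {
    sub <- df[df$percentile == p, ]
    fit <- fit_hill(sub$dose_mg, sub$prop_gt90)
    data.frame(percentile = p, pmax = fit[["pmax"]], d50 = fit[["d50"]],
               hill = fit[["h"]], ed90 = fit[["d50"]] * 9^(1 / fit[["h"]]))
  })
  tab <- do.call(rbind, fits)
  central <- tab[which.min(abs(tab$percentile - 50)), ]
  ci <- if (nrow(tab) > 1) range(tab$ed90) else c(NA_real_, NA_real_)
  structure(list(ed90 = central$ed90, ci_low = ci[1], ci_high = ci[2],
                 pmax = central$pmax, d50 = central$d50, hill = central$hill,
                 curves = tab),
            class = "btk_ed90")
}

#' @export
print.btk_ed90 <- function(x, ...) {
  cat(sprintf("ED90 = %.0f mg (plateau %.3f, D50 %.1f mg, Hill %.2f)\n",
              x$ed90, x$pmax, x$d50, x$hill))
  if (!is.na(x$ci_low))
    cat(sprintf("  interval across uncertainty curves: %.0f - %.0f mg\n",
                x$ci_low, x$ci_high))
  invisible(x)
}

# Least-squares Hill fit of a proportion-vs-dose curve.
fit_hill <- function(dose, prop) {
  if (length(dose) < 5) stop("need at least 5 doses spanning the curve rise")
  if (any(prop < 0 | prop > 1)) stop("proportions must be in [0, 1]")
  pmax0 <- max(prop)
  if (pmax0 <= 0) stop("curve is identically zero; cannot estimate ED90")
  d50_0 <- dose[which.min(abs(prop - pmax0 / 2))]
  d50_0 <- max(d50_0, min(dose[dose > 0]))
  fit <- tryCatch(
    minpack.lm::nlsLM(prop ~ pmax * dose^h / (d50^h + dose^h),
                      start = list(pmax = pmax0, d50 = d50_0, h = 1.2),
                      lower = c(pmax = 1e-3, d50 = 1e-3, h = 0.1),
                      upper = c(pmax = 1.0, d50 = 1e5, h = 10),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Hill fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  if (max(prop) < 0.75 * cf[["pmax"]])
    stop("plateau not approached by the dose grid; extend the sweep ",
         sprintf("(max observed %.3f vs fitted plateau %.3f)",
                 max(prop), cf[["pmax"]]))
  c(pmax = cf[["pmax"]], d50 = cf[["d50"]], h = cf[["h"]])
}

#' Difference between two dose-response curves
#'
#' Interpolates both curves onto a common dose grid and returns the
#' difference of the proportions in percentage points.
#'
#' @param curve_a,curve_b `btk_dose_response` objects or data frames with
#'   `dose_mg` and `prop_gt90` (fractions). Multi-percentile sweeps are
#'   reduced to their central curve.
#' @param doses_mg optional dose grid; defaults to the overlap of the two
#'   curves' grids.
#' @return Data frame with `dose_mg` and `diff_pp` (`a - b`, percentage
#'   points).
#' @export
curve_difference <- function(curve_a, curve_b, doses_mg = NULL) {
  a <- if (inherits(curve_a, "btk_dose_response")) central_curve(curve_a)
       else as.data.frame(curve_a)
  b <- if (inherits(curve_b, "btk_dose_response")) central_curve(curve_b)
       else as.data.frame(curve_b)
  lo <- max(min(a$dose_mg), min(b$dose_mg))
  hi <- min(max(a$dose_mg), max(b$dose_mg))
  if (lo > hi) stop("dose ranges do not overlap")
  if (is.null(doses_mg)) {
    doses_mg <- sort(unique(c(a$dose_mg, b$dose_mg)))
    doses_mg <- doses_mg[doses_mg >= lo & doses_mg <= hi]
  } else if (any(doses_mg < lo | doses_mg > hi)) {
    stop("requested doses outside the common range")
  }
  pa <- approx(a$dose_mg, a$prop_gt90, doses_mg)$y
  pb <- approx(b$dose_mg, b$prop_gt90, doses_mg)$y
  data.frame(dose_mg = doses_mg, diff_pp = 100 * (pa - pb))
}
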