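#' Oral dosing regimens
#'
#' A regimen is a data frame of oral dose events with columns `time` (h),
#' `amount_ug` (dose in mg times 1000), `fed` and `antacid`. The food and
#' antacid flags select the bioavailability (`F1` = 1 fed, 0.67 fasted) and
#' the zero-order input duration (`D` = 3.29 h fed, 1.10 h fasted, times 1.61
#' with antacids) applied to the event.
#'
#' @param dose_mg dose per administration (mg); must be non-negative.
#' @param days number of once-daily administrations.
#' @param fed,antacid logical covariate flags applied to every event.
#' @param start_h time of the first dose (h).
#' @return An object of class `btk_regimen`.
#' @examples
#' qd_regimen(420, days = 7)
#' @export
qd_regimen <- function(dose_mg, days = 7, fed = TRUE, antacid = FALSE,
                       start_h = 0) {
  if (!is.numeric(dose_mg) || length(dose_mg) != 1 || dose_mg < 0)
    stop("dose_mg must be a single non-negative number")
  if (days < 1) stop("days must be >= 1")
  ev <- data.frame(time = start_h + 24 * (seq_len(days) - 1),
                   amount_ug = dose_mg * 1000,
                   fed = fed, antacid = antacid)
  structure(ev, class = c("btk_regimen", "data.frame"))
}

#' Sequential multi-cycle regimen (dose reductions)
#'
#' Builds a contiguous once-daily regimen from ordered cycles, e.g. the
#' 420 -> 280 -> 140 mg reduction cascade with three 28-day cycles.
#'
#' @param cycles data frame with columns `dose_mg` and `days`.
#' @inheritParams qd_regimen
#' @return An object of class `btk_regimen` with attribute `cycles`.
#' @examples
#' reduction_regimen()  # default 420/280/140 mg, 28 days each
#' @export
reduction_regimen <- function(cycles = data.frame(dose_mg = c(420, 280, 140),
                                                  days = c(28, 28, 28)),
                              fed = TRUE, antacid = FALSE) {
  stopifnot(is.data.frame(cycles), all(c("dose_mg", "days") %in% names(cycles)))
  if (any(cycles$dose_mg < 0) || any(cycles$days < 1))
    stop("cycles must have non-negative doses and days >= 1")
  start <- 0
  evs <- vector("list", nrow(cycles))
  for (i in seq_len(nrow(cycles))) {
    evs[[i]] <- qd_regimen(cycles$dose_mg[i], cycles$days[i], fed = fed,
                           antacid = antacid, start_h = start)
    start <- start + 24 * cycles$days[i]
  }
  out <- do.call(rbind, lapply(evs, as.data.frame))
  structure(out, class = c("btk_regimen", "data.frame"), cycles = cycles)
}

#' @export
print.btk_regimen <- function(x, ...) {
  cat(sprintf("Oral dosing regimen: %d event(s), %.0f to %.0f h\n",
              nrow(x), min(x$time), max(x$time)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more events\n")
  invisible(x)
}

# Effective absorption quantities for one event given the PK parameter set
# (typical or individual): returns f1 and D after food/antacid adjustment.
event_absorption <- function(pk, fed, antacid) {
  f1 <- if (fed) pk$f1_fed else pk$f1_fasted
  d0 <- if (fed) pk$d_fed else pk$d_fasted
  if (antacid) d0 <- d0 * pk$antacid_d_factor
  list(f1 = f1, d_zero = d0)
}

# Piecewise-constant depot input implied by a regimen: returns breaks (h) and
# the input rate (ug/h) on each interval, with t_out merged into the breaks.
build_input_segments <- function(regimen, pk, t_out) {
  t_end <- max(t_out)
  starts <- ends <- rates <- numeric(nrow(regimen))
  for (i in seq_len(nrow(regimen))) {
    ab <- event_absorption(pk, regimen$fed[i], regimen$antacid[i])
    starts[i] <- regimen$time[i] + pk$tlag
    ends[i] <- starts[i] + ab$d_zero
    rates[i] <- ab$f1 * regimen$amount_ug[i] / ab$d_zero
  }
  edges <- sort(unique(c(0, t_out, starts[starts < t_end],
                         ends[ends < t_end], t_end)))
  edges <- edges[edges >= 0 & edges <= t_end]
  edges <- edges[c(TRUE, diff(edges) > 1e-9)]
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  seg_rate <- vapply(mids, function(m) {
    sum(rates[m >= starts & m < ends])
  }, numeric(1))
  list(breaks = edges, rates = seg_rate)
}
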