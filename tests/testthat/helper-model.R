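# Shared fixtures for the test suite.

typical_pk <- function() pk_params()
typical_pd <- function(t_half = 60) pd_params(t_half_btk = t_half)

# Population spec with all between-subject variability switched off and a
# degenerate half-life (for comparing population runs against the typical
# subject).
degenerate_spec <- function(t_half = 60) {
  bsv <- default_bsv()
  bsv[] <- 0
  population_spec(scenario = half_life_scenario("slow", hours = t_half,
                                                cv = 0),
                  bsv = bsv)
}

# Reference right-hand side of the six-state model, written independently of
# the package internals, for use with deSolve (oracle route).
reference_rhs <- function(t, y, p) {
  R <- 0
  for (k in seq_along(p$dose_times)) {
    s <- p$dose_times[k] + p$tlag
    if (t >= s && t < s + p$D) R <- R + p$f1 * p$amount_ug[k] / p$D
  }
  C2 <- 1000 * p$fu * (y[2] / p$v2) / p$mw
  list(c(R - p$ka * y[1],
         p$ka * y[1] - (p$kel + p$k23) * y[2] + p$k32 * y[3],
         p$k23 * y[2] - p$k32 * y[3],
         p$ksyn - p$kon * C2 * y[4] + p$koff * y[5] - p$kdeg * y[4],
         p$kon * C2 * y[4] - (p$koff + p$kinact) * y[5],
         p$kinact * y[5] - p$kdeg * y[6]))
}

# Integrate the reference model with a stiff adaptive solver, restarting at
# every input discontinuity.
reference_trajectory <- function(dose_mg, days, t_half = 60, t_out) {
  pk <- typical_pk()
  pd <- typical_pd(t_half)
  r <- derive_pk_rates(pk)
  p <- list(dose_times = 24 * (seq_len(days) - 1),
            amount_ug = rep(dose_mg * 1000, days),
            tlag = pk$tlag, D = pk$d_fed, f1 = pk$f1_fed,
            ka = pk$ka, kel = r[["kel"]], k23 = r[["k23"]], k32 = r[["k32"]],
            v2 = r[["v2"]], fu = pd$fu, mw = pd$mw,
            ksyn = pd$ksyn, kdeg = pd$kdeg, kon = pd$kon, koff = pd$koff,
            kinact = pd$kinact)
  bps <- sort(unique(c(0, p$dose_times + p$tlag, p$dose_times + p$tlag + p$D,
                       t_out)))
  bps <- bps[bps <= max(t_out)]
  y <- c(0, 0, 0, pd$btk0, 0, 0)
  out <- matrix(NA_real_, length(t_out), 6)
  if (any(t_out == 0)) out[t_out == 0, ] <- rep(y, each = sum(t_out == 0))
  for (i in seq_len(length(bps) - 1)) {
    o <- deSolve::lsoda(y, c(bps[i], bps[i + 1]), reference_rhs, p,
                        rtol = 1e-10, atol = 1e-12)
    y <- as.numeric(o[nrow(o), -1])
    hit <- which(abs(t_out - bps[i + 1]) < 1e-9)
    if (length(hit)) out[hit, ] <- rep(y, each = length(hit))
  }
  out
}
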