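#' Pharmacokinetic parameter set
#'
#' Apparent (oral) parameters of the ibrutinib two-compartment disposition
#' model with sequential zero/first-order absorption. Defaults are the
#' published population typical values for a fed CLL patient of median body
#' weight. Volumes carry an allometric body-weight correction
#' `(weight / ref_weight)^wt_v_exp`; clearances do not.
#'
#' @param cl_f apparent clearance CL/F (L/h).
#' @param v2_f apparent central volume V2/F (L), before allometric scaling.
#' @param q_f apparent inter-compartmental clearance Q/F (L/h).
#' @param v3_f apparent peripheral volume V3/F (L), before allometric scaling.
#' @param ka first-order absorption rate constant (1/h).
#' @param tlag absorption lag time (h).
#' @param d_fed,d_fasted duration of the zero-order input into the depot (h)
#'   under fed and fasted conditions.
#' @param f1_fed,f1_fasted relative bioavailability under fed and fasted
#'   conditions (fraction).
#' @param antacid_d_factor multiplicative effect of antacid coadministration
#'   on the zero-order duration.
#' @param weight body weight (kg).
#' @param wt_v_exp allometric exponent on volumes.
#' @param ref_weight reference (median) body weight (kg).
#' @return An object of class `btk_pk`.
#' @examples
#' pk <- pk_params()
#' derive_pk_rates(pk)
#' @export
pk_params <- function(cl_f = 1060, v2_f = 246, q_f = 865, v3_f = 9620,
                      ka = 0.463, tlag = 0.283,
                      d_fed = 3.29, d_fasted = 1.10,
                      f1_fed = 1, f1_fasted = 0.67,
                      antacid_d_factor = 1.61,
                      weight = 80.4, wt_v_exp = 0.641, ref_weight = 80.4) {
  p <- list(cl_f = cl_f, v2_f = v2_f, q_f = q_f, v3_f = v3_f, ka = ka,
            tlag = tlag, d_fed = d_fed, d_fasted = d_fasted,
            f1_fed = f1_fed, f1_fasted = f1_fasted,
            antacid_d_factor = antacid_d_factor,
            weight = weight, wt_v_exp = wt_v_exp, ref_weight = ref_weight)
  pos <- c("cl_f", "v2_f", "q_f", "v3_f", "ka", "d_fed", "d_fasted",
           "f1_fed", "f1_fasted", "antacid_d_factor", "weight", "ref_weight")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("pk parameter '", nm, "' must be a single positive number")
    }
  }
  if (tlag < 0) stop("pk parameter 'tlag' must be non-negative")
  structure(p, class = "btk_pk")
}

#' Pharmacodynamic (covalent binding) parameter set
#'
#' Parameters of the free-BTK turnover and ibrutinib-BTK covalent binding
#' model. The degradation rate is `kdeg = ln(2) / t_half_btk`, the synthesis
#' rate `ksyn = btk0 * kdeg`, and the covalent complex degrades at
#' `kdegc = kdeg`. The binding constant of the reversible step is
#' `KI = (koff + kinact) / kon`; since `kinact >> koff` for ibrutinib, `kon`
#' is well approximated by `kinact / KI`.
#'
#' @param btk0 baseline free BTK concentration (nM).
#' @param t_half_btk free BTK half-life (h).
#' @param kon association rate constant (1/nM/h).
#' @param koff dissociation rate constant (1/h).
#' @param kinact maximum rate of covalent inactivation of the reversible
#'   complex (1/h).
#' @param fu unbound fraction of ibrutinib in plasma.
#' @param mw ibrutinib molecular weight (g/mol).
#' @return An object of class `btk_pd` with derived fields `kdeg`, `ksyn`,
#'   `kdegc` and `ki`.
#' @examples
#' pd <- pd_params(t_half_btk = 60)
#' pd$kdeg  # ln(2)/60
#' @export
pd_params <- function(btk0 = 1.04, t_half_btk = 60, kon = 1.72, koff = 0.205,
                      kinact = 95.76, fu = 0.03, mw = 440.5) {
  for (nm in c("btk0", "t_half_btk", "kon", "koff", "kinact", "fu", "mw")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("pd parameter '", nm, "' must be a single positive number")
  }
  rates <- derive_btk_rates(btk0, t_half_btk)
  structure(list(btk0 = btk0, t_half_btk = t_half_btk,
                 kdeg = rates[["kdeg"]], ksyn = rates[["ksyn"]],
                 kdegc = rates[["kdeg"]],
                 kon = kon, koff = koff, kinact = kinact,
                 ki = (koff + kinact) / kon, fu = fu, mw = mw),
            class = "btk_pd")
}

#' @export
print.btk_pk <- function(x, ...) {
  cat("Ibrutinib PK parameters (apparent, oral)\n")
  cat(sprintf("  CL/F %.4g L/h, V2/F %.4g L, Q/F %.4g L/h, V3/F %.4g L\n",
              x$cl_f, x$v2_f, x$q_f, x$v3_f))
  cat(sprintf("  ka %.3g 1/h, tlag %.3g h, D %.3g h (fed) / %.3g h (fasted)\n",
              x$ka, x$tlag, x$d_fed, x$d_fasted))
  cat(sprintf("  F1 %.3g (fed) / %.3g (fasted); weight %.4g kg (ref %.4g, exp %.3g on volumes)\n",
              x$f1_fed, x$f1_fasted, x$weight, x$ref_weight, x$wt_v_exp))
  invisible(x)
}

#' @export
print.btk_pd <- function(x, ...) {
  cat("BTK turnover and covalent binding parameters\n")
  cat(sprintf("  BTK0 %.3g nM, t1/2 %.4g h (kdeg %.4g 1/h, ksyn %.4g nM/h)\n",
              x$btk0, x$t_half_btk, x$kdeg, x$ksyn))
  cat(sprintf("  kon %.3g 1/nM/h, koff %.3g 1/h, kinact %.4g 1/h (KI %.3g nM)\n",
              x$kon, x$koff, x$kinact, x$ki))
  cat(sprintf("  fu %.3g, MW %.4g g/mol\n", x$fu, x$mw))
  invisible(x)
}

#' Allometric scaling factor on volumes
#' @param pk a [pk_params()] object.
#' @return The multiplicative factor applied to V2/F and V3/F.
#' @export
allometric_factor <- function(pk) {
  (pk$weight / pk$ref_weight)^pk$wt_v_exp
}

#' Secondary (micro) rate constants of the disposition model
#'
#' `kel = CL/V2`, `k23 = Q/V2`, `k32 = Q/V3`, with the volumes taken after
#' allometric body-weight scaling.
#'
#' @param pk a [pk_params()] object.
#' @return Named numeric vector with `kel`, `k23`, `k32` (1/h) and the scaled
#'   central volume `v2` (L).
#' @export
derive_pk_rates <- function(pk) {
  stopifnot(inherits(pk, "btk_pk"))
  fwt <- allometric_factor(pk)
  v2 <- pk$v2_f * fwt
  v3 <- pk$v3_f * fwt
  c(kel = pk$cl_f / v2, k23 = pk$q_f / v2, k32 = pk$q_f / v3, v2 = v2)
}

#' BTK turnover rate constants
#'
#' @param btk0 baseline free BTK (nM).
#' @param t_half_btk free BTK half-life (h).
#' @return Named vector with `kdeg = ln(2)/t_half_btk` (1/h) and
#'   `ksyn = btk0 * kdeg` (nM/h).
#' @export
derive_btk_rates <- function(btk0, t_half_btk) {
  if (any(btk0 <= 0) || any(t_half_btk <= 0))
    stop("btk0 and t_half_btk must be positive")
  kdeg <- log(2) / t_half_btk
  c(kdeg = kdeg, ksyn = btk0 * kdeg)
}

#' Free drug concentration in the central compartment
#'
#' Converts a central-compartment amount to the free molar concentration:
#' `C2 = 1000 * fu * (A2 / V2) / MW`. With the amount in micrograms and the
#' volume in litres, `A2/V2` is in ug/L (equivalently ng/mL) and the result is
#' in nM.
#'
#' @param a2 central compartment amount (ug); vectorized.
#' @param v2 central volume of distribution (L), after allometric scaling.
#' @param fu unbound fraction.
#' @param mw molecular weight (g/mol).
#' @return Free concentration (nM).
#' @export
free_concentration_nM <- function(a2, v2, fu = 0.03, mw = 440.5) {
  if (v2 <= 0) stop("v2 must be positive")
  1000 * fu * (a2 / v2) / mw
}

#' BTK occupancy statistic
#'
#' Fraction of total BTK bound by drug, reversibly or covalently, expressed in
#' percent: `100 * (rc + cc) / (f + rc + cc)`. This is the intrinsic
#' occupancy, without residual (assay) error.
#'
#' @param btk_f free BTK (nM).
#' @param btk_rc reversible ibrutinib-BTK complex (nM).
#' @param btk_cc covalent ibrutinib-BTK complex (nM).
#' @return Occupancy in percent, in `[0, 100]`. Vectorized.
#' @export
occupancy_percent <- function(btk_f, btk_rc, btk_cc) {
  total <- btk_f + btk_rc + btk_cc
  if (any(total <= 0)) stop("occupancy undefined: total BTK is zero")
  100 * (btk_rc + btk_cc) / total
}

#' Steady-state occupancy at a constant free drug concentration
#'
#' Closed-form plateau of the binding subsystem when the free drug
#' concentration is held constant: setting the three BTK derivatives to zero
#' gives `btk_f* = ksyn / (kdeg + kon C kinact / (koff + kinact))`,
#' `rc* = kon C btk_f* / (koff + kinact)` and `cc* = kinact rc* / kdegc`.
#' Serves as an analytic oracle for the numerical integrator.
#'
#' @param c_free constant free drug concentration (nM); vectorized.
#' @param pd a [pd_params()] object.
#' @return Occupancy in percent at the plateau.
#' @export
steady_state_occupancy <- function(c_free, pd) {
  stopifnot(inherits(pd, "btk_pd"))
  if (any(c_free < 0)) stop("c_free must be non-negative")
  keff <- pd$kon * c_free * pd$kinact / (pd$koff + pd$kinact)
  f <- pd$ksyn / (pd$kdeg + keff)
  rc <- pd$kon * c_free * f / (pd$koff + pd$kinact)
  cc <- pd$kinact * rc / pd$kdegc
  occupancy_percent(f, rc, cc)
}
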