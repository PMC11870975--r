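#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// State layout: y[0..2] = depot/central/peripheral ibrutinib amounts (ug),
// y[3..5] = free BTK / reversible complex / covalent complex (nM).
// Parameter layout (length 11):
//   0 ka, 1 kel, 2 k23, 3 k32, 4 c2f (C2 = c2f * A2, nM per ug),
//   5 ksyn, 6 kdeg, 7 kon, 8 koff, 9 kinact, 10 kdegc
static inline void rhs(const double* y, const double R, const double* p,
                       double* dy) {
  const double C2 = p[4] * y[1];
  dy[0] = R - p[0] * y[0];
  dy[1] = p[0] * y[0] - (p[1] + p[2]) * y[1] + p[3] * y[2];
  dy[2] = p[2] * y[1] - p[3] * y[2];
  dy[3] = p[5] - p[7] * C2 * y[3] + p[8] * y[4] - p[6] * y[3];
  dy[4] = p[7] * C2 * y[3] - (p[8] + p[9]) * y[4];
  dy[5] = p[9] * y[4] - p[10] * y[5];
}

static inline void rk4_step(double* y, const double R, const double* p,
                            const double h) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  rhs(y, R, p, k1);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  rhs(tmp, R, p, k2);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  rhs(tmp, R, p, k3);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + h * k3[i];
  rhs(tmp, R, p, k4);
  for (int i = 0; i < 6; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * (k2[i] + k3[i]) + k4[i]);
}

// Largest first-order rate in the system; the explicit RK4 step is capped at
// 2/lambda_max (stability boundary ~2.785 on the negative real axis).
static inline double step_cap(const double* p, const double dt_max) {
  double lam = p[0];
  if (p[1] + p[2] > lam) lam = p[1] + p[2];
  if (p[3] > lam) lam = p[3];
  if (p[8] + p[9] > lam) lam = p[8] + p[9];
  if (p[6] > lam) lam = p[6];
  double dt = dt_max;
  if (lam > 0 && 2.0 / lam < dt) dt = 2.0 / lam;
  return dt;
}

// Piecewise integration over intervals [breaks[i], breaks[i+1]) with constant
// depot input rate rates[i]; records the state wherever a break coincides with
// an output time (t_out must be a subset of breaks).
// [[Rcpp::export]]
NumericMatrix cpp_simulate(NumericVector params, double btk0,
                           NumericVector breaks, NumericVector rates,
                           NumericVector t_out, double dt_max) {
  const int nb = breaks.size();
  if (rates.size() != nb - 1) stop("rates must have length(breaks) - 1");
  const int nout = t_out.size();
  NumericMatrix out(nout, 6);
  double p[11];
  for (int i = 0; i < 11; ++i) p[i] = params[i];
  const double dt = step_cap(p, dt_max);

  double y[6] = {0.0, 0.0, 0.0, btk0, 0.0, 0.0};
  int iout = 0;
  while (iout < nout && std::fabs(t_out[iout] - breaks[0]) < 1e-9) {
    for (int j = 0; j < 6; ++j) out(iout, j) = y[j];
    ++iout;
  }
  for (int i = 0; i < nb - 1; ++i) {
    const double len = breaks[i + 1] - breaks[i];
    if (len < 0) stop("breaks must be non-decreasing");
    if (len > 0) {
      const int nsub = (int)std::ceil(len / dt - 1e-12);
      const double h = len / nsub;
      const double R = rates[i];
      for (int s = 0; s < nsub; ++s) rk4_step(y, R, p, h);
    }
    while (iout < nout && std::fabs(t_out[iout] - breaks[i + 1]) < 1e-9) {
      for (int j = 0; j < 6; ++j) out(iout, j) = (y[j] > 0.0 ? y[j] : 0.0);
      ++iout;
    }
  }
  if (iout < nout) stop("output times must coincide with break points");
  return out;
}

// Builds the piecewise-constant depot input implied by dose events with
// subject-specific lag, zero-order duration and bioavailability, merging the
// edges with requested evaluation times.
static void build_segments(const std::vector<double>& dose_t,
                           const std::vector<double>& dose_amt,
                           const double tlag, const double dur, const double f1,
                           const NumericVector& eval_t, const double t_end,
                           std::vector<double>& breaks,
                           std::vector<double>& rates) {
  std::vector<double> edges;
  edges.push_back(0.0);
  edges.push_back(t_end);
  for (size_t k = 0; k < dose_t.size(); ++k) {
    const double s = dose_t[k] + tlag;
    if (s < t_end) edges.push_back(s);
    if (s + dur < t_end) edges.push_back(s + dur);
  }
  for (int k = 0; k < eval_t.size(); ++k)
    if (eval_t[k] > 0 && eval_t[k] < t_end) edges.push_back(eval_t[k]);
  std::sort(edges.begin(), edges.end());
  breaks.clear();
  for (size_t k = 0; k < edges.size(); ++k)
    if (breaks.empty() || edges[k] - breaks.back() > 1e-9)
      breaks.push_back(edges[k]);
  rates.assign(breaks.size() - 1, 0.0);
  for (size_t i = 0; i + 1 < breaks.size(); ++i) {
    const double mid = 0.5 * (breaks[i] + breaks[i + 1]);
    double R = 0.0;
    for (size_t k = 0; k < dose_t.size(); ++k) {
      const double s = dose_t[k] + tlag;
      if (mid >= s && mid < s + dur) R += f1 * dose_amt[k] / dur;
    }
    rates[i] = R;
  }
}

// Virtual population run for one shared dose schedule. `pars` holds one row
// per subject: the 11 ODE parameters followed by btk0, tlag, D, f1.
// Returns occupancy (%) at each evaluation time, one row per subject.
// [[Rcpp::export]]
NumericMatrix cpp_population_occupancy(NumericMatrix pars,
                                       NumericVector dose_times,
                                       NumericVector dose_amt_ug,
                                       NumericVector eval_times,
                                       double dt_max) {
  const int n = pars.nrow();
  const int ne = eval_times.size();
  if (pars.ncol() != 15) stop("pars must have 15 columns");
  if (dose_times.size() != dose_amt_ug.size())
    stop("dose_times and dose_amt_ug lengths differ");
  double t_end = 0.0;
  for (int k = 0; k < ne; ++k) if (eval_times[k] > t_end) t_end = eval_times[k];
  std::vector<double> dt_(dose_times.begin(), dose_times.end());
  std::vector<double> da_(dose_amt_ug.begin(), dose_amt_ug.end());
  NumericMatrix occ(n, ne);

  std::vector<double> breaks, rates;
  for (int i = 0; i < n; ++i) {
    double p[11];
    for (int j = 0; j < 11; ++j) p[j] = pars(i, j);
    const double btk0 = pars(i, 11), tlag = pars(i, 12), dur = pars(i, 13),
                 f1 = pars(i, 14);
    build_segments(dt_, da_, tlag, dur, f1, eval_times, t_end, breaks, rates);
    const double dt = step_cap(p, dt_max);
    double y[6] = {0.0, 0.0, 0.0, btk0, 0.0, 0.0};
    size_t nb = breaks.size();
    int iout_done = 0;
    std::vector<int> matched(ne, 0);
    for (size_t b = 0; b + 1 < nb; ++b) {
      const double len = breaks[b + 1] - breaks[b];
      if (len > 0) {
        const int nsub = (int)std::ceil(len / dt - 1e-12);
        const double h = len / nsub;
        const double R = rates[b];
        for (int s = 0; s < nsub; ++s) rk4_step(y, R, p, h);
      }
      for (int k = 0; k < ne; ++k) {
        if (!matched[k] && std::fabs(eval_times[k] - breaks[b + 1]) < 1e-9) {
          const double f = y[3] > 0 ? y[3] : 0, rc = y[4] > 0 ? y[4] : 0,
                       cc = y[5] > 0 ? y[5] : 0;
          const double tot = f + rc + cc;
          occ(i, k) = tot > 0 ? 100.0 * (rc + cc) / tot : NA_REAL;
          matched[k] = 1;
          ++iout_done;
        }
      }
    }
    for (int k = 0; k < ne; ++k)
      if (!matched[k]) {
        if (eval_times[k] == 0.0) { occ(i, k) = 0.0; ++iout_done; }
        else stop("evaluation time beyond simulation span");
      }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return occ;
}

// Dose-response sweep with common random numbers: each subject's unit-dose
// pharmacokinetic profile is integrated once (the disposition is linear in
// dose), then the three BTK states are integrated per dose with the free
// concentration scaled by the dose amount.
// [[Rcpp::export]]
NumericMatrix cpp_sweep_occupancy(NumericMatrix pars, NumericVector dose_times,
                                  NumericVector doses_mg, double eval_time,
                                  double dt_max) {
  const int n = pars.nrow();
  const int nd = doses_mg.size();
  if (pars.ncol() != 15) stop("pars must have 15 columns");
  NumericMatrix occ(n, nd);
  NumericVector eval_t(1);
  eval_t[0] = eval_time;
  std::vector<double> dt_(dose_times.begin(), dose_times.end());
  std::vector<double> unit(dose_times.size(), 1.0);  // 1 ug per dose
  std::vector<double> breaks, rates, c2grid;

  for (int i = 0; i < n; ++i) {
    double p[11];
    for (int j = 0; j < 11; ++j) p[j] = pars(i, j);
    const double btk0 = pars(i, 11), tlag = pars(i, 12), dur = pars(i, 13),
                 f1 = pars(i, 14);
    build_segments(dt_, unit, tlag, dur, f1, eval_t, eval_time, breaks, rates);
    const double dt = step_cap(p, dt_max);
    const size_t nb = breaks.size();

    // Pass 1: PK states only, half-step grid so that C2 is available at the
    // nodes and midpoints of the coarser BTK steps.
    size_t total = 1;
    std::vector<int> nsubs(nb - 1, 0);
    for (size_t b = 0; b + 1 < nb; ++b) {
      const double len = breaks[b + 1] - breaks[b];
      nsubs[b] = len > 0 ? (int)std::ceil(len / dt - 1e-12) : 0;
      total += 2 * (size_t)nsubs[b];
    }
    c2grid.assign(total, 0.0);
    {
      double ypk[3] = {0.0, 0.0, 0.0};
      size_t idx = 0;
      c2grid[idx++] = p[4] * ypk[1];
      for (size_t b = 0; b + 1 < nb; ++b) {
        const int nsub = nsubs[b];
        if (nsub == 0) continue;
        const double h2 = (breaks[b + 1] - breaks[b]) / (2.0 * nsub);
        const double R = rates[b];
        for (int s = 0; s < 2 * nsub; ++s) {
          // RK4 on the 3 linear PK states
          double k1[3], k2[3], k3[3], tmp[3], k4[3];
          for (int rep = 0; rep < 1; ++rep) {
            k1[0] = R - p[0] * ypk[0];
            k1[1] = p[0] * ypk[0] - (p[1] + p[2]) * ypk[1] + p[3] * ypk[2];
            k1[2] = p[2] * ypk[1] - p[3] * ypk[2];
            for (int q = 0; q < 3; ++q) tmp[q] = ypk[q] + 0.5 * h2 * k1[q];
            k2[0] = R - p[0] * tmp[0];
            k2[1] = p[0] * tmp[0] - (p[1] + p[2]) * tmp[1] + p[3] * tmp[2];
            k2[2] = p[2] * tmp[1] - p[3] * tmp[2];
            for (int q = 0; q < 3; ++q) tmp[q] = ypk[q] + 0.5 * h2 * k2[q];
            k3[0] = R - p[0] * tmp[0];
            k3[1] = p[0] * tmp[0] - (p[1] + p[2]) * tmp[1] + p[3] * tmp[2];
            k3[2] = p[2] * tmp[1] - p[3] * tmp[2];
            for (int q = 0; q < 3; ++q) tmp[q] = ypk[q] + h2 * k3[q];
            k4[0] = R - p[0] * tmp[0];
            k4[1] = p[0] * tmp[0] - (p[1] + p[2]) * tmp[1] + p[3] * tmp[2];
            k4[2] = p[2] * tmp[1] - p[3] * tmp[2];
            for (int q = 0; q < 3; ++q)
              ypk[q] += h2 / 6.0 * (k1[q] + 2.0 * (k2[q] + k3[q]) + k4[q]);
          }
          c2grid[idx++] = p[4] * ypk[1];
        }
      }
    }

    // Pass 2: BTK states per dose, C2 read off the cached unit profile.
    for (int d = 0; d < nd; ++d) {
      const double mult = doses_mg[d] * 1000.0;  // mg -> ug per unit amount
      double f = btk0, rc = 0.0, cc = 0.0;
      size_t idx = 0;
      const double kon = p[7], koff = p[8], kin = p[9], ksyn = p[5],
                   kdeg = p[6], kdegc = p[10];
      for (size_t b = 0; b + 1 < nb; ++b) {
        const int nsub = nsubs[b];
        if (nsub == 0) continue;
        const double h = (breaks[b + 1] - breaks[b]) / nsub;
        for (int s = 0; s < nsub; ++s) {
          const double c0 = mult * c2grid[idx], cm = mult * c2grid[idx + 1],
                       c1 = mult * c2grid[idx + 2];
          idx += 2;
          double k1f, k1r, k1c, k2f, k2r, k2c, k3f, k3r, k3c, k4f, k4r, k4c;
          double tf, tr;
          k1f = ksyn - kon * c0 * f + koff * rc - kdeg * f;
          k1r = kon * c0 * f - (koff + kin) * rc;
          k1c = kin * rc - kdegc * cc;
          tf = f + 0.5 * h * k1f; tr = rc + 0.5 * h * k1r;
          k2f = ksyn - kon * cm * tf + koff * tr - kdeg * tf;
          k2r = kon * cm * tf - (koff + kin) * tr;
          k2c = kin * tr - kdegc * (cc + 0.5 * h * k1c);
          tf = f + 0.5 * h * k2f; tr = rc + 0.5 * h * k2r;
          k3f = ksyn - kon * cm * tf + koff * tr - kdeg * tf;
          k3r = kon * cm * tf - (koff + kin) * tr;
          k3c = kin * tr - kdegc * (cc + 0.5 * h * k2c);
          tf = f + h * k3f; tr = rc + h * k3r;
          k4f = ksyn - kon * c1 * tf + koff * tr - kdeg * tf;
          k4r = kon * c1 * tf - (koff + kin) * tr;
          k4c = kin * tr - kdegc * (cc + h * k3c);
          f += h / 6.0 * (k1f + 2.0 * (k2f + k3f) + k4f);
          rc += h / 6.0 * (k1r + 2.0 * (k2r + k3r) + k4r);
          cc += h / 6.0 * (k1c + 2.0 * (k2c + k3c) + k4c);
        }
      }
      const double ff = f > 0 ? f : 0, rr = rc > 0 ? rc : 0,
                   ccc = cc > 0 ? cc : 0;
      const double tot = ff + rr + ccc;
      occ(i, d) = tot > 0 ? 100.0 * (rr + ccc) / tot : NA_REAL;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return occ;
}
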