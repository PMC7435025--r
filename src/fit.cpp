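#include "kinetic.h"
#include <climits>
using namespace Rcpp;

// Bounded Levenberg-Marquardt least squares for the 5-parameter
// convolution model. Accept-only updates guarantee the returned objective
// never exceeds the objective at the initialization. Hot loops use a
// preallocated workspace shared across starts and voxels.

namespace {

constexpr int NP = 5;

struct Workspace {
  arma::vec irf, pred, r, r_try;
  arma::mat J, dirf;
  Workspace(int n)
      : irf(n), pred(n), r(n), r_try(n), J(n, NP), dirf(n, NP) {}
};

struct LMResult {
  double theta[NP];
  double sse = 0.0;
  int n_iter = 0;
  bool converged = false;
};

inline void clamp_to(double* th, const double* lo, const double* hi) {
  for (int p = 0; p < NP; ++p) {
    if (th[p] < lo[p]) th[p] = lo[p];
    if (th[p] > hi[p]) th[p] = hi[p];
  }
}

// residual r = conv(aif, irf) * dt - tc
inline double residual_only(const double* th, const arma::vec& tc,
                            const arma::vec& aif, double dt, Workspace& w) {
  const int n = aif.n_elem;
  ath_irf_lags(w.irf, n, dt, th[0], th[1], th[2], th[3], th[4]);
  const int l0 = std::min<int>(n, std::max(0, (int)std::ceil(th[1] / dt - 1e-12)));
  double sse = 0.0;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int l = l0; l <= i; ++l) acc += aif[i - l] * w.irf[l];
    const double ri = dt * acc - tc[i];
    w.r_try[i] = ri;
    sse += ri * ri;
  }
  return sse;
}

// Jacobian of the residual at th (r itself is already in w.r)
inline void jacobian(const double* th, const arma::vec& aif, double dt,
                     Workspace& w) {
  const int n = aif.n_elem;
  double g[NP];
  for (int l = 0; l < n; ++l) {
    ath_irf_grad(l * dt, th[0], th[1], th[2], th[3], th[4], g);
    for (int p = 0; p < NP; ++p) w.dirf(l, p) = g[p];
  }
  const int l0 = std::min<int>(n, std::max(0, (int)std::floor(th[1] / dt)));
  for (int p = 0; p < NP; ++p) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int l = l0; l <= i; ++l) acc += aif[i - l] * w.dirf(l, p);
      w.J(i, p) = dt * acc;
    }
  }
}

// Cholesky solve of the 5x5 system A x = b; returns false if not SPD.
inline bool chol_solve5(double A[NP][NP], const double* b, double* x) {
  double L[NP][NP] = {};
  for (int i = 0; i < NP; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i][j];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i][i] = std::sqrt(s);
      } else {
        L[i][j] = s / L[j][j];
      }
    }
  }
  double y[NP];
  for (int i = 0; i < NP; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i][k] * y[k];
    y[i] = s / L[i][i];
  }
  for (int i = NP - 1; i >= 0; --i) {
    double s = y[i];
    for (int k = i + 1; k < NP; ++k) s -= L[k][i] * x[k];
    x[i] = s / L[i][i];
  }
  return true;
}

LMResult lm_fit(const arma::vec& tc, const arma::vec& aif, double dt,
                const double* init, const double* lo, const double* hi,
                double ftol, double xtol, int max_iter, Workspace& w) {
  LMResult res;
  double theta[NP];
  for (int p = 0; p < NP; ++p) theta[p] = init[p];
  clamp_to(theta, lo, hi);
  double sse = residual_only(theta, tc, aif, dt, w);
  w.r = w.r_try;
  jacobian(theta, aif, dt, w);
  double lambda = 1e-3;
  bool converged = false;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    double A[NP][NP], g[NP], dA[NP];
    for (int p = 0; p < NP; ++p) {
      g[p] = arma::dot(w.J.col(p), w.r);
      for (int q = 0; q <= p; ++q) {
        A[p][q] = A[q][p] = arma::dot(w.J.col(p), w.J.col(q));
      }
    }
    double dmax = 0.0;
    for (int p = 0; p < NP; ++p) dmax = std::max(dmax, A[p][p]);
    if (!(dmax > 0)) { converged = true; break; } // flat model (e.g. zero AIF)
    for (int p = 0; p < NP; ++p) {
      dA[p] = std::max(A[p][p], dmax * 1e-14);
    }
    bool accepted = false;
    double theta_new[NP], sse_new = sse;
    while (lambda < 1e12) {
      double Areg[NP][NP];
      for (int p = 0; p < NP; ++p) {
        for (int q = 0; q < NP; ++q) Areg[p][q] = A[p][q];
        Areg[p][p] += lambda * dA[p];
      }
      double delta[NP], negg[NP];
      for (int p = 0; p < NP; ++p) negg[p] = -g[p];
      if (chol_solve5(Areg, negg, delta)) {
        for (int p = 0; p < NP; ++p) theta_new[p] = theta[p] + delta[p];
        clamp_to(theta_new, lo, hi);
        sse_new = residual_only(theta_new, tc, aif, dt, w);
        if (sse_new <= sse) { accepted = true; break; }
      }
      lambda *= 4.0;
    }
    if (!accepted) { // no descent at any damping: treat as local minimum
      converged = true;
      break;
    }
    const double drop = sse - sse_new;
    double step2 = 0.0, scale2 = 0.0;
    for (int p = 0; p < NP; ++p) {
      const double d = theta_new[p] - theta[p];
      step2 += d * d;
      scale2 += theta[p] * theta[p];
    }
    for (int p = 0; p < NP; ++p) theta[p] = theta_new[p];
    sse = sse_new;
    w.r = w.r_try;
    lambda = std::max(lambda / 4.0, 1e-12);
    if (drop <= ftol * std::max(sse, 1e-25) ||
        std::sqrt(step2) <= xtol * (std::sqrt(scale2) + xtol)) {
      converged = true;
      ++iter;
      break;
    }
    jacobian(theta, aif, dt, w);
  }
  for (int p = 0; p < NP; ++p) res.theta[p] = theta[p];
  res.sse = sse;
  res.n_iter = iter;
  res.converged = converged;
  return res;
}

// The frame-sampled model is smooth only within integer cells of
// (c1, c2) = (ceil(t0), ceil(t0 + minTT)); plain descent cannot cross the
// SSE jumps at cell boundaries, and inside one cell t0 is identified only
// through s = t0 + minTT. The multigrid selection therefore finishes with
// a scan over candidate cells: c2 exhaustive within the minTT bounds, c1
// within one frame of the initialization grid, so the search stays local
// to the starts' bolus-arrival basins. Within a cell the model is linear
// in the plateau amplitude a = F/6000 and the tail amplitude b = a * E:
//   model = dt * (a * P(c1, c2) + b * T(s, k)),
// with P a prefix-sum difference of shifted AIF columns and T the AIF
// convolved with the exponential tail. Each cell is fitted by damped
// Gauss-Newton on (s, k) with (a, b) profiled out by a constrained
// closed-form solve; the winning cell is then polished by a cell-confined
// 5-parameter LM run.

// prefix sums of shifted AIF columns: S.col(m)[i] = sum_{j<m, j<=i} aif[i-j]
inline arma::mat build_colsum(const arma::vec& aif) {
  const int n = aif.n_elem;
  arma::mat S(n, n + 1, arma::fill::zeros);
  for (int m = 1; m <= n; ++m) {
    S.col(m) = S.col(m - 1);
    for (int i = m - 1; i < n; ++i) S(i, m) += aif[i - (m - 1)];
  }
  return S;
}

struct CellFit {
  double a = 0.0, b = 0.0, s = 0.0, k = 0.0;
  double sse = arma::datum::inf;
  bool ok = false;
};

// constrained LS for (a, b) in model dt*(a*P + b*T) given dot products;
// box a in [a_lo, a_hi], ratio b/a in [e_lo, e_hi]
inline double solve_ab(double PP, double PT, double TT, double Py, double Ty,
                       double yy, double dt, double a_lo, double a_hi,
                       double e_lo, double e_hi, double& a_out,
                       double& b_out) {
  const double dt2 = dt * dt;
  auto sse_of = [&](double a, double b) {
    return dt2 * (a * a * PP + 2 * a * b * PT + b * b * TT) -
           2 * dt * (a * Py + b * Ty) + yy;
  };
  double best_a = a_lo, best_b = a_lo * e_lo, best = sse_of(best_a, best_b);
  auto consider = [&](double a, double b) {
    a = std::min(std::max(a, a_lo), a_hi);
    b = std::min(std::max(b, a * e_lo), a * e_hi);
    const double v = sse_of(a, b);
    if (v < best) { best = v; best_a = a; best_b = b; }
  };
  const double det = PP * TT - PT * PT;
  if (det > 1e-300) {
    consider((Py * TT - Ty * PT) / det / dt, (Ty * PP - Py * PT) / det / dt);
  }
  for (double a : {a_lo, a_hi}) { // a pinned, b free
    if (TT > 1e-300) consider(a, (Ty / dt - a * PT) / TT);
  }
  for (double e : {e_lo, e_hi}) { // ratio pinned, amplitude free
    const double den = PP + 2 * e * PT + e * e * TT;
    if (den > 1e-300) {
      const double a = (Py + e * Ty) / dt / den;
      consider(a, e * a);
    }
  }
  a_out = best_a;
  b_out = best_b;
  return best;
}

// tail convolution T and its k-derivative at (s, k)
inline void tail_conv(const arma::vec& aif, int c2, double s, double k,
                      double dt, arma::vec& T, arma::vec& dTdk) {
  const int n = aif.n_elem;
  T.zeros();
  dTdk.zeros();
  for (int j = c2; j < n; ++j) {
    const double u = j * dt - s;
    const double e = std::exp(-k * u);
    const double de = -u * e;
    for (int i = j; i < n; ++i) {
      T[i] += e * aif[i - j];
      dTdk[i] += de * aif[i - j];
    }
  }
}

// profiled Gauss-Newton fit of one (c1, c2) cell with t0 pinned
CellFit cell_fit(const arma::vec& y, const arma::vec& aif,
                 const arma::mat& S, int c1, int c2, double t0_seed,
                 double dt, const double* lo, const double* hi,
                 double k_init) {
  const int n = y.n_elem;
  CellFit out;
  const double s_lo = std::max((c2 - 1) * dt + 1e-9, t0_seed + lo[2]);
  const double s_hi = std::min(c2 * dt, t0_seed + hi[2]);
  if (s_lo > s_hi || c2 < c1 + 1) return out;
  const double a_lo = lo[0] / 6000.0, a_hi = hi[0] / 6000.0;
  const double e_lo = lo[3], e_hi = hi[3];
  arma::vec P = S.col(std::min(c2, n)) - S.col(std::min(c1, n));
  const double PP = arma::dot(P, P);
  const double Py = arma::dot(P, y);
  const double yy = arma::dot(y, y);
  double s = 0.5 * (s_lo + s_hi);
  double k = std::min(std::max(k_init, lo[4]), hi[4]);
  double a, b;

  if (c2 >= n || PP <= 1e-300) {
    // tail beyond the window (or empty plateau): amplitude-only fit
    if (PP <= 1e-300) return out;
    a = std::min(std::max(Py / (dt * PP), a_lo), a_hi);
    out.a = a; out.b = a * e_lo; out.s = s; out.k = k;
    out.sse = dt * dt * a * a * PP - 2 * dt * a * Py + yy;
    out.ok = true;
    return out;
  }

  arma::vec T(n), dTdk(n), T2(n), dTdk2(n);
  tail_conv(aif, c2, s, k, dt, T, dTdk);
  double sse = solve_ab(PP, arma::dot(P, T), arma::dot(T, T), Py,
                        arma::dot(T, y), yy, dt, a_lo, a_hi, e_lo, e_hi,
                        a, b);
  double lambda = 1e-3;
  for (int it = 0; it < 30; ++it) {
    // residual and Jacobian of (s, k) at the profiled (a, b)
    arma::vec r = dt * (a * P + b * T) - y;
    arma::vec Js = (dt * b * k) * T;
    arma::vec Jk = (dt * b) * dTdk;
    const double A11 = arma::dot(Js, Js), A12 = arma::dot(Js, Jk),
                 A22 = arma::dot(Jk, Jk), g1 = arma::dot(Js, r),
                 g2 = arma::dot(Jk, r);
    if (A11 + A22 <= 1e-300) break;
    bool accepted = false;
    double s_new = s, k_new = k, a_new = a, b_new = b, sse_new = sse;
    while (lambda < 1e10) {
      const double d11 = A11 + lambda * std::max(A11, 1e-14 * (A11 + A22));
      const double d22 = A22 + lambda * std::max(A22, 1e-14 * (A11 + A22));
      const double det = d11 * d22 - A12 * A12;
      if (std::abs(det) > 1e-300) {
        const double ds = (-g1 * d22 + g2 * A12) / det;
        const double dk = (-g2 * d11 + g1 * A12) / det;
        s_new = std::min(std::max(s + ds, s_lo), s_hi);
        k_new = std::min(std::max(k + dk, lo[4]), hi[4]);
        tail_conv(aif, c2, s_new, k_new, dt, T2, dTdk2);
        sse_new = solve_ab(PP, arma::dot(P, T2), arma::dot(T2, T2), Py,
                           arma::dot(T2, y), yy, dt, a_lo, a_hi, e_lo,
                           e_hi, a_new, b_new);
        if (sse_new <= sse) { accepted = true; break; }
      }
      lambda *= 4.0;
    }
    if (!accepted) break;
    const double drop = sse - sse_new;
    s = s_new; k = k_new; a = a_new; b = b_new; sse = sse_new;
    T = T2; dTdk = dTdk2;
    lambda = std::max(lambda / 4.0, 1e-12);
    if (drop <= 1e-12 * std::max(sse, 1e-25)) break;
  }
  out.a = a; out.b = b; out.s = s; out.k = k; out.sse = sse; out.ok = true;
  return out;
}

LMResult cell_scan(const LMResult& from, int c1_from, int c1_to,
                   const arma::vec& y, const arma::vec& aif,
                   const arma::mat& S, double dt, const double* lo,
                   const double* hi, double ftol, double xtol, int max_iter,
                   Workspace& w) {
  const int n = y.n_elem;
  LMResult best = from;
  const int c1_lo = std::max(c1_from, (int)std::ceil(lo[1] / dt));
  const int c1_hi = std::min(c1_to, (int)std::floor(hi[1] / dt) + 1);
  CellFit bestcell;
  int bc1 = 0, bc2 = 0;
  double bt0 = 0.0;
  for (int c1 = c1_lo; c1 <= c1_hi; ++c1) {
    double t0_seed = (c1 - 0.5) * dt;
    if (t0_seed < lo[1]) t0_seed = lo[1];
    if (t0_seed > hi[1]) t0_seed = hi[1];
    const int c2_lo = c1 + std::max(1, (int)std::ceil(lo[2] / dt));
    const int c2_hi = std::min(c1 + (int)std::floor(hi[2] / dt), n);
    for (int c2 = c2_lo; c2 <= c2_hi; ++c2) {
      CellFit cf = cell_fit(y, aif, S, c1, c2, t0_seed, dt, lo, hi,
                            from.theta[4]);
      if (cf.ok && cf.sse < bestcell.sse) {
        bestcell = cf;
        bc1 = c1; bc2 = c2; bt0 = t0_seed;
      }
    }
  }
  if (bestcell.ok && bestcell.sse < best.sse * (1.0 - 1e-12)) {
    // confined 5-parameter polish inside the winning cell
    const double mlo = std::max(lo[2], (bc2 - 1) * dt - bt0 + 1e-9);
    const double mhi = std::min(hi[2], std::max(mlo, bc2 * dt - bt0));
    double lo2[NP] = {lo[0], bt0, mlo, lo[3], lo[4]};
    double hi2[NP] = {hi[0], bt0, mhi, hi[3], hi[4]};
    double cand[NP] = {bestcell.a * 6000.0, bt0, bestcell.s - bt0,
                       bestcell.b / std::max(bestcell.a, 1e-300),
                       bestcell.k};
    clamp_to(cand, lo2, hi2);
    LMResult r = lm_fit(y, aif, dt, cand, lo2, hi2, ftol, xtol, max_iter, w);
    if (r.sse > bestcell.sse) {
      // keep the profiled solution if polishing could not improve it
      for (int p = 0; p < NP; ++p) r.theta[p] = cand[p];
      r.sse = bestcell.sse;
      r.converged = true;
    }
    if (r.sse < best.sse) best = r;
  }
  return best;
}

} // namespace

// Fit every voxel (row of `tc`) from every initialization (row of
// `inits`), keeping the lowest-SSE run; ties break toward the earlier
// initialization. With `cell_scan` enabled, the best run of each distinct
// bolus-arrival (t0) basin is finished with the local cell scan.
// [[Rcpp::export]]
List fit_voxels_cpp(const arma::mat& tc, const arma::vec& aif, double dt,
                    const arma::mat& inits, const arma::vec& lower,
                    const arma::vec& upper, double ftol, double xtol,
                    int max_iter, bool cell_scan_on, bool keep_start_sse) {
  const int nv = tc.n_rows;
  const int ns = inits.n_rows;
  const int n = aif.n_elem;
  arma::mat params(nv, NP);
  arma::vec rss(nv);
  IntegerVector init_index(nv), n_iter(nv);
  LogicalVector converged(nv);
  arma::mat start_sse;
  if (keep_start_sse) start_sse.set_size(nv, ns);
  Workspace w(n);
  double lo[NP], hi[NP], init[NP];
  for (int p = 0; p < NP; ++p) { lo[p] = lower[p]; hi[p] = upper[p]; }

  // bolus-arrival cell range spanned by the initialization grid
  int c1_min = INT_MAX, c1_max = INT_MIN;
  for (int s = 0; s < ns; ++s) {
    const int c1 = (int)std::ceil(inits(s, 1) / dt - 1e-12);
    c1_min = std::min(c1_min, c1);
    c1_max = std::max(c1_max, c1);
  }

  const arma::mat colsum = cell_scan_on ? build_colsum(aif) : arma::mat();
  std::vector<LMResult> runs(ns);
  for (int v = 0; v < nv; ++v) {
    arma::vec y = tc.row(v).t();
    for (int s = 0; s < ns; ++s) {
      for (int p = 0; p < NP; ++p) init[p] = inits(s, p);
      runs[s] = lm_fit(y, aif, dt, init, lo, hi, ftol, xtol, max_iter, w);
    }
    if (cell_scan_on) {
      // one scan over the union of the starts' bolus-arrival basins
      // (each extended by one frame), seeded from the best run so far
      int bs = 0;
      for (int s = 1; s < ns; ++s) {
        if (runs[s].sse < runs[bs].sse) bs = s;
      }
      LMResult r = cell_scan(runs[bs], c1_min - 1, c1_max + 1, y, aif,
                             colsum, dt, lo, hi, ftol, xtol, max_iter, w);
      if (r.sse < runs[bs].sse) runs[bs] = r;
    }
    LMResult best;
    int best_s = -1;
    for (int s = 0; s < ns; ++s) {
      if (keep_start_sse) start_sse(v, s) = runs[s].sse;
      if (best_s < 0 || runs[s].sse < best.sse) { best = runs[s]; best_s = s; }
    }
    for (int p = 0; p < NP; ++p) params(v, p) = best.theta[p];
    rss[v] = best.sse;
    init_index[v] = best_s + 1;
    n_iter[v] = best.n_iter;
    converged[v] = best.converged;
    if (v % 256 == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(
      _["params"] = params, _["rss"] = rss, _["init_index"] = init_index,
      _["n_iter"] = n_iter, _["converged"] = converged);
  if (keep_start_sse) out["start_sse"] = start_sse;
  return out;
}
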