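#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;
typedef std::complex<double> cplx;

// The voxel SAR for drive s .* e^{i phi} is Re(u^H A u) with u_l = e^{i phi_l}
// and A_lm = s_l Q_lm s_m. The coordinate update phi_l = atan2(Y_l, X_l) is,
// in complex form, u_l <- Z_l / |Z_l| with Z_l = sum_{m != l} A_lm u_m: the
// exact maximizer of the SAR along coordinate l (X_l = Re Z_l, Y_l = Im Z_l).

static double sar_u(const std::vector<cplx>& A, const std::vector<cplx>& u,
                    int nc) {
  double v = 0.0;
  for (int l = 0; l < nc; ++l) {
    v += A[l * nc + l].real();
    for (int m = l + 1; m < nc; ++m)
      v += 2.0 * (std::conj(u[l]) * A[l * nc + m] * u[m]).real();
  }
  return v;
}

static void tm_sweep(const std::vector<cplx>& A, std::vector<cplx>& u, int nc,
                     bool gauss_seidel) {
  std::vector<cplx> src;
  const std::vector<cplx>* ref = &u;
  if (!gauss_seidel) { src = u; ref = &src; }
  for (int l = 0; l < nc; ++l) {
    cplx z(0.0, 0.0);
    for (int m = 0; m < nc; ++m) {
      if (m == l) continue;
      z += A[l * nc + m] * (*ref)[m];
    }
    double a = std::abs(z);
    if (a > 0.0) u[l] = z / a; // |Z_l| = 0: decoupled channel, keep phase
  }
}

struct TmResult {
  std::vector<double> phases;
  double max_sar;
  int iterations;
  bool converged;
  std::vector<double> history;
};

static TmResult tm_core(const std::vector<cplx>& A, std::vector<double> phi,
                        int nc, double eps, double eps_rel, int max_iter,
                        bool gauss_seidel, bool keep_history) {
  std::vector<cplx> u(nc);
  for (int l = 0; l < nc; ++l) u[l] = std::polar(1.0, phi[l]);
  TmResult r;
  double sar_prev = sar_u(A, u, nc);
  if (keep_history) r.history.push_back(sar_prev);
  const double sar_init = sar_prev;
  r.converged = false;
  int k = 0;
  while (k < max_iter) {
    tm_sweep(A, u, nc, gauss_seidel);
    ++k;
    double s = sar_u(A, u, nc);
    if (keep_history) r.history.push_back(s);
    double d = std::fabs(s - sar_prev);
    double scale = std::max(std::fabs(s), 1e-300);
    sar_prev = s;
    if (k >= 2 && d <= eps && d / scale <= std::max(eps_rel, 0.0)) {
      r.converged = true;
      break;
    }
  }
  // each update is an exact coordinate maximizer; guard rounding anyway
  r.max_sar = std::max(sar_prev, sar_init);
  r.iterations = k;
  r.phases.resize(nc);
  for (int l = 0; l < nc; ++l) r.phases[l] = std::arg(u[l]);
  return r;
}

static void fill_A(const Rcomplex* qv, const double* s, int nc,
                   std::vector<cplx>& A) {
  for (int l = 0; l < nc; ++l)
    for (int m = 0; m < nc; ++m) {
      const Rcomplex& z = qv[l + nc * m];
      A[l * nc + m] = s[l] * s[m] * cplx(z.r, z.i);
    }
}

// [[Rcpp::export]]
List tm_fixed_point_cpp(ComplexMatrix q, NumericVector amplitudes,
                        NumericVector phases0, double eps, double eps_rel,
                        int max_iter, bool gauss_seidel) {
  int nc = q.nrow();
  std::vector<cplx> A(nc * nc);
  fill_A(q.begin(), amplitudes.begin(), nc, A);
  std::vector<double> phi(phases0.begin(), phases0.end());
  TmResult r = tm_core(A, phi, nc, eps, eps_rel, max_iter, gauss_seidel, true);
  return List::create(
      _["phases"] = NumericVector(r.phases.begin(), r.phases.end()),
      _["max_sar"] = r.max_sar, _["iterations"] = r.iterations,
      _["converged"] = r.converged,
      _["sar_history"] = NumericVector(r.history.begin(), r.history.end()));
}

// worst-case SAR per (amplitude set, matrix): S is n_sets x nc,
// qarr is [nc, nc, nv], starts is [nc, n_starts, nv] (per-matrix starting
// phase sets; the fixed point is run from each and the best kept);
// returns n_sets x nv
// [[Rcpp::export]]
NumericMatrix tm_batch_cpp(ComplexVector qarr, NumericMatrix S,
                           NumericVector starts, double eps, double eps_rel,
                           int max_iter, bool gauss_seidel) {
  IntegerVector dims = qarr.attr("dim");
  int nc = dims[0], nv = dims[2];
  IntegerVector sdims = starts.attr("dim");
  int nstart = sdims[1];
  int ns = S.nrow();
  NumericMatrix out(ns, nv);
  std::vector<cplx> A(nc * nc);
  std::vector<double> s(nc), phi(nc);
  const Rcomplex* base = qarr.begin();
  const double* st = starts.begin();
  for (int v = 0; v < nv; ++v) {
    const Rcomplex* qv = base + (R_xlen_t)v * nc * nc;
    const double* stv = st + (R_xlen_t)v * nc * nstart;
    for (int i = 0; i < ns; ++i) {
      for (int c = 0; c < nc; ++c) s[c] = S(i, c);
      fill_A(qv, s.data(), nc, A);
      double best = -std::numeric_limits<double>::infinity();
      for (int j = 0; j < nstart; ++j) {
        for (int c = 0; c < nc; ++c) phi[c] = stv[c + nc * j];
        TmResult r = tm_core(A, phi, nc, eps, eps_rel, max_iter, gauss_seidel,
                             false);
        if (r.max_sar > best) best = r.max_sar;
      }
      out(i, v) = best;
    }
    if (v % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Peak worst-case SAR over matrices per amplitude set, with upper-bound
// pruning: the magnitude sum sum_nm s_n |Q_nm| s_m bounds the worst case of
// each matrix from above, so matrices are visited in descending-bound order
// and the scan stops when no remaining bound can beat the best fixed-point
// value. Returns a vector of length n_sets.
// [[Rcpp::export]]
NumericVector tm_peak_cpp(ComplexVector qarr, NumericMatrix S,
                          NumericVector starts, double eps, double eps_rel,
                          int max_iter, bool gauss_seidel) {
  IntegerVector dims = qarr.attr("dim");
  int nc = dims[0], nv = dims[2];
  IntegerVector sdims = starts.attr("dim");
  int nstart = sdims[1];
  int ns = S.nrow();
  NumericVector out(ns);
  const Rcomplex* base = qarr.begin();
  const double* st = starts.begin();
  std::vector<double> absq((R_xlen_t)nv * nc * nc);
  for (R_xlen_t j = 0; j < (R_xlen_t)nv * nc * nc; ++j)
    absq[j] = std::hypot(base[j].r, base[j].i);
  std::vector<cplx> A(nc * nc);
  std::vector<double> s(nc), phi(nc), ub(nv);
  std::vector<int> ord(nv);
  for (int i = 0; i < ns; ++i) {
    for (int c = 0; c < nc; ++c) s[c] = S(i, c);
    for (int v = 0; v < nv; ++v) {
      const double* aq = absq.data() + (R_xlen_t)v * nc * nc;
      double u = 0.0;
      for (int a = 0; a < nc; ++a) {
        u += s[a] * s[a] * aq[a + nc * a];
        for (int b = a + 1; b < nc; ++b)
          u += 2.0 * s[a] * s[b] * aq[a + nc * b];
      }
      ub[v] = u;
      ord[v] = v;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return ub[a] > ub[b]; });
    double best = -std::numeric_limits<double>::infinity();
    for (int r = 0; r < nv; ++r) {
      int v = ord[r];
      if (ub[v] <= best) break;
      const Rcomplex* qv = base + (R_xlen_t)v * nc * nc;
      const double* stv = st + (R_xlen_t)v * nc * nstart;
      fill_A(qv, s.data(), nc, A);
      for (int j = 0; j < nstart; ++j) {
        for (int c = 0; c < nc; ++c) phi[c] = stv[c + nc * j];
        TmResult tr = tm_core(A, phi, nc, eps, eps_rel, max_iter,
                              gauss_seidel, false);
        if (tr.max_sar > best) best = tr.max_sar;
      }
    }
    out[i] = best;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Re(w^H Q w) for every drive row w (complex) and matrix; returns n x nv
// [[Rcpp::export]]
NumericMatrix sar_many_cpp(ComplexVector qarr, ComplexMatrix W) {
  IntegerVector dims = qarr.attr("dim");
  int nc = dims[0], nv = dims[2];
  int n = W.nrow();
  NumericMatrix out(n, nv);
  std::vector<cplx> w(nc);
  const Rcomplex* base = qarr.begin();
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < nc; ++c) w[c] = cplx(W(i, c).r, W(i, c).i);
    for (int v = 0; v < nv; ++v) {
      const Rcomplex* qv = base + (R_xlen_t)v * nc * nc;
      double val = 0.0;
      for (int a = 0; a < nc; ++a) {
        val += qv[a + nc * a].r * std::norm(w[a]);
        for (int b = a + 1; b < nc; ++b) {
          cplx qab(qv[a + nc * b].r, qv[a + nc * b].i);
          val += 2.0 * (std::conj(w[a]) * qab * w[b]).real();
        }
      }
      out(i, v) = val;
    }
  }
  return out;
}

// Exhaustive phase-grid maximization with the global phase fixed (phi_1 = 0).
// Remaining phases range over the G-point grid 2*pi*i/G. Pair (n, m)
// contributes 2 a_nm cos(t_nm + phi_m - phi_n), a lookup in a length-2G
// doubled table indexed by i_m - i_n + G (branch-free). Supports nc in 2..5.
// [[Rcpp::export]]
List grid_oracle_cpp(ComplexMatrix q, NumericVector amplitudes, int G) {
  int nc = q.nrow();
  if (nc < 2 || nc > 5) stop("grid oracle supports 2 to 5 channels");
  if (G < 2) stop("grid_points must be at least 2");
  double base = 0.0;
  for (int n = 0; n < nc; ++n)
    base += amplitudes[n] * amplitudes[n] * q(n, n).r;
  // doubled tables: tab[p][d + G] = 2 a_nm cos(t_nm + 2 pi d / G), d in (-G, G)
  int npair = nc * (nc - 1) / 2;
  std::vector<std::vector<double> > T(npair, std::vector<double>(2 * G));
  std::vector<int> pidx(nc * nc, -1);
  int p = 0;
  for (int n = 0; n < nc; ++n)
    for (int m = n + 1; m < nc; ++m, ++p) {
      cplx z(q(n, m).r, q(n, m).i);
      double a = 2.0 * amplitudes[n] * std::abs(z) * amplitudes[m];
      double t = std::arg(z);
      for (int d = -G; d < G; ++d)
        T[p][d + G] = a * std::cos(t + 2.0 * M_PI * d / G);
      pidx[n * nc + m] = p;
    }
  auto tb = [&](int n, int m) -> const double* {
    return T[pidx[n * nc + m]].data();
  };
  double best = -std::numeric_limits<double>::infinity();
  int bi[5] = {0, 0, 0, 0, 0};
  if (nc == 2) {
    const double* t01 = tb(0, 1) + G;
    for (int i1 = 0; i1 < G; ++i1)
      if (t01[i1] > best) { best = t01[i1]; bi[1] = i1; }
  } else if (nc == 3) {
    const double* t01 = tb(0, 1) + G;
    const double* t02 = tb(0, 2) + G;
    for (int i1 = 0; i1 < G; ++i1) {
      double p1 = t01[i1];
      const double* t12 = tb(1, 2) + G - i1;
      for (int i2 = 0; i2 < G; ++i2) {
        double v = p1 + t02[i2] + t12[i2];
        if (v > best) { best = v; bi[1] = i1; bi[2] = i2; }
      }
    }
  } else if (nc == 4) {
    const double* t01 = tb(0, 1) + G;
    const double* t02 = tb(0, 2) + G;
    const double* t03 = tb(0, 3) + G;
    for (int i1 = 0; i1 < G; ++i1) {
      double p1 = t01[i1];
      const double* t12 = tb(1, 2) + G - i1;
      const double* t13 = tb(1, 3) + G - i1;
      for (int i2 = 0; i2 < G; ++i2) {
        double p2 = p1 + t02[i2] + t12[i2];
        const double* t23 = tb(2, 3) + G - i2;
        for (int i3 = 0; i3 < G; ++i3) {
          double v = p2 + t03[i3] + t13[i3] + t23[i3];
          if (v > best) { best = v; bi[1] = i1; bi[2] = i2; bi[3] = i3; }
        }
      }
      Rcpp::checkUserInterrupt();
    }
  } else { // nc == 5
    const double* t01 = tb(0, 1) + G;
    const double* t02 = tb(0, 2) + G;
    const double* t03 = tb(0, 3) + G;
    const double* t04 = tb(0, 4) + G;
    for (int i1 = 0; i1 < G; ++i1) {
      double p1 = t01[i1];
      const double* t12 = tb(1, 2) + G - i1;
      const double* t13 = tb(1, 3) + G - i1;
      const double* t14 = tb(1, 4) + G - i1;
      for (int i2 = 0; i2 < G; ++i2) {
        double p2 = p1 + t02[i2] + t12[i2];
        const double* t23 = tb(2, 3) + G - i2;
        const double* t24 = tb(2, 4) + G - i2;
        for (int i3 = 0; i3 < G; ++i3) {
          double p3 = p2 + t03[i3] + t13[i3] + t23[i3];
          const double* t34 = tb(3, 4) + G - i3;
          for (int i4 = 0; i4 < G; ++i4) {
            double v = p3 + t04[i4] + t14[i4] + t24[i4] + t34[i4];
            if (v > best) {
              best = v; bi[1] = i1; bi[2] = i2; bi[3] = i3; bi[4] = i4;
            }
          }
        }
        Rcpp::checkUserInterrupt();
      }
    }
  }
  NumericVector phases(nc);
  for (int c = 1; c < nc; ++c) phases[c] = 2.0 * M_PI * bi[c] / G;
  return List::create(_["max_sar"] = base + best, _["phases"] = phases);
}
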