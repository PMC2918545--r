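#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bivariate LOESS engine: nearest-neighbour spans, tricube kernel weights,
// weighted local-linear fits.  The neighbourhood structure of a fixed
// evaluation set depends only on the coordinates and the span, so it is
// precomputed once and reused across local-scoring iterations and
// permutation refits.
//
// Local design matrices are centred at the evaluation point and scaled by
// the bandwidth (the q-th nearest distance), so the prediction is simply the
// local intercept and all conditioning thresholds are scale-free.

// [[Rcpp::export]]
List loess2d_precompute(const NumericMatrix& data_xy,
                        const NumericMatrix& eval_xy,
                        const int q,
                        const IntegerVector& self_idx) {
  const int n = data_xy.nrow(), m = eval_xy.nrow();
  if (q < 3 || q > n)
    stop("neighbourhood size q must satisfy 3 <= q <= n");
  if (self_idx.size() != m)
    stop("self_idx must have one entry per evaluation point");

  std::vector<int> idx;
  std::vector<double> kw, dx, dy;
  idx.reserve((size_t)m * q);
  kw.reserve((size_t)m * q);
  dx.reserve((size_t)m * q);
  dy.reserve((size_t)m * q);
  IntegerVector off(m + 1);
  IntegerVector selfpos(m, -1);

  std::vector<double> d2(n), tmp(n);
  for (int t = 0; t < m; ++t) {
    const double tx = eval_xy(t, 0), ty = eval_xy(t, 1);
    for (int j = 0; j < n; ++j) {
      const double ax = data_xy(j, 0) - tx, ay = data_xy(j, 1) - ty;
      d2[j] = ax * ax + ay * ay;
    }
    tmp = d2;
    std::nth_element(tmp.begin(), tmp.begin() + (q - 1), tmp.end());
    const double dq2 = tmp[q - 1];
    const double dq = std::sqrt(dq2);
    const double inv_dq = dq > 0.0 ? 1.0 / dq : 1.0;
    off[t + 1] = off[t];
    for (int j = 0; j < n; ++j) {
      // ties at the boundary distance are all included; the tricube gives
      // them weight zero unless the whole neighbourhood is coincident
      if (d2[j] <= dq2) {
        double w;
        if (dq > 0.0) {
          const double r = std::sqrt(d2[j]) * inv_dq;
          const double u = 1.0 - r * r * r;
          w = u > 0.0 ? u * u * u : 0.0;
        } else {
          w = 1.0;  // all q nearest points coincide with t
        }
        if (self_idx[t] == j) selfpos[t] = (int)idx.size();
        idx.push_back(j);
        kw.push_back(w);
        dx.push_back((data_xy(j, 0) - tx) * inv_dq);
        dy.push_back((data_xy(j, 1) - ty) * inv_dq);
        ++off[t + 1];
      }
    }
  }

  return List::create(
      _["off"] = off, _["idx"] = wrap(idx), _["kw"] = wrap(kw),
      _["dx"] = wrap(dx), _["dy"] = wrap(dy), _["selfpos"] = selfpos,
      _["n_data"] = n, _["n_eval"] = m, _["q"] = q);
}

// Solve the 3x3 weighted normal equations accumulated in a[], b[]; returns
// the first row of the inverse in inv0[] and the local intercept (the
// prediction).  Falls back to a tiny ridge on the diagonal when the local
// design is singular (collinear neighbourhood), and to the weighted mean
// when even that fails.
static inline double solve_local(double a00, double a01, double a02,
                                 double a11, double a12, double a22,
                                 double b0, double b1, double b2,
                                 double inv0[3], bool& used_ridge) {
  used_ridge = false;
  for (int attempt = 0; attempt < 2; ++attempt) {
    const double c00 = a11 * a22 - a12 * a12;
    const double c01 = a02 * a12 - a01 * a22;
    const double c02 = a01 * a12 - a02 * a11;
    const double det = a00 * c00 + a01 * c01 + a02 * c02;
    // scale-free threshold: dx, dy are O(1) after bandwidth scaling
    const double scale = a00 > 0.0 ? a00 : 1.0;
    if (std::fabs(det) > 1e-10 * scale * scale * scale) {
      inv0[0] = c00 / det;
      inv0[1] = c01 / det;
      inv0[2] = c02 / det;
      return inv0[0] * b0 + inv0[1] * b1 + inv0[2] * b2;
    }
    // ridge fallback, documented tiny regulariser
    const double lam = 1e-8 * scale;
    a00 += lam; a11 += lam; a22 += lam;
    used_ridge = true;
  }
  // degenerate: all kernel x prior weights zero or ridge still singular
  inv0[0] = a00 > 0.0 ? 1.0 / a00 : 0.0;
  inv0[1] = inv0[2] = 0.0;
  return a00 > 0.0 ? b0 / a00 : NA_REAL;
}

// [[Rcpp::export]]
List loess2d_apply(const List& pre, const NumericVector& z,
                   const NumericVector& wprior, const bool want_diag) {
  const IntegerVector off = pre["off"], idx = pre["idx"], selfpos = pre["selfpos"];
  const NumericVector kw = pre["kw"], dx = pre["dx"], dy = pre["dy"];
  const int n = pre["n_data"], m = pre["n_eval"];
  if (z.size() != n || wprior.size() != n)
    stop("response/weights length must match the data the neighbourhoods were built on");

  NumericVector fitted(m);
  NumericVector diag(want_diag ? m : 0);
  int n_ridge = 0;
  for (int t = 0; t < m; ++t) {
    double a00 = 0, a01 = 0, a02 = 0, a11 = 0, a12 = 0, a22 = 0;
    double b0 = 0, b1 = 0, b2 = 0;
    double zsum = 0;
    int cnt = 0;
    for (int k = off[t]; k < off[t + 1]; ++k) {
      const int j = idx[k];
      const double w = kw[k] * wprior[j];
      zsum += z[j];
      ++cnt;
      if (w <= 0.0) continue;
      const double x1 = dx[k], x2 = dy[k], zz = z[j];
      a00 += w;
      a01 += w * x1;
      a02 += w * x2;
      a11 += w * x1 * x1;
      a12 += w * x1 * x2;
      a22 += w * x2 * x2;
      b0 += w * zz;
      b1 += w * x1 * zz;
      b2 += w * x2 * zz;
    }
    double inv0[3];
    bool ridge = false;
    double pred = solve_local(a00, a01, a02, a11, a12, a22, b0, b1, b2,
                              inv0, ridge);
    if (ridge) ++n_ridge;
    if (!R_finite(pred)) pred = cnt > 0 ? zsum / cnt : NA_REAL;
    fitted[t] = pred;
    if (want_diag) {
      const int sp = selfpos[t];
      if (sp >= 0) {
        const double wself = kw[sp] * wprior[idx[sp]];
        diag[t] = inv0[0] * wself;
      } else {
        diag[t] = NA_REAL;
      }
    }
  }
  if (want_diag)
    return List::create(_["fitted"] = fitted, _["diag"] = diag,
                        _["n_ridge"] = n_ridge);
  return List::create(_["fitted"] = fitted, _["n_ridge"] = n_ridge);
}

// Dense rows of the linear smoother operator (prediction = L %*% z for the
// given prior weights).  Intended for small problems and verification.
// [[Rcpp::export]]
NumericMatrix loess2d_rows(const List& pre, const NumericVector& wprior) {
  const IntegerVector off = pre["off"], idx = pre["idx"];
  const NumericVector kw = pre["kw"], dx = pre["dx"], dy = pre["dy"];
  const int n = pre["n_data"], m = pre["n_eval"];
  if (wprior.size() != n) stop("weights length must match data");

  NumericMatrix L(m, n);
  for (int t = 0; t < m; ++t) {
    double a00 = 0, a01 = 0, a02 = 0, a11 = 0, a12 = 0, a22 = 0;
    int cnt = 0;
    double wtot = 0;
    for (int k = off[t]; k < off[t + 1]; ++k) {
      const double w = kw[k] * wprior[idx[k]];
      ++cnt;
      wtot += w;
      if (w <= 0.0) continue;
      const double x1 = dx[k], x2 = dy[k];
      a00 += w;
      a01 += w * x1;
      a02 += w * x2;
      a11 += w * x1 * x1;
      a12 += w * x1 * x2;
      a22 += w * x2 * x2;
    }
    double inv0[3];
    bool ridge = false;
    const double chk = solve_local(a00, a01, a02, a11, a12, a22, 0, 0, 0,
                                   inv0, ridge);
    (void)chk;
    if (inv0[0] == 0.0 && wtot <= 0.0) {
      // degenerate neighbourhood: operator row is the plain average
      for (int k = off[t]; k < off[t + 1]; ++k) L(t, idx[k]) += 1.0 / cnt;
      continue;
    }
    for (int k = off[t]; k < off[t + 1]; ++k) {
      const double w = kw[k] * wprior[idx[k]];
      if (w <= 0.0) continue;
      L(t, idx[k]) += w * (inv0[0] + inv0[1] * dx[k] + inv0[2] * dy[k]);
    }
  }
  return L;
}

// Multi-response apply: fits B responses/weight columns in lockstep so the
// neighbourhood stream is traversed once per scoring iteration for the
// whole permutation batch.  Zt and Wt are B x n (response index fastest).
// [[Rcpp::export]]
List loess2d_apply_multi(const List& pre, const NumericMatrix& Zt,
                         const NumericMatrix& Wt) {
  const IntegerVector off = pre["off"], idx = pre["idx"];
  const NumericVector kw = pre["kw"], dx = pre["dx"], dy = pre["dy"];
  const int n = pre["n_data"], m = pre["n_eval"];
  const int B = Zt.nrow();
  if (Zt.ncol() != n || Wt.ncol() != n || Wt.nrow() != B)
    stop("Zt/Wt must be B x n for the data the neighbourhoods were built on");

  NumericMatrix fitted(m, B);
  const double* ztp = &Zt(0, 0);
  const double* wtp = &Wt(0, 0);
  std::vector<double> acc((size_t)9 * B);
  for (int t = 0; t < m; ++t) {
    std::fill(acc.begin(), acc.end(), 0.0);
    double* a00 = &acc[0];
    double* a01 = a00 + B; double* a02 = a01 + B;
    double* a11 = a02 + B; double* a12 = a11 + B;
    double* a22 = a12 + B; double* b0 = a22 + B;
    double* b1 = b0 + B;   double* b2 = b1 + B;
    for (int k = off[t]; k < off[t + 1]; ++k) {
      const int j = idx[k];
      const double kk = kw[k];
      if (kk <= 0.0) continue;
      const double x1 = dx[k], x2 = dy[k];
      const double x11 = x1 * x1, x12 = x1 * x2, x22 = x2 * x2;
      const double* wj = wtp + (size_t)j * B;
      const double* zj = ztp + (size_t)j * B;
      for (int b = 0; b < B; ++b) {
        const double w = kk * wj[b];
        const double wz = w * zj[b];
        a00[b] += w;
        a01[b] += w * x1;
        a02[b] += w * x2;
        a11[b] += w * x11;
        a12[b] += w * x12;
        a22[b] += w * x22;
        b0[b] += wz;
        b1[b] += wz * x1;
        b2[b] += wz * x2;
      }
    }
    for (int b = 0; b < B; ++b) {
      double inv0[3];
      bool ridge = false;
      double predb = solve_local(a00[b], a01[b], a02[b], a11[b], a12[b],
                                 a22[b], b0[b], b1[b], b2[b], inv0, ridge);
      if (!R_finite(predb)) {
        // degenerate neighbourhood for this column: plain average
        double s = 0; int c = 0;
        for (int k = off[t]; k < off[t + 1]; ++k) {
          s += ztp[(size_t)idx[k] * B + b];
          ++c;
        }
        predb = c > 0 ? s / c : NA_REAL;
      }
      fitted(t, b) = predb;
    }
  }
  return List::create(_["fitted"] = fitted);
}
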