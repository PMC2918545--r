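#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Circular Bernoulli scan statistic.  Candidate zones are, for every
// subject taken as a centre, the nested sets of its 1..floor(N/2) nearest
// subjects (subjects at identical distance enter together, so zone sizes
// may skip).  The log-likelihood ratio uses the Bernoulli likelihood of
// cases inside vs outside the zone; x*log(x) values are tabulated so the
// Monte Carlo loop performs no log evaluations.

struct ZoneBest {
  double llr;
  int center;   // 0-based
  int size;
  int cases;
  int dir;      // +1 high, -1 low
};

static inline double zone_llr(const std::vector<double>& g, int c, int k,
                              int C, int N, double LCN) {
  // L(c,k) + L(C-c, N-k) - L(C,N), with L(c,n) = g[c] + g[n-c] - g[n]
  const double v = g[c] + g[k - c] - g[k] + g[C - c] + g[N - k - (C - c)] -
                   g[N - k] - LCN;
  return v > 0.0 ? v : 0.0;
}

// Scan one labelling; when `best` is non-null records the argmax with the
// deterministic tie-break (larger llr, then smaller zone, then smaller
// centre index).
static double scan_max(const std::vector<int>& ord,
                       const std::vector<char>& valid, int K,
                       const std::vector<double>& g, const IntegerVector& y,
                       int C, int N, bool dir_high, bool dir_low,
                       ZoneBest* best) {
  const double LCN = g[C] + g[N - C] - g[N];
  double mx = 0.0;
  for (int i = 0; i < N; ++i) {
    const int* o = &ord[(size_t)i * K];
    const char* v = &valid[(size_t)i * K];
    int c = 0;
    for (int k = 0; k < K; ++k) {
      c += y[o[k]];
      if (!v[k]) continue;
      const int nz = k + 1;
      // direction of the zone: compare c/nz with C/N in integers
      const long long lhs = (long long)c * N, rhs = (long long)C * nz;
      int dir;
      if (lhs > rhs) dir = 1;
      else if (lhs < rhs) dir = -1;
      else continue;  // llr is exactly 0
      if ((dir == 1 && !dir_high) || (dir == -1 && !dir_low)) continue;
      const double llr = zone_llr(g, c, nz, C, N, LCN);
      if (best) {
        if (llr > best->llr + 1e-9 ||
            (std::fabs(llr - best->llr) <= 1e-9 &&
             (nz < best->size ||
              (nz == best->size && i < best->center)))) {
          best->llr = llr;
          best->center = i;
          best->size = nz;
          best->cases = c;
          best->dir = dir;
        }
      }
      if (llr > mx) mx = llr;
    }
  }
  return mx;
}

// [[Rcpp::export]]
List scan_bernoulli_cpp(const NumericMatrix& xy, const IntegerVector& y,
                        const int n_mc, const bool dir_high,
                        const bool dir_low) {
  const int N = xy.nrow();
  if (y.size() != N) stop("outcome length must match coordinates");
  int C = 0;
  for (int i = 0; i < N; ++i) {
    if (y[i] != 0 && y[i] != 1) stop("outcomes must be 0/1");
    C += y[i];
  }
  if (C == 0 || C == N) stop("degenerate outcomes: need both cases and controls");
  if (!dir_high && !dir_low) stop("at least one scan direction is required");
  const int K = N / 2;
  if (K < 1) stop("need at least two subjects");

  // distance-ordered neighbour lists per centre, truncated to K entries,
  // with validity flags marking zone boundaries (strictly increasing next
  // distance keeps tied subjects together)
  std::vector<int> ord((size_t)N * K);
  std::vector<char> valid((size_t)N * K);
  std::vector<double> radius((size_t)N * K);
  {
    std::vector<std::pair<double, int> > d(N);
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j) {
        const double ax = xy(j, 0) - xy(i, 0), ay = xy(j, 1) - xy(i, 1);
        d[j] = std::make_pair(ax * ax + ay * ay, j);
      }
      std::sort(d.begin(), d.end());
      for (int k = 0; k < K; ++k) {
        ord[(size_t)i * K + k] = d[k].second;
        radius[(size_t)i * K + k] = std::sqrt(d[k].first);
        valid[(size_t)i * K + k] = (d[k].first < d[k + 1].first) ? 1 : 0;
      }
    }
  }

  std::vector<double> g(N + 1);
  g[0] = 0.0;
  for (int x = 1; x <= N; ++x) g[x] = (double)x * std::log((double)x);

  ZoneBest best;
  best.llr = 0.0; best.center = -1; best.size = 0; best.cases = 0; best.dir = 0;
  scan_max(ord, valid, K, g, y, C, N, dir_high, dir_low, &best);

  int n_ge = 0;
  if (n_mc > 0) {
    // Monte Carlo replicates only need "max llr >= observed", so convert
    // the observed llr into per-zone-size case-count thresholds (llr is
    // convex in the case count around the null proportion) and early-exit
    // each replicate at the first zone crossing a threshold.  Decisions
    // are identical to full evaluation.
    const double LCN = g[C] + g[N - C] - g[N];
    const double cut = best.llr - 1e-9;
    std::vector<int> c_hi(K + 1), c_lo(K + 1);
    for (int k = 1; k <= K; ++k) {
      // high side: smallest c with llr >= cut and c/k > C/N
      int hi = k + 1;  // sentinel: impossible
      if (dir_high) {
        int lo_b = (int)((long long)C * k / N) + 1;  // first strictly-high c
        int hi_b = std::min(k, C);
        if (lo_b <= hi_b && zone_llr(g, hi_b, k, C, N, LCN) >= cut &&
            (long long)hi_b * N > (long long)C * k) {
          int a = lo_b, b = hi_b;
          while (a < b) {  // llr nondecreasing in c on the high side
            const int mid = a + (b - a) / 2;
            if ((long long)mid * N > (long long)C * k &&
                zone_llr(g, mid, k, C, N, LCN) >= cut) b = mid; else a = mid + 1;
          }
          hi = a;
        }
      }
      c_hi[k] = hi;
      // low side: largest c with llr >= cut and c/k < C/N
      int lo = -1;  // sentinel: impossible
      if (dir_low) {
        int lo_b = std::max(0, C - (N - k));
        int hi_b = ((long long)C * k % N == 0) ? (int)((long long)C * k / N) - 1
                                               : (int)((long long)C * k / N);
        if (lo_b <= hi_b && zone_llr(g, lo_b, k, C, N, LCN) >= cut &&
            (long long)lo_b * N < (long long)C * k) {
          int a = lo_b, b = hi_b;
          while (a < b) {  // llr nonincreasing in c on the low side
            const int mid = b - (b - a) / 2;
            if ((long long)mid * N < (long long)C * k &&
                zone_llr(g, mid, k, C, N, LCN) >= cut) a = mid; else b = mid - 1;
          }
          lo = a;
        }
      }
      c_lo[k] = lo;
    }
    RNGScope scope;
    IntegerVector yy = clone(y);
    for (int r = 0; r < n_mc; ++r) {
      // Fisher-Yates label permutation driven by R's RNG
      for (int i = N - 1; i > 0; --i) {
        const int j = (int)(unif_rand() * (i + 1));
        const int t = yy[i]; yy[i] = yy[j]; yy[j] = t;
      }
      bool exceeded = false;
      for (int i = 0; i < N && !exceeded; ++i) {
        const int* o = &ord[(size_t)i * K];
        const char* v = &valid[(size_t)i * K];
        int c = 0;
        for (int k = 0; k < K; ++k) {
          c += yy[o[k]];
          if (v[k] && (c >= c_hi[k + 1] || c <= c_lo[k + 1])) {
            exceeded = true;
            break;
          }
        }
      }
      if (exceeded) ++n_ge;
    }
  }

  IntegerVector members(best.size);
  for (int k = 0; k < best.size; ++k)
    members[k] = ord[(size_t)best.center * K + k] + 1;
  const double rad =
      best.size > 0 ? radius[(size_t)best.center * K + (best.size - 1)] : NA_REAL;

  return List::create(
      _["center_index"] = best.center + 1, _["n_z"] = best.size,
      _["c_z"] = best.cases, _["llr"] = best.llr,
      _["direction"] = best.dir == 1 ? "high" : "low", _["radius"] = rad,
      _["members"] = members, _["n_ge"] = n_ge, _["n_cases"] = C);
}
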