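#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

// Hartigan & Hartigan dip statistic: the smallest uniform distance between the
// empirical CDF and any unimodal CDF (convex on (-inf, mode], concave on
// [mode, inf), with an atom permitted at the mode).
//
// Work on the K unique sample values u_1 < ... < u_K with
//   A_j = fraction of observations strictly below u_j  (left limit of the ECDF)
//   B_j = fraction of observations <= u_j.
// A candidate unimodal CDF within distance d must run through the tube
// [B_j - d, A_j + d] at every u_j (continuity pins the left limit), except that
// at the mode itself a jump of the CDF may absorb the tube's upper constraint.
// For a mode between u_t and u_{t+1}, feasibility splits into a convex part on
// 1..t and a concave part on t+1..K; for a mode at u_t the convex part skips
// the lower check at t and the concave part skips the upper check at t.
// The minimal d for each part is half the largest deviation between the ECDF
// and the greatest convex minorant of the upper bounds (resp. least concave
// majorant of the lower bounds).
//
// The convex-side deviation P(t) is nondecreasing in t and the concave-side
// deviation S(t) nonincreasing, so min_t max(P(t), S(t+1)) sits at the single
// sign change of S - P; a binary search with O(K) single-prefix evaluations
// finds it in O(K log K) overall.

struct Ecdf {
  std::vector<double> x, A, B; // unique values, ECDF left limits, ECDF values
  int K;
};

// max_{j <= t} B_j - GCM_{A,0..t}(x_j); excl_last drops the j = t check
static double eval_convex(const Ecdf& e, int t, bool excl_last) {
  std::vector<int> st;
  st.reserve(t + 1);
  for (int i = 0; i <= t; ++i) {
    while (st.size() >= 2) {
      int a = st[st.size() - 2], b = st[st.size() - 1];
      if ((e.A[b] - e.A[a]) * (e.x[i] - e.x[b]) >=
          (e.A[i] - e.A[b]) * (e.x[b] - e.x[a]))
        st.pop_back();
      else
        break;
    }
    st.push_back(i);
  }
  double dev = R_NegInf;
  size_t seg = 0;
  int jmax = excl_last ? t - 1 : t;
  for (int j = 0; j <= jmax; ++j) {
    while (seg + 1 < st.size() && e.x[st[seg + 1]] < e.x[j]) ++seg;
    double g;
    if (seg + 1 < st.size()) { // x[st[seg]] <= x[j] <= x[st[seg+1]]
      int p = st[seg], q = st[seg + 1];
      g = e.A[p] + (e.A[q] - e.A[p]) * (e.x[j] - e.x[p]) / (e.x[q] - e.x[p]);
    } else {
      g = e.A[st[seg]]; // single-vertex hull (t = 0)
    }
    double d = e.B[j] - g;
    if (d > dev) dev = d;
  }
  return dev == R_NegInf ? 0.0 : dev;
}

// max_{j >= s} LCM_{B,s..K-1}(x_j) - A_j; excl_first drops the j = s check
static double eval_concave(const Ecdf& e, int s, bool excl_first) {
  const int K = e.K;
  std::vector<int> st;
  st.reserve(K - s);
  for (int i = K - 1; i >= s; --i) { // scan right-to-left, upper hull of B
    while (st.size() >= 2) {
      int a = st[st.size() - 2], b = st[st.size() - 1];
      // mirror of the convex case: pop b if it lies on or below chord a->i
      if ((e.B[b] - e.B[a]) * (e.x[i] - e.x[b]) >=
          (e.B[i] - e.B[b]) * (e.x[b] - e.x[a]))
        st.pop_back();
      else
        break;
    }
    st.push_back(i);
  }
  // st holds hull indices in decreasing x; st.back() == s
  double dev = R_NegInf;
  size_t seg = st.size() - 1;
  int jmin = excl_first ? s + 1 : s;
  for (int j = jmin; j <= K - 1; ++j) {
    while (seg >= 1 && e.x[st[seg - 1]] < e.x[j]) --seg;
    double g;
    if (e.x[st[seg]] == e.x[j]) {
      g = e.B[st[seg]];
    } else {
      int p = st[seg], q = st[seg - 1]; // x[p] < x[j] <= x[q]
      g = e.B[p] + (e.B[q] - e.B[p]) * (e.x[j] - e.x[p]) / (e.x[q] - e.x[p]);
    }
    double d = g - e.A[j];
    if (d > dev) dev = d;
  }
  return dev == R_NegInf ? 0.0 : dev;
}

// valley minimum of f(t) = max(g(t), h(t)) with g nondecreasing and h
// nonincreasing over integer t in [lo, hi]
template <typename G, typename H>
static double valley_min(int lo, int hi, G g, H h) {
  int t0 = lo - 1;
  int a = lo, b = hi;
  while (a <= b) {
    int mid = a + (b - a) / 2;
    if (h(mid) > g(mid)) { t0 = mid; a = mid + 1; }
    else b = mid - 1;
  }
  double best = R_PosInf;
  for (int t = std::max(lo, t0); t <= std::min(hi, t0 + 1); ++t) {
    double f = std::max(g(t), h(t));
    if (f < best) best = f;
  }
  if (!R_FINITE(best)) { // empty candidate window: take the ends
    best = std::min(std::max(g(lo), h(lo)), std::max(g(hi), h(hi)));
  }
  return best;
}

static double dip_from_ecdf(const Ecdf& e, double n) {
  const int K = e.K;
  // mode strictly between u_t and u_{t+1}, t in [-1, K-1]
  auto g1 = [&](int t) { return t >= 0 ? eval_convex(e, t, false) : 0.0; };
  auto h1 = [&](int t) { return t + 1 <= K - 1 ? eval_concave(e, t + 1, false) : 0.0; };
  double best = valley_min(-1, K - 1, g1, h1);
  // mode exactly at u_t (atom allowed there), t in [0, K-1]
  auto g2 = [&](int t) { return eval_convex(e, t, true); };
  auto h2 = [&](int t) { return eval_concave(e, t, true); };
  double best2 = valley_min(0, K - 1, g2, h2);
  if (best2 < best) best = best2;
  double D = 0.5 * best;
  double lo = 1.0 / (2.0 * n);
  return (D < lo) ? lo : D;
}

static double dip_sorted(const std::vector<double>& xs) {
  const double n = (double)xs.size();
  Ecdf e;
  e.x.reserve(xs.size());
  e.A.reserve(xs.size());
  e.B.reserve(xs.size());
  size_t i = 0;
  double below = 0.0;
  while (i < xs.size()) {
    size_t j = i;
    while (j < xs.size() && xs[j] == xs[i]) ++j;
    e.x.push_back(xs[i]);
    e.A.push_back(below / n);
    below += (double)(j - i);
    e.B.push_back(below / n);
    i = j;
  }
  e.K = (int)e.x.size();
  return dip_from_ecdf(e, n);
}

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(Rcpp::NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  return dip_sorted(xs);
}

// Monte-Carlo null sample of the dip under uniform(0,1), using R's RNG stream.
// [[Rcpp::export(name = ".dip_null_mc_cpp")]]
Rcpp::NumericVector dip_null_mc_cpp(int n, int B) {
  Rcpp::NumericVector out(B);
  std::vector<double> xs(n);
  Rcpp::RNGScope scope;
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) xs[i] = unif_rand();
    std::sort(xs.begin(), xs.end());
    out[b] = dip_sorted(xs);
  }
  return out;
}
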