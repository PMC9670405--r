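#include <Rcpp.h>
#include <vector>
#include <cmath>

// Online (stochastic) self-organizing map on a rectangular grid with a bubble
// neighbourhood: per presented event, the best-matching unit and every node
// within the current grid radius move a step alpha toward the event. Radius
// decays linearly from radius0 to 0 and alpha from alpha0 to alpha1 over the
// full presentation sequence. Initial codebook and presentation order come
// from the caller so the R side owns all randomness.

static int bmu(const std::vector<double>& cb, const double* ev, int k, int d) {
  int best = 0;
  double bestd = R_PosInf;
  for (int g = 0; g < k; ++g) {
    double s = 0.0;
    const double* row = &cb[(size_t)g * d];
    for (int j = 0; j < d; ++j) {
      double diff = ev[j] - row[j];
      s += diff * diff;
    }
    if (s < bestd) { bestd = s; best = g; } // strict: ties keep lowest index
  }
  return best;
}

// [[Rcpp::export(name = ".som_train_cpp")]]
Rcpp::NumericMatrix som_train_cpp(Rcpp::NumericMatrix X, Rcpp::NumericMatrix init,
                                  int rows, int cols, Rcpp::IntegerVector order,
                                  double radius0, double alpha0, double alpha1) {
  const int n = X.nrow(), d = X.ncol(), k = rows * cols;
  // row-major copies for locality
  std::vector<double> ev((size_t)n * d), cb((size_t)k * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) ev[(size_t)i * d + j] = X(i, j);
  for (int g = 0; g < k; ++g)
    for (int j = 0; j < d; ++j) cb[(size_t)g * d + j] = init(g, j);

  // grid coordinates, node g = (g % rows, g / rows) matching R column-major ids
  std::vector<double> gr(k), gc(k);
  for (int g = 0; g < k; ++g) { gr[g] = g % rows; gc[g] = g / rows; }
  std::vector<std::vector<double> > gd(k, std::vector<double>(k));
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b) {
      double dr = gr[a] - gr[b], dc = gc[a] - gc[b];
      gd[a][b] = std::sqrt(dr * dr + dc * dc);
    }

  const int T = order.size();
  for (int s = 0; s < T; ++s) {
    double frac = (T > 1) ? (double)s / (double)(T - 1) : 0.0;
    double alpha = alpha0 + (alpha1 - alpha0) * frac;
    double radius = radius0 * (1.0 - frac);
    int e = order[s] - 1;
    const double* evp = &ev[(size_t)e * d];
    int w = bmu(cb, evp, k, d);
    const std::vector<double>& dw = gd[w];
    for (int g = 0; g < k; ++g) {
      if (dw[g] <= radius) {
        double* row = &cb[(size_t)g * d];
        for (int j = 0; j < d; ++j) row[j] += alpha * (evp[j] - row[j]);
      }
    }
  }

  Rcpp::NumericMatrix out(k, d);
  for (int g = 0; g < k; ++g)
    for (int j = 0; j < d; ++j) out(g, j) = cb[(size_t)g * d + j];
  return out;
}

// [[Rcpp::export(name = ".som_assign_cpp")]]
Rcpp::List som_assign_cpp(Rcpp::NumericMatrix codebook, Rcpp::NumericMatrix X) {
  const int n = X.nrow(), d = X.ncol(), k = codebook.nrow();
  std::vector<double> cb((size_t)k * d);
  for (int g = 0; g < k; ++g)
    for (int j = 0; j < d; ++j) cb[(size_t)g * d + j] = codebook(g, j);
  Rcpp::IntegerVector node(n);
  Rcpp::NumericVector dist(n);
  std::vector<double> evrow(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) evrow[j] = X(i, j);
    int w = bmu(cb, &evrow[0], k, d);
    node[i] = w + 1;
    double s = 0.0;
    const double* row = &cb[(size_t)w * d];
    for (int j = 0; j < d; ++j) {
      double diff = evrow[j] - row[j];
      s += diff * diff;
    }
    dist[i] = std::sqrt(s);
  }
  return Rcpp::List::create(Rcpp::Named("node") = node,
                            Rcpp::Named("dist") = dist);
}
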