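#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Pincus approximate entropy, self-matches included, Chebyshev distance,
// natural log. ApEn = Phi_m(r) - Phi_{m+1}(r). Template matches for m and
// m+1 are counted in one symmetric pass over pairs: a pair matching at
// length m+1 also matches at length m.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector xv, int m, double r) {
  const int n = xv.size();
  const double* x = REAL(xv);
  const int nv1 = n - m + 1;  // templates of length m
  const int nv2 = n - m;      // templates of length m+1
  std::vector<double> c1(nv1, 1.0), c2(nv2, 1.0);  // self-matches
  for (int i = 0; i < nv1; ++i) {
    for (int j = i + 1; j < nv1; ++j) {
      double d = 0.0;
      int k = 0;
      for (; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > r) break;
      }
      if (k < m) continue;  // not even an m-match
      c1[i] += 1.0;
      c1[j] += 1.0;
      if (i < nv2 && j < nv2 && std::fabs(x[i + m] - x[j + m]) <= r &&
          d <= r) {
        c2[i] += 1.0;
        c2[j] += 1.0;
      }
    }
  }
  double phi1 = 0.0, phi2 = 0.0;
  for (int i = 0; i < nv1; ++i) phi1 += std::log(c1[i] / nv1);
  for (int i = 0; i < nv2; ++i) phi2 += std::log(c2[i] / nv2);
  return phi1 / nv1 - phi2 / nv2;
}

// Correlation sums C(r) of a delay embedding over an ascending radius
// grid. C(r) = (2 / (N (N-1))) * #{i<j : ||y_i - y_j|| <= r}, Euclidean.
// Each pair is placed in the first radius >= its distance by binary
// search; a cumulative sum then yields all C(r) at once.
// [[Rcpp::export(name = ".corr_sums_cpp")]]
NumericVector corr_sums_cpp(NumericVector xv, int emb_dim, int delay,
                            NumericVector radii) {
  const int n = xv.size();
  const double* x = REAL(xv);
  const int np = n - (emb_dim - 1) * delay;
  const int nr = radii.size();
  std::vector<double> r2(nr);
  for (int q = 0; q < nr; ++q) r2[q] = radii[q] * radii[q];
  std::vector<double> hist(nr, 0.0);
  const double rmax2 = r2[nr - 1];
  for (int i = 0; i < np; ++i) {
    for (int j = i + 1; j < np; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < emb_dim; ++k) {
        double dk = x[i + k * delay] - x[j + k * delay];
        d2 += dk * dk;
        if (d2 > rmax2) break;
      }
      if (d2 > rmax2) continue;
      int pos = (int)(std::lower_bound(r2.begin(), r2.end(), d2) -
                      r2.begin());
      hist[pos] += 1.0;
    }
  }
  NumericVector out(nr);
  double npairs = (double)np * (np - 1.0) / 2.0;
  double acc = 0.0;
  for (int q = 0; q < nr; ++q) {
    acc += hist[q];
    out[q] = acc / npairs;
  }
  return out;
}

// Pairwise Euclidean distances of the embedding, subsampled to at most
// max_pairs via a fixed stride; used to set the scaling-region radii.
// [[Rcpp::export(name = ".embed_dist_sample_cpp")]]
NumericVector embed_dist_sample_cpp(NumericVector xv, int emb_dim, int delay,
                                    int max_pairs) {
  const int n = xv.size();
  const double* x = REAL(xv);
  const int np = n - (emb_dim - 1) * delay;
  const double total = (double)np * (np - 1.0) / 2.0;
  int stride = (int)std::ceil(total / (double)max_pairs);
  if (stride < 1) stride = 1;
  std::vector<double> out;
  out.reserve((size_t)(total / stride) + 1);
  long long idx = 0;
  for (int i = 0; i < np; ++i) {
    for (int j = i + 1; j < np; ++j, ++idx) {
      if (idx % stride != 0) continue;
      double d2 = 0.0;
      for (int k = 0; k < emb_dim; ++k) {
        double dk = x[i + k * delay] - x[j + k * delay];
        d2 += dk * dk;
      }
      out.push_back(std::sqrt(d2));
    }
  }
  return wrap(out);
}

// Hampel filter: replace x[i] by the window median when it deviates from it
// by more than n_mad scaled MADs (1.4826 * median |x_j - med|, j in window).
// Window is centered, half-width h = (window-1)/2, truncated at the edges.
// [[Rcpp::export(name = ".hampel_cpp")]]
NumericVector hampel_cpp(NumericVector xv, int window, double n_mad) {
  const int n = xv.size();
  const double* x = REAL(xv);
  const int h = (window - 1) / 2;
  const double kappa = 1.4826;
  NumericVector y = clone(xv);
  std::vector<double> buf;
  buf.reserve(window);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - h), hi = std::min(n - 1, i + h);
    buf.assign(x + lo, x + hi + 1);
    const int w = (int)buf.size();
    std::nth_element(buf.begin(), buf.begin() + w / 2, buf.end());
    double med = buf[w / 2];
    if (w % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + w / 2 - 1, buf.end());
      med = 0.5 * (med + buf[w / 2 - 1]);
    }
    for (int k = 0; k < w; ++k) buf[k] = std::fabs(x[lo + k] - med);
    std::nth_element(buf.begin(), buf.begin() + w / 2, buf.end());
    double mad = buf[w / 2];
    if (w % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + w / 2 - 1, buf.end());
      mad = 0.5 * (mad + buf[w / 2 - 1]);
    }
    if (std::fabs(x[i] - med) > n_mad * kappa * mad) y[i] = med;
  }
  return y;
}
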