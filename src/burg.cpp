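#include <Rcpp.h>
#include <cmath>
#include <cfloat>
#include <vector>

using namespace Rcpp;

// Burg (maximum-entropy) AR estimation of one window.
// Fills `a` (length `order`) with prediction coefficients in the convention
// x[t] = sum_k a[k] x[t-k] + e[t], and returns the final prediction error
// variance. `x` is assumed demeaned by the caller.
static double burg_fit(const std::vector<double>& x, int order,
                       std::vector<double>& a) {
  const int n = (int)x.size();
  std::vector<double> f(x), b(x), tmp(order);
  double e = 0.0;
  for (int i = 0; i < n; ++i) e += x[i] * x[i];
  e /= n;
  for (int k = 0; k < order; ++k) {
    double num = 0.0, den = 0.0;
    for (int i = k + 1; i < n; ++i) {
      num += f[i] * b[i - 1];
      den += f[i] * f[i] + b[i - 1] * b[i - 1];
    }
    double rc = (den > 0.0) ? 2.0 * num / den : 0.0;
    e *= (1.0 - rc * rc);
    for (int i = 0; i < k; ++i) tmp[i] = a[i] - rc * a[k - 1 - i];
    for (int i = 0; i < k; ++i) a[i] = tmp[i];
    a[k] = rc;
    for (int i = n - 1; i > k; --i) {
      double fi = f[i];
      f[i] = fi - rc * b[i - 1];
      b[i] = b[i - 1] - rc * fi;
    }
  }
  return e;
}

// [[Rcpp::export(name = ".burg_ar")]]
List burg_ar(NumericVector x, int order, bool demean = true) {
  int n = x.size();
  if (order >= n) stop("AR order must be smaller than the window length");
  std::vector<double> xv(n);
  double mu = 0.0;
  if (demean) {
    for (int i = 0; i < n; ++i) mu += x[i];
    mu /= n;
  }
  for (int i = 0; i < n; ++i) xv[i] = x[i] - mu;
  std::vector<double> a(order, 0.0);
  double e = burg_fit(xv, order, a);
  return List::create(_["ar"] = NumericVector(a.begin(), a.end()),
                      _["var_pred"] = e);
}

// Evaluate the AR power spectral density at the requested frequencies:
// psd(f) = var / |1 - sum_k a_k exp(-i 2 pi f k / fs)|^2.
static void ar_psd(const std::vector<double>& a, double var,
                   const std::vector<double>& cosw,
                   const std::vector<double>& sinw,
                   int nfreq, int order, double* out) {
  for (int j = 0; j < nfreq; ++j) {
    // Recursively form cos(k w_j), sin(k w_j) from the k = 1 values.
    double c1 = cosw[j], s1 = sinw[j];
    double ck = 1.0, sk = 0.0; // k = 0
    double re = 1.0, im = 0.0;
    for (int k = 0; k < order; ++k) {
      double cn = ck * c1 - sk * s1;
      double sn = sk * c1 + ck * s1;
      ck = cn; sk = sn; // now cos/sin((k+1) w_j)
      re -= a[k] * ck;
      im += a[k] * sk;
    }
    double denom = re * re + im * im;
    out[j] = var / std::max(denom, 1e-300);
  }
}

// Sliding-window Burg spectrogram: rows are windows starting at samples
// 0, step, 2*step, ... (0-based), columns are the requested frequencies.
// [[Rcpp::export(name = ".burg_spectrogram")]]
NumericMatrix burg_spectrogram(NumericVector x, int win, int step, int order,
                               NumericVector freq, double fs) {
  int n = x.size();
  if (win > n) stop("signal shorter than one window");
  if (order >= win) stop("AR order must be smaller than the window length");
  int nwin = (n - win) / step + 1;
  int nfreq = freq.size();
  std::vector<double> cosw(nfreq), sinw(nfreq);
  for (int j = 0; j < nfreq; ++j) {
    double w = 2.0 * M_PI * freq[j] / fs;
    cosw[j] = std::cos(w);
    sinw[j] = std::sin(w);
  }
  NumericMatrix out(nwin, nfreq);
  std::vector<double> seg(win), a(order), row(nfreq);
  for (int w = 0; w < nwin; ++w) {
    int s0 = w * step;
    double mu = 0.0;
    for (int i = 0; i < win; ++i) mu += x[s0 + i];
    mu /= win;
    double ss = 0.0;
    for (int i = 0; i < win; ++i) {
      seg[i] = x[s0 + i] - mu;
      ss += seg[i] * seg[i];
    }
    if (ss <= 0.0) {
      // Degenerate (constant) window: floor at machine epsilon.
      for (int j = 0; j < nfreq; ++j) out(w, j) = DBL_EPSILON;
      continue;
    }
    std::fill(a.begin(), a.end(), 0.0);
    double e = burg_fit(seg, order, a);
    if (e <= 0.0) e = DBL_EPSILON;
    ar_psd(a, e, cosw, sinw, nfreq, order, row.data());
    for (int j = 0; j < nfreq; ++j) out(w, j) = row[j];
  }
  return out;
}
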