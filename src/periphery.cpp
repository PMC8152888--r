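#include <Rcpp.h>
using namespace Rcpp;

// One gammatone channel: cascade of four second-order sections sharing the
// denominator (b0, b1, b2); the four numerators differ only in their first-
// order coefficient (a11..a14). Coefficients follow the all-pole gammatone
// digital approximation with per-channel normalising gain.
static void gammatone_channel(const NumericVector& x, double a0, double a11,
                              double a12, double a13, double a14, double a2,
                              double b1, double b2, double gain,
                              std::vector<double>& y) {
  const R_xlen_t n = x.size();
  y.assign(n, 0.0);
  const double a1s[4] = {a11 / gain, a12, a13, a14};
  const double b0s[4] = {a0 / gain, a0, a0, a0};
  const double a2s[4] = {a2 / gain, a2, a2, a2};
  // all four second-order sections in a single pass (direct form II)
  double w1[4] = {0, 0, 0, 0}, w2[4] = {0, 0, 0, 0};
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    for (int s = 0; s < 4; ++s) {
      double w0 = v - b1 * w1[s] - b2 * w2[s];
      v = b0s[s] * w0 + a1s[s] * w1[s] + a2s[s] * w2[s];
      w2[s] = w1[s]; w1[s] = w0;
    }
    y[i] = v;
  }
}

// Meddis hair-cell transduction (reservoir model), constants as published
// for the 1988 parameterisation. Input is the filter output interpreted as
// instantaneous amplitude; output approximates firing probability * h.
static void meddis_haircell(std::vector<double>& s, double fs) {
  const double M = 1.0, A = 5.0, B = 300.0, g = 2000.0, y = 5.05,
               l = 2500.0, r = 6580.0, x = 66.31, h = 50000.0;
  const double dt = 1.0 / fs;
  double kt = g * A / (A + B);
  double spont = M * y * kt / (l * kt + y * (l + r));
  double c = spont;
  double q = c * (l + r) / kt;
  double w = c * r / x;
  for (std::size_t i = 0; i < s.size(); ++i) {
    double limited = s[i] + A > 0.0 ? s[i] + A : 0.0;
    kt = g * limited / (limited + B);
    double replenish = M - q > 0.0 ? y * (M - q) : 0.0;
    double eject = kt * q;
    double loss = l * c;
    double reuptake = r * c;
    double reprocess = x * w;
    q += (replenish - eject + reprocess) * dt;
    c += (eject - loss - reuptake) * dt;
    w += (reuptake - reprocess) * dt;
    s[i] = c * h;
  }
}

// Simplified transduction: half-wave rectification, power-law compression
// and a divisive adaptation loop (gain divided by a slow low-passed copy of
// the output, time constant tau). Output is non-negative by construction.
static void rca_haircell(std::vector<double>& s, double fs,
                         double compression, double adapt_strength,
                         double tau) {
  const double alpha = 1.0 - std::exp(-1.0 / (tau * fs));
  double state = 0.0;
  for (std::size_t i = 0; i < s.size(); ++i) {
    double v = s[i] > 0.0 ? std::pow(s[i], compression) : 0.0;
    double out = v / (1.0 + adapt_strength * state);
    state += alpha * (out - state);
    s[i] = out;
  }
}

// [[Rcpp::export]]
NumericMatrix periphery_kernel(NumericVector x, double fs,
                               NumericMatrix coefs, std::string haircell,
                               double out_rate, double compression,
                               double adapt_strength, double adapt_tau) {
  const int n_channels = coefs.nrow();
  const double ratio = fs / out_rate;
  const R_xlen_t n = x.size();
  const R_xlen_t n_out = (R_xlen_t)std::floor((double)n / ratio);
  NumericMatrix out(n_channels, n_out);
  std::vector<double> y;
  for (int ch = 0; ch < n_channels; ++ch) {
    gammatone_channel(x, coefs(ch, 0), coefs(ch, 1), coefs(ch, 2),
                      coefs(ch, 3), coefs(ch, 4), coefs(ch, 5),
                      coefs(ch, 6), coefs(ch, 7), coefs(ch, 8), y);
    if (haircell == "meddis") meddis_haircell(y, fs);
    else rca_haircell(y, fs, compression, adapt_strength, adapt_tau);
    // block-average decimation to the output rate
    for (R_xlen_t j = 0; j < n_out; ++j) {
      R_xlen_t lo = (R_xlen_t)std::floor(j * ratio);
      R_xlen_t hi = (R_xlen_t)std::floor((j + 1) * ratio);
      if (hi > n) hi = n;
      double acc = 0.0;
      for (R_xlen_t k = lo; k < hi; ++k) acc += y[k];
      out(ch, j) = acc / (double)(hi - lo);
    }
  }
  return out;
}
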