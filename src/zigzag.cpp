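#include <Rcpp.h>
using namespace Rcpp;

// Amplitude-hysteresis turning-point scan (zigzag). An extremum is accepted
// once the trace has reversed by >= thr from the running candidate extremum;
// each accepted extremum is therefore >= thr away from the previously
// accepted one. The first reference is the trace's starting value.
// [[Rcpp::export(name = ".zigzag_cpp")]]
List zigzag_cpp(NumericVector x, double thr) {
  int n = x.size();
  std::vector<int> idx;
  std::vector<double> amp;
  std::vector<int> pol;
  if (n >= 2) {
    double ref = x[0], cand = x[0];
    int ci = 0, dir = 0;
    for (int i = 1; i < n; ++i) {
      double v = x[i];
      if (dir == 0) {
        if (v >= ref + thr) { dir = 1; cand = v; ci = i; }
        else if (v <= ref - thr) { dir = -1; cand = v; ci = i; }
      } else if (dir == 1) {
        if (v > cand) { cand = v; ci = i; }
        else if (v <= cand - thr) {
          idx.push_back(ci + 1); amp.push_back(cand - ref); pol.push_back(1);
          ref = cand; dir = -1; cand = v; ci = i;
        }
      } else {
        if (v < cand) { cand = v; ci = i; }
        else if (v >= cand + thr) {
          idx.push_back(ci + 1); amp.push_back(ref - cand); pol.push_back(-1);
          ref = cand; dir = 1; cand = v; ci = i;
        }
      }
    }
  }
  return List::create(_["idx"] = wrap(idx), _["amplitude"] = wrap(amp),
                      _["polarity"] = wrap(pol));
}

// Single biquad pass, zero initial state.
static void biquad_pass(std::vector<double>& x, const double b[3],
                        const double a[2]) {
  double x1 = 0, x2 = 0, y1 = 0, y2 = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    double xi = x[i];
    double yi = b[0] * xi + b[1] * x1 + b[2] * x2 - a[0] * y1 - a[1] * y2;
    x2 = x1; x1 = xi; y2 = y1; y1 = yi;
    x[i] = yi;
  }
}

// Zero-phase 2nd-order Butterworth high-pass (applied forward and backward,
// so the effective magnitude response is 4th order). Odd-reflection padding
// suppresses edge transients.
// [[Rcpp::export(name = ".highpass_cpp")]]
NumericVector highpass_cpp(NumericVector x, double cutoff_hz, double fs,
                           int pad) {
  int n = x.size();
  if (n < 4 || cutoff_hz <= 0) return clone(x);
  if (pad > n - 1) pad = n - 1;

  double w0 = 2.0 * M_PI * cutoff_hz / fs;
  double cw = std::cos(w0);
  double alpha = std::sin(w0) / std::sqrt(2.0);  // Q = 1/sqrt(2)
  double a0 = 1.0 + alpha;
  double b[3] = { (1.0 + cw) / 2.0 / a0, -(1.0 + cw) / a0, (1.0 + cw) / 2.0 / a0 };
  double a[2] = { -2.0 * cw / a0, (1.0 - alpha) / a0 };

  std::vector<double> xp(n + 2 * pad);
  for (int i = 0; i < pad; ++i) xp[i] = 2.0 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) xp[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) xp[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  biquad_pass(xp, b, a);
  std::reverse(xp.begin(), xp.end());
  biquad_pass(xp, b, a);
  std::reverse(xp.begin(), xp.end());

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = xp[pad + i];
  return out;
}
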