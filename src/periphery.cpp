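#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One second-order IIR section applied in place (transposed direct form II),
// repeated `times` to realise a cascade of identical sections.
static void biquad_cascade(std::vector<double> &x,
                           const double *b, const double *a, int times) {
  const int n = (int)x.size();
  for (int s = 0; s < times; ++s) {
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double xn = x[i];
      double yn = b[0] * xn + z1;
      z1 = b[1] * xn - a[1] * yn + z2;
      z2 = b[2] * xn - a[2] * yn;
      x[i] = yn;
    }
  }
}

// Cascade of first-order gammatone stages realised as complex one-pole
// resonators. Each stage has unit gain at the resonator frequency
// (per-stage gain 1 - |p|); the factor 2 at the end folds the suppressed
// negative-frequency component back so that an on-frequency tone passes
// with unit amplitude.
static void gammatone_cascade(std::vector<double> &xr, double pre, double pim,
                              int nstages) {
  const int n = (int)xr.size();
  const double r = std::sqrt(pre * pre + pim * pim);
  const double g = 1.0 - r;
  std::vector<double> xi(n, 0.0);
  for (int s = 0; s < nstages; ++s) {
    double wr = 0.0, wi = 0.0;
    for (int i = 0; i < n; ++i) {
      double ir = xr[i], ii = xi[i];
      double nwr = g * ir + pre * wr - pim * wi;
      double nwi = g * ii + pre * wi + pim * wr;
      wr = nwr;
      wi = nwi;
      xr[i] = wr;
      xi[i] = wi;
    }
  }
  for (int i = 0; i < n; ++i) xr[i] *= 2.0;
}

static inline double broken_stick_scalar(double i, double a, double b,
                                         double c) {
  double ai = std::fabs(i);
  if (ai == 0.0) return 0.0;
  double lin = a * ai;
  double comp = b * std::pow(ai, c);
  double y = lin < comp ? lin : comp;
  return i < 0.0 ? -y : y;
}

// In-place broken stick over a vector. The knee |i| = (b/a)^(1/(1-c))
// splits the domain: below it the linear branch wins and no power call is
// needed; c = 1/4 (the human parameter set's constant) uses two square
// roots instead of pow.
static void broken_stick_vec(std::vector<double> &x, double a, double b,
                             double c) {
  const double knee = std::pow(b / a, 1.0 / (1.0 - c));
  const bool quarter = std::fabs(c - 0.25) < 1e-12;
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    double av = std::fabs(v);
    if (av <= knee) {
      x[i] = a * v;
    } else {
      double comp =
          b * (quarter ? std::sqrt(std::sqrt(av)) : std::pow(av, c));
      x[i] = v < 0.0 ? -comp : comp;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_broken_stick(NumericVector input, double a, double b,
                               double c) {
  int n = input.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = broken_stick_scalar(input[i], a, b, c);
  return out;
}

// Dual-resonance non-linear filter for one channel.
// prm holds, for the linear path: gain, pole (re, im), number of gammatone
// stages, one low-pass biquad (b, a) and its cascade count; likewise for the
// non-linear path plus the broken-stick coefficients a, b, c.
// [[Rcpp::export]]
NumericVector cpp_drnl_channel(NumericVector x, List prm) {
  const int n = x.size();
  std::vector<double> lin(x.begin(), x.end());
  std::vector<double> nl(x.begin(), x.end());

  // linear path: gain -> gammatones -> low-pass cascade
  double lin_gain = as<double>(prm["lin_gain"]);
  for (int i = 0; i < n; ++i) lin[i] *= lin_gain;
  gammatone_cascade(lin, as<double>(prm["lin_pole_re"]),
                    as<double>(prm["lin_pole_im"]),
                    as<int>(prm["lin_n_gt"]));
  {
    NumericVector b = prm["lin_lp_b"], a = prm["lin_lp_a"];
    biquad_cascade(lin, b.begin(), a.begin(), as<int>(prm["lin_n_lp"]));
  }

  // non-linear path: gammatones -> broken stick -> gammatones -> low-pass
  double pa = as<double>(prm["a"]), pb = as<double>(prm["b"]),
         pc = as<double>(prm["c"]);
  double npre = as<double>(prm["nl_pole_re"]),
         npim = as<double>(prm["nl_pole_im"]);
  int n_gt_nl = as<int>(prm["nl_n_gt"]);
  gammatone_cascade(nl, npre, npim, n_gt_nl);
  broken_stick_vec(nl, pa, pb, pc);
  gammatone_cascade(nl, npre, npim, n_gt_nl);
  {
    NumericVector b = prm["nl_lp_b"], a = prm["nl_lp_a"];
    biquad_cascade(nl, b.begin(), a.begin(), as<int>(prm["nl_n_lp"]));
  }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = lin[i] + nl[i];
  return out;
}

// Leaky-integrate-and-fire spike count for one fiber.
// Membrane: v <- v + (dt/tau) (-v + I) + sigma * sqrt(2 dt / tau) * xi,
// spike and reset to 0 when v >= theta, absolute refractory period t_ref.
// Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
int cpp_lif_spike_count(NumericVector current, double theta, double sigma,
                        double tau, double t_ref, double dt) {
  const int n = current.size();
  const double alpha = dt / tau;
  const double noise_scale = sigma * std::sqrt(2.0 * dt / tau);
  const int ref_steps = (int)std::ceil(t_ref / dt);
  double v = 0.0;
  int refractory = 0;
  int count = 0;
  for (int i = 0; i < n; ++i) {
    if (refractory > 0) {
      --refractory;
      continue;
    }
    double xi = sigma > 0.0 ? norm_rand() : 0.0;
    v += alpha * (-v + current[i]) + noise_scale * xi;
    if (v >= theta) {
      ++count;
      v = 0.0;
      refractory = ref_steps;
    }
  }
  return count;
}

// Spike counts for the three fiber classes attached to one channel.
// drive is the common deterministic input current (already scaled and
// rectified); each class has its own threshold and noise level.
// [[Rcpp::export]]
IntegerVector cpp_lif_channel_counts(NumericVector drive, NumericVector theta,
                                     NumericVector sigma, double tau,
                                     double t_ref, double dt) {
  int k = theta.size();
  IntegerVector out(k);
  for (int j = 0; j < k; ++j)
    out[j] = cpp_lif_spike_count(drive, theta[j], sigma[j], tau, t_ref, dt);
  return out;
}

// Half-wave rectified mean of a waveform (the deterministic drive statistic
// used by the rate-mode transfer functions).
// [[Rcpp::export]]
double cpp_rectified_mean(NumericVector x) {
  double s = 0.0;
  int n = x.size();
  for (int i = 0; i < n; ++i)
    if (x[i] > 0.0) s += x[i];
  return n > 0 ? s / n : 0.0;
}
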