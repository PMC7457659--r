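#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Excitation patterns from banded component spectra.
//
// Each column of `levels_db` holds the post-ear-filter levels (dB) of the
// 61 spectral components (one per analysis band, treated as a sinusoid at
// the band centre). For every auditory channel the component contributions
// are weighted by a rounded-exponential (roex) filter whose lower skirt
// broadens with component level, and power-summed:
//
//   w(g) = (1 + p g) exp(-p g),  g = |f - fc| / fc
//   upper skirt: p_u = 4 fc / ERB(fc)                (level-invariant)
//   lower skirt: p_l = p51 (1 - 0.35 (L - 51) / p51_1k)   per component
//
// Components below `floor_db` are treated as absent. Returns excitation in
// dB, floored at -100 dB.
//
// [[Rcpp::export(name = ".excitation_matrix_cpp")]]
NumericMatrix excitation_matrix_cpp(NumericMatrix levels_db,
                                    NumericVector component_hz,
                                    NumericVector channel_hz,
                                    NumericVector p51,
                                    double p51_1k,
                                    double floor_db) {
  const int n_comp = levels_db.nrow();
  const int n_frames = levels_db.ncol();
  const int n_chan = channel_hz.size();
  if (component_hz.size() != n_comp)
    stop("component frequency table does not match spectrum rows");
  if (p51.size() != n_chan)
    stop("p51 table does not match channel count");

  // precompute normalised deviations g and the upper-skirt weights
  std::vector<double> g(n_chan * n_comp);
  std::vector<double> w_upper(n_chan * n_comp);
  std::vector<bool> upper_side(n_chan * n_comp);
  for (int i = 0; i < n_chan; ++i) {
    const double fc = channel_hz[i];
    const double pu = p51[i];  // upper skirt fixed at the 51-dB value
    for (int j = 0; j < n_comp; ++j) {
      const double dev = std::fabs(component_hz[j] - fc) / fc;
      const double gd = dev > 4.0 ? 4.0 : dev;
      g[i * n_comp + j] = gd;
      upper_side[i * n_comp + j] = component_hz[j] >= fc;
      const double pg = pu * gd;
      w_upper[i * n_comp + j] = (1.0 + pg) * std::exp(-pg);
    }
  }

  NumericMatrix out(n_chan, n_frames);
  for (int t = 0; t < n_frames; ++t) {
    for (int i = 0; i < n_chan; ++i) {
      double e = 0.0;
      const double pi51 = p51[i];
      for (int j = 0; j < n_comp; ++j) {
        const double L = levels_db(j, t);
        if (L <= floor_db) continue;
        const double pow_j = std::pow(10.0, L / 10.0);
        const int k = i * n_comp + j;
        double w;
        if (upper_side[k]) {
          w = w_upper[k];
        } else {
          double pl = pi51 * (1.0 - 0.35 * (L - 51.0) / p51_1k);
          if (pl < 0.1) pl = 0.1;
          const double pg = pl * g[k];
          w = (1.0 + pg) * std::exp(-pg);
        }
        e += w * pow_j;
      }
      out(i, t) = e > 1e-10 ? 10.0 * std::log10(e) : -100.0;
    }
  }
  return out;
}

// Cascaded asymmetric one-pole smoothing of a loudness series (sone
// domain). `a_attack` is used when the input exceeds the state, `a_release`
// otherwise. The state starts at 0.
//
// [[Rcpp::export(name = ".ar_smooth_cpp")]]
NumericVector ar_smooth_cpp(NumericVector x, double a_attack,
                            double a_release) {
  const int n = x.size();
  NumericVector out(n);
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double a = x[i] > s ? a_attack : a_release;
    s += a * (x[i] - s);
    out[i] = s;
  }
  return out;
}
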