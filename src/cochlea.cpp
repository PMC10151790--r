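#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample-synchronous CAR-FAC cascade.
//
// Each channel is a two-state coupled-form asymmetric resonator:
//   z1' = r*(a0*z1 - c0*z2) + x
//   z2' = r*(c0*z1 + a0*z2)
//   y   = g*(x + h*z2')
// with r = r1 + drz * nlf * b, where b in [0,1] is the per-channel relative
// undamping driven by the AGC loop (fast-acting compression) and nlf is the
// instantaneous outer-hair-cell velocity nonlinearity. With fac_enabled =
// false, r is frozen at its maximally undamped value (b = 1, nlf = 1) and the
// cascade is exactly linear.
//
// DIHC: half-wave rectification of the BM output followed by two one-pole
// low-pass smoothers. AGC: per channel, a 4-stage cascade of one-pole
// smoothers of the IHC output with geometrically increasing time constants;
// the mixed stage output sets b = 1 / (1 + strength * control).
//
// Optional fixed-point emulation quantises the BM and IHC state variables to
// a signed word of `q_bits` with `q_frac` fractional bits (0 = off).
static inline double quantize(double x, double step, double lim) {
  double q = std::nearbyint(x / step) * step;
  if (q > lim) q = lim;
  if (q < -lim) q = -lim;
  return q;
}

// [[Rcpp::export]]
List carfac_process_cpp(NumericVector x,
                        NumericVector a0, NumericVector c0,
                        NumericVector h, NumericVector g,
                        NumericVector r1, NumericVector drz,
                        double c_ihc,
                        NumericVector agc_c, NumericVector agc_w,
                        double agc_strength,
                        double ohc_vel_scale, double ohc_vel_offset,
                        bool fac_enabled,
                        double ihc_gain,
                        int bm_q_bits, int bm_q_frac,
                        int ihc_q_bits, int ihc_q_frac) {
  const int T = x.size();
  const int N = a0.size();
  NumericMatrix bm(T, N);
  NumericMatrix ihc(T, N);

  std::vector<double> z1(N, 0.0), z2(N, 0.0);
  std::vector<double> lp1(N, 0.0), lp2(N, 0.0);
  const int n_agc = agc_c.size();
  std::vector<double> agc(N * n_agc, 0.0);
  std::vector<double> b(N, 1.0);

  const bool q_bm = bm_q_bits > 0;
  const bool q_ihc = ihc_q_bits > 0;
  const double bm_step = q_bm ? std::ldexp(1.0, -bm_q_frac) : 0.0;
  const double bm_lim = q_bm ? std::ldexp(1.0, bm_q_bits - 1 - bm_q_frac) : 0.0;
  const double ihc_step = q_ihc ? std::ldexp(1.0, -ihc_q_frac) : 0.0;
  const double ihc_lim = q_ihc ? std::ldexp(1.0, ihc_q_bits - 1 - ihc_q_frac) : 0.0;

  for (int t = 0; t < T; ++t) {
    double in = x[t];
    for (int i = 0; i < N; ++i) {
      double r;
      if (fac_enabled) {
        // one-sample-lagged OHC velocity nonlinearity (z2 is the velocity
        // proxy in the coupled form), standard for the digital OHC
        double nlf = 1.0 / (1.0 + std::pow(ohc_vel_scale * z2[i] + ohc_vel_offset, 2.0));
        r = r1[i] + drz[i] * nlf * b[i];
      } else {
        r = r1[i] + drz[i];
      }
      {
        double z1n = r * (a0[i] * z1[i] - c0[i] * z2[i]) + in;
        double z2n = r * (c0[i] * z1[i] + a0[i] * z2[i]);
        z1[i] = z1n;
        z2[i] = z2n;
      }
      if (q_bm) {
        z1[i] = quantize(z1[i], bm_step, bm_lim);
        z2[i] = quantize(z2[i], bm_step, bm_lim);
      }
      double y = g[i] * (in + h[i] * z2[i]);
      bm(t, i) = y;
      in = y;  // cascade: next channel filters this channel's output

      // DIHC: half-wave + double one-pole smoothing
      double hw = y > 0.0 ? y : 0.0;
      lp1[i] += c_ihc * (hw - lp1[i]);
      lp2[i] += c_ihc * (lp1[i] - lp2[i]);
      if (q_ihc) {
        lp1[i] = quantize(lp1[i], ihc_step, ihc_lim);
        lp2[i] = quantize(lp2[i], ihc_step, ihc_lim);
      }
      double det = ihc_gain * lp2[i];
      ihc(t, i) = det;

      if (fac_enabled) {
        double *ag = &agc[i * n_agc];
        double prev = det;
        double control = 0.0;
        for (int s = 0; s < n_agc; ++s) {
          ag[s] += agc_c[s] * (prev - ag[s]);
          prev = ag[s];
          control += agc_w[s] * ag[s];
        }
        b[i] = 1.0 / (1.0 + agc_strength * control);
      }
    }
  }
  return List::create(_["bm"] = bm, _["ihc"] = ihc);
}

// Leaky integrate-and-fire bank over a (time x channel) drive matrix.
// v[t] = v[t-1] + c_lif * (drive - v[t-1]); spike iff v > threshold
// (strict), then v = v_reset in the same sample. One membrane per
// (channel, threshold, neuron) triple; neurons within a threshold group are
// desynchronised by deterministic initial potentials `init_frac * threshold`.
// [[Rcpp::export]]
List lif_encode_cpp(NumericMatrix drive, double c_lif,
                    NumericVector thresholds, int neurons_per_threshold,
                    double v_reset, NumericVector init_frac) {
  const int T = drive.nrow();
  const int N = drive.ncol();
  const int K = thresholds.size();
  const int M = neurons_per_threshold;

  std::vector<double> v(N * K * M);
  for (int ch = 0; ch < N; ++ch)
    for (int k = 0; k < K; ++k)
      for (int m = 0; m < M; ++m)
        v[(ch * K + k) * M + m] = init_frac[m] * thresholds[k];

  std::vector<int> out_t, out_ch, out_k, out_m;
  for (int t = 0; t < T; ++t) {
    for (int ch = 0; ch < N; ++ch) {
      double d = drive(t, ch);
      for (int k = 0; k < K; ++k) {
        for (int m = 0; m < M; ++m) {
          double &vm = v[(ch * K + k) * M + m];
          vm += c_lif * (d - vm);
          if (vm > thresholds[k]) {
            out_t.push_back(t);
            out_ch.push_back(ch);
            out_k.push_back(k);
            out_m.push_back(m);
            vm = v_reset;
          }
        }
      }
    }
  }
  return List::create(_["t"] = wrap(out_t), _["channel"] = wrap(out_ch),
                      _["threshold_id"] = wrap(out_k), _["neuron_id"] = wrap(out_m));
}
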