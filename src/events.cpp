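#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Resampled event-context row: `sel` are the grid positions (in units of
// resampled samples, possibly negative for spikes before the window) of the
// selected spikes, sorted ascending. Value at grid point g is the exponential
// decay, in grid units with constant tau_grid, from the most recent selected
// spike at or before g; 0 if none.
static void ec_row(const std::vector<double> &sel, int n_samples,
                   double tau_grid, double *out) {
  const double eps = 1e-9;
  size_t j = 0;
  double last = R_NegInf;
  for (int g = 0; g < n_samples; ++g) {
    while (j < sel.size() && sel[j] <= g + eps) {
      last = sel[j];
      ++j;
    }
    out[g] = R_finite(last) ? std::exp(-((double)g - last) / tau_grid) : 0.0;
  }
}

// 1-D event-context batch: for each event in stream order, the k most recent
// spikes in its own channel ending at (and including) the event define the
// window; events with fewer than k channel spikes of history are skipped.
// [[Rcpp::export]]
List ec_batch_1d_cpp(NumericVector t, IntegerVector ch, int n_channels,
                     int k, int n_samples, double tau_grid) {
  const int n = t.size();
  std::vector<std::vector<double>> hist(n_channels);
  std::vector<std::vector<double>> rows;
  std::vector<int> anchors;
  int skipped = 0;

  for (int i = 0; i < n; ++i) {
    int c = ch[i];
    hist[c].push_back(t[i]);
    int sz = (int)hist[c].size();
    if (sz < k) {
      ++skipped;
      continue;
    }
    double t0 = hist[c][sz - k], t1 = t[i];
    double span = t1 - t0;
    if (span <= 0) {
      ++skipped;
      continue;
    }
    std::vector<double> sel(k);
    for (int j = 0; j < k; ++j)
      sel[j] = (hist[c][sz - k + j] - t0) / span * (n_samples - 1);
    std::vector<double> row(n_samples);
    ec_row(sel, n_samples, tau_grid, row.data());
    rows.push_back(std::move(row));
    anchors.push_back(i + 1);  // 1-based index into the stream
  }

  NumericMatrix out((int)rows.size(), n_samples);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int g = 0; g < n_samples; ++g) out((int)r, g) = rows[r][g];
  return List::create(_["ec"] = out, _["anchor"] = wrap(anchors),
                      _["skipped"] = skipped);
}

// 2-D multi-channel event-context batch. For each event, `scale` adjacent
// channels centred on the event's channel share the anchor channel's window;
// per channel the k causally nearest spikes are selected. Channels outside
// the bank or with fewer than k spikes give zero rows. Events are processed
// grouped by timestamp so same-time spikes in neighbouring channels are
// visible (causal: time <= anchor time). Rows are flattened channel-major
// (lowest channel index first).
// [[Rcpp::export]]
List ec_batch_2d_cpp(NumericVector t, IntegerVector ch, int n_channels,
                     int k, int n_samples, int scale, double tau_grid) {
  const int n = t.size();
  const int half = scale / 2;
  const int d = scale * n_samples;
  std::vector<std::vector<double>> hist(n_channels);
  std::vector<std::vector<double>> rows;
  std::vector<int> anchors;
  int skipped = 0;

  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && t[j] == t[i]) {
      hist[ch[j]].push_back(t[j]);
      ++j;
    }
    for (int e = i; e < j; ++e) {
      int c = ch[e];
      int sz = (int)hist[c].size();
      // the anchor's own spike may not be the channel's latest if several
      // same-time spikes landed in this channel; same-time duplicates per
      // channel are excluded upstream so hist[c] ends at the anchor
      if (sz < k) {
        ++skipped;
        continue;
      }
      double t0 = hist[c][sz - k], t1 = t[e];
      double span = t1 - t0;
      if (span <= 0) {
        ++skipped;
        continue;
      }
      std::vector<double> vec(d, 0.0);
      for (int s = 0; s < scale; ++s) {
        int cc = c - half + s;
        if (cc < 0 || cc >= n_channels) continue;
        const std::vector<double> &hc = hist[cc];
        // spikes at time <= t1; hist holds exactly those (timestamp group
        // already appended), minus any later same-time group entries: none,
        // since groups share one timestamp and all were pushed
        int m = (int)hc.size();
        if (m < k) continue;
        std::vector<double> sel(k);
        for (int q = 0; q < k; ++q)
          sel[q] = (hc[m - k + q] - t0) / span * (n_samples - 1);
        ec_row(sel, n_samples, tau_grid, vec.data() + s * n_samples);
      }
      rows.push_back(std::move(vec));
      anchors.push_back(e + 1);
    }
    i = j;
  }

  NumericMatrix out((int)rows.size(), d);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int g = 0; g < d; ++g) out((int)r, g) = rows[r][g];
  return List::create(_["ec"] = out, _["anchor"] = wrap(anchors),
                      _["skipped"] = skipped);
}

// FEAST training inner loop. Presentations follow `order` (1-based rows of
// `ecs`, one column per epoch, supplied pre-shuffled by the caller so all
// randomness stays in R's RNG). Winner = argmax cosine similarity among
// neurons whose similarity >= own threshold (ties -> lowest index).
// Winner: Vth += dI (clamp 1), W <- (1-eta) W + eta EC.
// No winner: all Vth -= dE (clamp 0).
// [[Rcpp::export]]
List feast_train_cpp(NumericMatrix ecs, NumericMatrix W0, NumericVector Vth0,
                     double dI, double dE, double eta, IntegerMatrix order,
                     double tol) {
  const int n = ecs.nrow(), d = ecs.ncol(), m = W0.nrow();
  const int epochs = order.ncol();
  NumericMatrix W = clone(W0);
  NumericVector Vth = clone(Vth0);
  std::vector<double> wnorm(m);
  for (int i = 0; i < m; ++i) {
    double s = 0;
    for (int j = 0; j < d; ++j) s += W(i, j) * W(i, j);
    wnorm[i] = std::sqrt(s);
  }
  NumericMatrix wins(m, epochs);
  NumericVector mean_dw(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    double acc_dw = 0.0;
    for (int p = 0; p < order.nrow(); ++p) {
      int idx = order(p, ep) - 1;
      double en = 0;
      for (int j = 0; j < d; ++j) en += ecs(idx, j) * ecs(idx, j);
      en = std::sqrt(en);
      if (en <= 0) continue;
      int winner = -1;
      double best = -1.0;
      for (int i = 0; i < m; ++i) {
        double dot = 0;
        for (int j = 0; j < d; ++j) dot += ecs(idx, j) * W(i, j);
        double sim = (wnorm[i] > 0) ? dot / (en * wnorm[i]) : 0.0;
        if (sim >= Vth[i] && sim > best) {
          best = sim;
          winner = i;
        }
      }
      if (winner >= 0) {
        Vth[winner] = std::min(1.0, Vth[winner] + dI);
        double dw = 0.0, s = 0.0;
        for (int j = 0; j < d; ++j) {
          double wn = (1.0 - eta) * W(winner, j) + eta * ecs(idx, j);
          dw += std::fabs(wn - W(winner, j));
          W(winner, j) = wn;
          s += wn * wn;
        }
        wnorm[winner] = std::sqrt(s);
        acc_dw += dw / d;
        wins(winner, ep) += 1;
      } else {
        for (int i = 0; i < m; ++i) Vth[i] = std::max(0.0, Vth[i] - dE);
      }
    }
    mean_dw[ep] = acc_dw / order.nrow();
    if (tol > 0 && mean_dw[ep] < tol && ep + 1 < epochs) {
      // early stop: truncate logs to the epochs actually run
      NumericMatrix w2(m, ep + 1);
      NumericVector d2(ep + 1);
      for (int e2 = 0; e2 <= ep; ++e2) {
        d2[e2] = mean_dw[e2];
        for (int i = 0; i < m; ++i) w2(i, e2) = wins(i, e2);
      }
      return List::create(_["W"] = W, _["Vth"] = Vth, _["wins"] = w2,
                          _["mean_dw"] = d2);
    }
  }
  return List::create(_["W"] = W, _["Vth"] = Vth, _["wins"] = wins,
                      _["mean_dw"] = mean_dw);
}
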