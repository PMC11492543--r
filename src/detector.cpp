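#include <Rcpp.h>
using namespace Rcpp;

// Windowed two-means transition weights for fixation detection.
//
// For every window of `win` samples (advanced by `step`), the valid samples
// are split into two clusters by Lloyd iterations initialised from the
// temporal halves of the window. Each sample where the cluster label switches
// receives weight 1/(number of switches in that window); the returned
// per-sample weight is the mean over all windows covering the sample.
// Saccadic samples accumulate large weights because every window that spans
// the displacement localises its single cluster switch there; fixational
// noise spreads its many switches thinly.
//
// [[Rcpp::export]]
NumericVector transition_weights_cpp(NumericVector x, NumericVector y,
                                     LogicalVector ok, int win, int step) {
  const int n = x.size();
  if (win < 4) stop("window must span at least 4 samples");
  if (step < 1) stop("step must be positive");
  std::vector<double> wsum(n, 0.0);
  std::vector<int> cover(n, 0);
  std::vector<int> idx;
  idx.reserve(win);
  std::vector<int> lab(win);

  std::vector<int> starts;
  for (int s = 0; s + win <= n; s += step) starts.push_back(s);
  // always include a final window flush with the end so trailing samples
  // are covered even when (n - win) is not a multiple of step
  if (n >= win && (starts.empty() || starts.back() != n - win))
    starts.push_back(n - win);

  for (size_t si = 0; si < starts.size(); ++si) {
    const int s = starts[si];
    idx.clear();
    for (int i = s; i < s + win; ++i)
      if (ok[i] && R_finite(x[i]) && R_finite(y[i])) idx.push_back(i);
    const int m = (int)idx.size();
    if (m < 4) continue;

    const int h = m / 2;
    double c1x = 0, c1y = 0, c2x = 0, c2y = 0;
    for (int j = 0; j < h; ++j) { c1x += x[idx[j]]; c1y += y[idx[j]]; }
    for (int j = h; j < m; ++j) { c2x += x[idx[j]]; c2y += y[idx[j]]; }
    c1x /= h; c1y /= h; c2x /= (m - h); c2y /= (m - h);

    for (int it = 0; it < 25; ++it) {
      bool changed = false;
      for (int j = 0; j < m; ++j) {
        const double dx1 = x[idx[j]] - c1x, dy1 = y[idx[j]] - c1y;
        const double dx2 = x[idx[j]] - c2x, dy2 = y[idx[j]] - c2y;
        const int l = (dx1 * dx1 + dy1 * dy1 <= dx2 * dx2 + dy2 * dy2) ? 0 : 1;
        if (it == 0 || l != lab[j]) { changed = true; lab[j] = l; }
      }
      if (!changed && it > 0) break;
      double s1x = 0, s1y = 0, s2x = 0, s2y = 0;
      int n1 = 0, n2 = 0;
      for (int j = 0; j < m; ++j) {
        if (lab[j] == 0) { s1x += x[idx[j]]; s1y += y[idx[j]]; ++n1; }
        else            { s2x += x[idx[j]]; s2y += y[idx[j]]; ++n2; }
      }
      if (n1 == 0 || n2 == 0) break;  // degenerate (e.g. constant trace)
      c1x = s1x / n1; c1y = s1y / n1; c2x = s2x / n2; c2y = s2y / n2;
    }

    int ntrans = 0;
    for (int j = 1; j < m; ++j) if (lab[j] != lab[j - 1]) ++ntrans;
    for (int j = 0; j < m; ++j) cover[idx[j]]++;
    if (ntrans > 0) {
      const double w = 1.0 / ntrans;
      for (int j = 1; j < m; ++j)
        if (lab[j] != lab[j - 1]) wsum[idx[j]] += w;
    }
  }

  NumericVector out(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (cover[i] > 0) out[i] = wsum[i] / cover[i];
  return out;
}
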