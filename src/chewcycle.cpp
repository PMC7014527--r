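#include <Rcpp.h>
using namespace Rcpp;

// Incremental window-index series for chewing-cycle onset detection.
// For each window start s (0-based), value =
//   #{first half-window samples < theta_c} + #{second half-window samples > theta_c}.
// Updated in O(1) per one-sample step; must be bit-identical to a brute-force
// per-window recount.
// [[Rcpp::export]]
IntegerVector index_series_cpp(NumericVector x, int w, double theta_c) {
  int n = x.size();
  int half = w / 2;
  int npos = n - w + 1;
  IntegerVector out(npos);
  int idx = 0;
  for (int i = 0; i < half; ++i)
    if (x[i] < theta_c) ++idx;
  for (int i = half; i < w; ++i)
    if (x[i] > theta_c) ++idx;
  out[0] = idx;
  for (int s = 1; s < npos; ++s) {
    // window moves to [s, s+w-1]; halves [s, s+half-1] and [s+half, s+w-1]
    if (x[s - 1] < theta_c) --idx;          // left sample leaves first half
    if (x[s + half - 1] < theta_c) ++idx;   // boundary sample joins first half
    if (x[s + half - 1] > theta_c) --idx;   // ... and leaves second half
    if (x[s + w - 1] > theta_c) ++idx;      // new sample joins second half
    out[s] = idx;
  }
  return out;
}

// Peak scan over the index series: accept strict local maxima I[i] < I[i+1],
// I[i+1] > I[i+2] with I[i+1] > peak_thr, then skip `skip` positions
// (refractory interval). Returns 0-based positions of accepted peaks in I.
// [[Rcpp::export]]
IntegerVector onset_scan_cpp(IntegerVector I, double peak_thr, int skip) {
  std::vector<int> out;
  int n = I.size();
  for (int i = 0; i + 2 < n; ++i) {
    if (I[i] < I[i + 1] && I[i + 1] > I[i + 2] &&
        (double)I[i + 1] > peak_thr) {
      out.push_back(i + 1);
      i += skip;
    }
  }
  return wrap(out);
}
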