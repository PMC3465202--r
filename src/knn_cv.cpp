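#include <Rcpp.h>
using namespace Rcpp;

// Pooled k-fold CV accuracy for Euclidean k-NN, driven by a precomputed
// m x m squared-distance matrix. Each sample is predicted from the samples
// outside its fold. Vote ties are broken by the class of the nearest
// neighbor among the tied classes; neighbor distance ties by sample index
// (matching order(d2, seq_along(d2)) on the R side).
// [[Rcpp::export]]
double knn_cv_acc_cpp(NumericMatrix d2, IntegerVector labels0,
                      IntegerVector fold, int k, int nlevels) {
  const int m = d2.nrow();
  std::vector<int> nb(k);
  std::vector<double> nbd(k);
  std::vector<int> votes(nlevels);
  int correct = 0;
  for (int i = 0; i < m; ++i) {
    int found = 0;
    // insertion into a running top-k (k is small: 5 by default)
    for (int j = 0; j < m; ++j) {
      if (fold[j] == fold[i]) continue;
      double d = d2(i, j);
      if (found < k) {
        int pos = found++;
        while (pos > 0 && nbd[pos - 1] > d) {
          nbd[pos] = nbd[pos - 1]; nb[pos] = nb[pos - 1]; --pos;
        }
        nbd[pos] = d; nb[pos] = j;
      } else if (d < nbd[k - 1]) {
        int pos = k - 1;
        while (pos > 0 && nbd[pos - 1] > d) {
          nbd[pos] = nbd[pos - 1]; nb[pos] = nb[pos - 1]; --pos;
        }
        nbd[pos] = d; nb[pos] = j;
      }
      // equal distances: earlier j was inserted first and is never displaced
      // by a later equal one, matching the stable R ordering
    }
    if (found == 0) continue;
    std::fill(votes.begin(), votes.end(), 0);
    int kk = std::min(k, found);
    for (int t = 0; t < kk; ++t) votes[labels0[nb[t]]]++;
    int vmax = *std::max_element(votes.begin(), votes.end());
    int ntied = 0, pred = -1;
    for (int c = 0; c < nlevels; ++c) if (votes[c] == vmax) ++ntied;
    if (ntied == 1) {
      for (int c = 0; c < nlevels; ++c) if (votes[c] == vmax) { pred = c; break; }
    } else {
      for (int t = 0; t < kk; ++t) {
        int c = labels0[nb[t]];
        if (votes[c] == vmax) { pred = c; break; }
      }
    }
    if (pred == labels0[i]) ++correct;
  }
  return static_cast<double>(correct) / m;
}
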