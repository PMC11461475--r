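// Surrogate distributions for phase-amplitude coupling metrics.
//
// Each surrogate rotates the amplitude series at a cut point (cut-and-swap:
// the two segments exchange order, i.e. a circular shift), which preserves
// the amplitude marginal exactly while destroying its alignment with the
// phase series. Both metrics are recomputed against the unchanged phases.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double mi_from_bins(const arma::vec& binsum, const arma::ivec& bincnt,
                           int n_bins) {
  arma::vec m(n_bins, arma::fill::zeros);
  for (int k = 0; k < n_bins; ++k)
    if (bincnt[k] > 0) m[k] = binsum[k] / bincnt[k];
  double tot = arma::accu(m);
  if (tot <= 0) return NA_REAL;
  double kl = 0.0;
  for (int k = 0; k < n_bins; ++k) {
    double p = m[k] / tot;
    if (p > 0) kl += p * std::log(p);
  }
  return (kl + std::log((double)n_bins)) / std::log((double)n_bins);
}

// [[Rcpp::export]]
NumericMatrix pac_surrogates_cpp(NumericVector A_, NumericVector cosphi_,
                                 NumericVector sinphi_, IntegerVector bin_,
                                 int n_bins, IntegerVector cuts) {
  int T = A_.size();
  int n = cuts.size();
  arma::vec A(A_.begin(), T, false);
  arma::vec cp(cosphi_.begin(), T, false), sp(sinphi_.begin(), T, false);

  arma::ivec bincnt(n_bins, arma::fill::zeros);
  for (int t = 0; t < T; ++t) bincnt[bin_[t]]++;

  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    int cut = cuts[i];  // surrogate amplitude: A[(cut+1):T], A[1:cut] (1-based)
    arma::vec binsum(n_bins, arma::fill::zeros);
    double re = 0.0, im = 0.0;
    for (int t = 0; t < T; ++t) {
      double a = A[(t + cut) % T];
      binsum[bin_[t]] += a;
      re += a * cp[t];
      im += a * sp[t];
    }
    out(i, 0) = mi_from_bins(binsum, bincnt, n_bins);
    out(i, 1) = std::sqrt(re * re + im * im) / T;
  }
  return out;
}
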