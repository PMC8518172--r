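#include <Rcpp.h>
using namespace Rcpp;

// EM for fractional read assignment over equivalence classes.
//
// An equivalence class (EC) is a set of transcripts compatible with the
// same observed block; because the covered block is observed, the posterior
// origin probability within an EC is proportional to the molar abundance
// theta_t alone (the transcript-length terms cancel against the uniform
// position density). The M-step is the classic theta_t proportional to
// x_t / l_t update; iteration stops when the max absolute change in theta
// falls below tol or after max_iter iterations. Returns the final expected
// counts x (summing exactly to the number of reads in the ECs).
//
// members: 0-based transcript indices, concatenated over ECs
// ec_start: length n_ec + 1, offsets into members
// ec_count: reads per EC
// len: transcript lengths
// [[Rcpp::export]]
NumericVector em_assign(IntegerVector members, IntegerVector ec_start,
                        NumericVector ec_count, NumericVector len,
                        int n_tx, int max_iter, double tol) {
  int n_ec = ec_count.size();
  NumericVector theta(n_tx, 1.0 / n_tx);
  NumericVector theta_new(n_tx);
  NumericVector x(n_tx);

  for (int it = 0; it < max_iter; ++it) {
    std::fill(x.begin(), x.end(), 0.0);
    for (int e = 0; e < n_ec; ++e) {
      double denom = 0.0;
      for (int k = ec_start[e]; k < ec_start[e + 1]; ++k)
        denom += theta[members[k]];
      if (denom <= 0.0) {
        // all members at zero abundance: revive with an even split
        int m = ec_start[e + 1] - ec_start[e];
        for (int k = ec_start[e]; k < ec_start[e + 1]; ++k)
          x[members[k]] += ec_count[e] / m;
      } else {
        for (int k = ec_start[e]; k < ec_start[e + 1]; ++k)
          x[members[k]] += ec_count[e] * theta[members[k]] / denom;
      }
    }
    double tot = 0.0;
    for (int t = 0; t < n_tx; ++t) { theta_new[t] = x[t] / len[t]; tot += theta_new[t]; }
    double delta = 0.0;
    for (int t = 0; t < n_tx; ++t) {
      theta_new[t] /= tot;
      double d = std::fabs(theta_new[t] - theta[t]);
      if (d > delta) delta = d;
      theta[t] = theta_new[t];
    }
    if (delta < tol) break;
  }

  // final E-step with converged abundances
  std::fill(x.begin(), x.end(), 0.0);
  for (int e = 0; e < n_ec; ++e) {
    double denom = 0.0;
    for (int k = ec_start[e]; k < ec_start[e + 1]; ++k)
      denom += theta[members[k]];
    if (denom <= 0.0) {
      int m = ec_start[e + 1] - ec_start[e];
      for (int k = ec_start[e]; k < ec_start[e + 1]; ++k)
        x[members[k]] += ec_count[e] / m;
    } else {
      for (int k = ec_start[e]; k < ec_start[e + 1]; ++k)
        x[members[k]] += ec_count[e] * theta[members[k]] / denom;
    }
  }
  return x;
}
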