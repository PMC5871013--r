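#include <Rcpp.h>
using namespace Rcpp;

// Wright-Fisher per-site trajectory kernels for the underdominant drift
// E(dq) = s p q (q - 1/2), sampled as q' ~ Binom(2N, q + s p q (q - 1/2))/2N.
// All randomness goes through R's RNG so results are reproducible with
// set.seed() on the R side.

static inline double drift_mu(double q, double s) {
  double mu = q + s * (1.0 - q) * q * (q - 0.5);
  if (mu < 0.0) mu = 0.0;
  if (mu > 1.0) mu = 1.0;
  return mu;
}

// Constant N: new mutation at 1/2N followed to absorption; accumulates the
// time-integrated heterozygosity sum_t p_t q_t per replicate. Returns the
// per-replicate vector when keep is true, otherwise only the moments
// (sum, sum of squares, replicates, fixations).
// [[Rcpp::export]]
List cpp_wf_integrated_pq(double s, int N, double reps, bool keep) {
  const double twoN = 2.0 * N;
  long R = (long) reps;
  double sum = 0.0, sumsq = 0.0;
  long nfix = 0;
  NumericVector out(keep ? R : 0);
  for (long r = 0; r < R; ++r) {
    double x = 1.0;   // copies
    double acc = 0.0;
    while (x > 0.0 && x < twoN) {
      double q = x / twoN;
      acc += q * (1.0 - q);
      x = R::rbinom(twoN, drift_mu(q, s));
    }
    if (x >= twoN) ++nfix;
    sum += acc;
    sumsq += acc * acc;
    if (keep) out[r] = acc;
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq,
                      _["reps"] = (double) R, _["n_fixed"] = (double) nfix,
                      _["acc"] = out);
}

// Piecewise demography: Nt[t] is the diploid size at generation t (1-based
// from R), origin[r] the generation at which replicate r's mutation arises
// (frequency 1/(2 Nt[origin])). Each trajectory is followed to absorption or
// to the present (the last generation of Nt). Returns final frequencies
// (0 lost, 1 fixed, interior segregating) and the integrated heterozygosity.
// [[Rcpp::export]]
List cpp_wf_demography(double s, IntegerVector Nt, IntegerVector origin) {
  const int T = Nt.size();
  const int R = origin.size();
  NumericVector qfin(R), accv(R);
  for (int r = 0; r < R; ++r) {
    int g = origin[r] - 1;   // 0-based
    if (g < 0 || g >= T) stop("origin generation out of range");
    double x = 1.0;
    double twoN = 2.0 * (double) Nt[g];
    double q = x / twoN;
    double acc = q * (1.0 - q);
    for (int t = g + 1; t < T; ++t) {
      double twoNnext = 2.0 * (double) Nt[t];
      x = R::rbinom(twoNnext, drift_mu(q, s));
      q = x / twoNnext;
      if (x <= 0.0) { q = 0.0; break; }
      if (x >= twoNnext) { q = 1.0; break; }
      acc += q * (1.0 - q);
    }
    qfin[r] = q;
    accv[r] = acc;
  }
  return List::create(_["q_final"] = qfin, _["sum_pq"] = accv);
}
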