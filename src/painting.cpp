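#include <Rcpp.h>
using namespace Rcpp;

// Li-Stephens copying HMM for one target haplotype on one chromosome.
//
// Hidden state = donor haplotype d in 1..k. Transition across an inter-site
// gap of g Morgans: stay with prob exp(-ne*g), otherwise jump to d' with
// prob prior[d'] (jump-to-self allowed; chunk boundaries are only counted on
// donor-identity change). Emission: 1-theta on allele match, theta on
// mismatch, 1 when the target allele is missing.
//
// target: length-L integer vector of 0/1, NA_INTEGER = missing.
// donors: k x L integer matrix of 0/1 (no missing donor alleles).
// gaps:   length L-1, inter-site distances in Morgans (> 0).
// prior:  length-k donor prior, sums to 1.
//
// Returns per-donor expected copied sites / Morgans / chunk counts, the
// log-likelihood, EM accumulators (expected mismatch emissions at observed
// sites, expected jump count including jumps-to-self, number of observed
// sites) and optionally the k x L posterior matrix and Viterbi path.
// [[Rcpp::export(name = ".ls_paint_cpp")]]
List ls_paint_cpp(IntegerVector target, IntegerMatrix donors,
                  NumericVector gaps, double ne, double theta,
                  NumericVector prior, bool want_posterior = false,
                  bool want_viterbi = false) {
  const int L = target.size();
  const int k = donors.nrow();
  if (k < 1) stop("at least one donor haplotype is required");
  if (donors.ncol() != L) stop("donor matrix and target length disagree");
  if (gaps.size() != L - 1) stop("need exactly L-1 inter-site distances");
  for (int l = 0; l + 1 < L; ++l)
    if (!R_FINITE(gaps[l]) || gaps[l] < 0)
      stop("non-finite or negative inter-site genetic distance at gap %d",
           l + 1);

  NumericMatrix alpha(k, L);       // scaled forward
  NumericVector logc(L);           // per-site log scaling factors
  NumericVector stay(std::max(L - 1, 0));
  for (int l = 0; l + 1 < L; ++l) stay[l] = std::exp(-ne * gaps[l]);

  auto emis = [&](int l, int d) -> double {
    int t = target[l];
    if (t == NA_INTEGER) return 1.0;
    return (donors(d, l) == t) ? (1.0 - theta) : theta;
  };

  // forward, scaled so each column sums to 1
  {
    double s = 0.0;
    for (int d = 0; d < k; ++d) { alpha(d, 0) = prior[d] * emis(0, d); s += alpha(d, 0); }
    if (s <= 0) stop("zero forward mass at site 1");
    for (int d = 0; d < k; ++d) alpha(d, 0) /= s;
    logc[0] = std::log(s);
  }
  for (int l = 1; l < L; ++l) {
    const double r = stay[l - 1];
    double s = 0.0;
    for (int d = 0; d < k; ++d) {
      double a = r * alpha(d, l - 1) + (1.0 - r) * prior[d];
      a *= emis(l, d);
      alpha(d, l) = a;
      s += a;
    }
    if (s <= 0) stop("zero forward mass at site %d", l + 1);
    for (int d = 0; d < k; ++d) alpha(d, l) /= s;
    logc[l] = std::log(s);
  }
  double loglik = 0.0;
  for (int l = 0; l < L; ++l) loglik += logc[l];

  // site integration weights for expected copied Morgans: each site owns
  // half of each adjacent gap, with the end gaps replicated outward so a
  // uniform map weights every site equally
  NumericVector w(L);
  for (int l = 0; l + 1 < L; ++l) {
    w[l] += gaps[l] / 2.0;
    w[l + 1] += gaps[l] / 2.0;
  }
  if (L > 1) {
    w[0] += gaps[0] / 2.0;
    w[L - 1] += gaps[L - 2] / 2.0;
  }

  // backward (scaled with the forward factors), accumulating posteriors and
  // transition statistics on the fly
  NumericVector beta(k, 1.0), beta_next(k);
  NumericVector exp_sites(k), exp_morgans(k), exp_chunks(k);
  double exp_mismatch = 0.0, exp_jumps = 0.0;
  int n_observed = 0;
  NumericMatrix post;
  if (want_posterior) post = NumericMatrix(k, L);

  // site L-1 (last)
  for (int d = 0; d < k; ++d) {
    double g = alpha(d, L - 1) * beta[d];
    exp_sites[d] += g;
    exp_morgans[d] += g * w[L - 1];
    if (target[L - 1] != NA_INTEGER && donors(d, L - 1) != target[L - 1])
      exp_mismatch += g;
    if (want_posterior) post(d, L - 1) = g;
  }
  if (target[L - 1] != NA_INTEGER) ++n_observed;

  for (int l = L - 2; l >= 0; --l) {
    const double r = stay[l];
    const double cinv = std::exp(-logc[l + 1]);
    // jump mass shared by all origins: sum_d' prior[d'] e_{l+1}(d') b_{l+1}(d')
    double jump_sum = 0.0;
    for (int d = 0; d < k; ++d) jump_sum += prior[d] * emis(l + 1, d) * beta[d];
    for (int d = 0; d < k; ++d) {
      beta_next[d] = cinv * (r * emis(l + 1, d) * beta[d] + (1.0 - r) * jump_sum);
      // switch-in posterior: P(d_{l+1} = d, d_l != d)
      double sw = (1.0 - r) * prior[d] * (1.0 - alpha(d, l)) *
                  emis(l + 1, d) * beta[d] * cinv;
      exp_chunks[d] += sw;
    }
    exp_jumps += (1.0 - r) * jump_sum * cinv;  // includes jumps-to-self
    for (int d = 0; d < k; ++d) beta[d] = beta_next[d];
    for (int d = 0; d < k; ++d) {
      double g = alpha(d, l) * beta[d];
      exp_sites[d] += g;
      exp_morgans[d] += g * w[l];
      if (target[l] != NA_INTEGER && donors(d, l) != target[l])
        exp_mismatch += g;
      if (want_posterior) post(d, l) = g;
    }
    if (target[l] != NA_INTEGER) ++n_observed;
  }
  // chunk count = initial occupancy + expected switch-ins
  for (int d = 0; d < k; ++d) exp_chunks[d] += alpha(d, 0) * beta[d];

  List out = List::create(
      _["expected_sites"] = exp_sites, _["expected_morgans"] = exp_morgans,
      _["expected_chunks"] = exp_chunks, _["log_likelihood"] = loglik,
      _["expected_mismatch"] = exp_mismatch, _["expected_jumps"] = exp_jumps,
      _["n_observed"] = n_observed);
  if (want_posterior) out["posterior"] = post;

  if (want_viterbi) {
    // log-space Viterbi under the same structured transition
    NumericMatrix v(k, L);
    IntegerMatrix from(k, L);
    for (int d = 0; d < k; ++d)
      v(d, 0) = std::log(prior[d]) + std::log(emis(0, d));
    for (int l = 1; l < L; ++l) {
      const double r = stay[l - 1];
      int argbest = 0;
      for (int d = 1; d < k; ++d) if (v(d, l - 1) > v(argbest, l - 1)) argbest = d;
      const double best = v(argbest, l - 1);
      for (int d = 0; d < k; ++d) {
        double stay_score = v(d, l - 1) + std::log(r + (1.0 - r) * prior[d]);
        double jump_score = best + std::log((1.0 - r) * prior[d]);
        if (stay_score >= jump_score) {
          v(d, l) = stay_score + std::log(emis(l, d));
          from(d, l) = d;
        } else {
          v(d, l) = jump_score + std::log(emis(l, d));
          from(d, l) = argbest;
        }
      }
    }
    IntegerVector path(L);
    int cur = 0;
    for (int d = 1; d < k; ++d) if (v(d, L - 1) > v(cur, L - 1)) cur = d;
    for (int l = L - 1; l >= 0; --l) { path[l] = cur + 1; cur = from(cur, l); }
    out["viterbi"] = path;
  }
  return out;
}
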