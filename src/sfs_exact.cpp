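// Exact expected site-frequency spectrum under piecewise-constant Ne.
//
// The number of ancestral lineages of an n-sample is a pure-death Markov
// chain (k -> k-1 at rate C(k,2)/(2N(t)) per generation). Per epoch of
// constant N the chain is homogeneous in scaled time tau = t/(2N); state
// probabilities and occupation times are propagated by uniformization
// (Poisson-weighted powers of the substochastic jump matrix), which is
// numerically stable at any sample size, with adaptive truncation of the
// active state range and an exact absorbing-horizon formula for long
// epochs. Expected branch length subtending i of n leaves then follows
// from E[time with k lineages] and the classical combinatorial weight
// P(i | k) = C(n-i-1, k-2) / C(n-1, k-1).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// scaled-time occupation integral to absorption from state vector p
// (states k=2..n stored at index k-2); q_k = k(k-1)/2
void occupy_to_absorption(const std::vector<double> &p, int n,
                          std::vector<double> &tau) {
  int m = n - 1;
  std::vector<double> t(m, 0.0);
  for (int k = n; k >= 2; --k) {
    double qk = k * (k - 1) / 2.0;
    double from_above = (k < n) ? (k + 1) * k / 2.0 * t[k + 1 - 2] : 0.0;
    t[k - 2] = (p[k - 2] + from_above) / qk;
  }
  for (int i = 0; i < m; ++i) tau[i] += t[i];
}

// propagate p over scaled duration delta; accumulate occupation times into
// tau (scaled units). kmax_io tracks the largest state with non-negligible
// mass.
void propagate_epoch(std::vector<double> &p, int n, double delta,
                     std::vector<double> &tau, int &kmax_io) {
  const double tiny = 1e-16;
  double remaining = delta;
  while (remaining > 0) {
    // shrink active range
    int kmax = 2;
    for (int k = n; k >= 2; --k)
      if (p[k - 2] > tiny) { kmax = k; break; }
    double mass = 0;
    for (int k = 2; k <= kmax; ++k) mass += p[k - 2];
    if (mass < 1e-15) { remaining = 0; break; }
    double lambda = kmax * (kmax - 1) / 2.0;
    double chunk = std::min(remaining, std::max(1.0, 8.0 / lambda));
    double ld = lambda * chunk;
    // uniformization over this chunk
    int m_hi = (int)std::ceil(ld + 10.0 * std::sqrt(ld + 1.0)) + 10;
    std::vector<double> v(p.begin(), p.begin() + (kmax - 1));
    // Poisson weights computed in log space around the mode
    double U = 1.0;  // upper tail P(Pois > m-1), starts at 1 for m=0
    std::vector<double> pend(kmax - 1, 0.0);
    for (int m = 0; m <= m_hi; ++m) {
      double logd = -ld + m * std::log(ld > 0 ? ld : 1e-300) - std::lgamma(m + 1.0);
      double d = (ld > 0) ? std::exp(logd) : (m == 0 ? 1.0 : 0.0);
      // occupation: (1/lambda) * P(Pois >= m+1) ... accumulated as U after
      // subtracting d below; but integral weight is P(Pois > m)/lambda
      double w_int = (U - d) / lambda;  // P(Pois > m) = U - d
      for (int k = 2; k <= kmax; ++k) {
        tau[k - 2] += w_int * v[k - 2];
        pend[k - 2] += d * v[k - 2];
      }
      U -= d;
      if (U < 1e-14 && m > ld) break;
      // v <- P v, P = I + Q/lambda (death chain)
      std::vector<double> nv(kmax - 1, 0.0);
      for (int k = 2; k <= kmax; ++k) {
        double qk = k * (k - 1) / 2.0;
        nv[k - 2] += (1.0 - qk / lambda) * v[k - 2];
        if (k > 2) nv[k - 3] += (qk / lambda) * v[k - 2];
      }
      v.swap(nv);
    }
    for (int k = 2; k <= kmax; ++k) p[k - 2] = pend[k - 2];
    for (int k = kmax + 1; k <= n; ++k) p[k - 2] = 0.0;
    remaining -= chunk;
    kmax_io = kmax;
  }
}

}  // namespace

// Expected *unfolded* SFS counts E[xi_i], i = 1..n-1, for mu per site per
// generation over L sites; epoch_start in generations (ascending, first 0),
// ne diploid size per epoch (last epoch extends to infinity).
// [[Rcpp::export]]
NumericVector expected_sfs_exact_cpp(int n, NumericVector epoch_start,
                                     NumericVector ne, double mu, double L) {
  int n_ep = ne.size();
  std::vector<double> p(n - 1, 0.0);
  p[n - 2] = 1.0;
  std::vector<double> T(n - 1, 0.0);  // E[time with k lineages], generations
  int kmax = n;
  for (int j = 0; j < n_ep; ++j) {
    double N = ne[j];
    bool last = (j == n_ep - 1);
    double len = last ? R_PosInf : (epoch_start[j + 1] - epoch_start[j]);
    double delta = len / (2.0 * N);
    std::vector<double> tau(n - 1, 0.0);
    if (last || delta > 40.0) {
      if (!last && delta > 40.0) {
        // negligible mass survives 40 scaled units; treat as absorbing
        occupy_to_absorption(p, n, tau);
        for (int i = 0; i < n - 1; ++i) { T[i] += 2.0 * N * tau[i]; p[i] = 0.0; }
        break;
      }
      occupy_to_absorption(p, n, tau);
      for (int i = 0; i < n - 1; ++i) { T[i] += 2.0 * N * tau[i]; p[i] = 0.0; }
    } else {
      propagate_epoch(p, n, delta, tau, kmax);
      for (int i = 0; i < n - 1; ++i) T[i] += 2.0 * N * tau[i];
    }
  }
  // combinatorial weights: E[xi_i] = mu L sum_k k T_k P(i | k),
  // with P(i|k) = C(n-i-1, k-2)/C(n-1, k-1) via a log-factorial table
  std::vector<double> lf(n + 1, 0.0);
  for (int i = 2; i <= n; ++i) lf[i] = lf[i - 1] + std::log((double)i);
  NumericVector xi(n - 1);
  for (int k = 2; k <= n; ++k) {
    double kT = k * T[k - 2];
    if (kT <= 0) continue;
    double lden = lf[n - 1] - lf[k - 1] - lf[n - k];
    for (int i = 1; i <= n - k + 1; ++i) {
      double lnum = lf[n - i - 1] - lf[k - 2] - lf[n - i - k + 1];
      xi[i - 1] += mu * L * kT * std::exp(lnum - lden);
    }
  }
  return xi;
}
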