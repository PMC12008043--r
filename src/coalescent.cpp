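// Coalescent simulation under piecewise-constant population size, with an
// optional two-deme island model. Single genealogy per locus (short GBS
// fragments, no intra-locus recombination); infinite-sites mutation within
// the locus length, with a finite-sites truncation fallback when more
// mutations arise than there are sites.
//
// All randomness comes from R's RNG so set.seed() in R gives full
// reproducibility.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Branch {
  double length;
  std::vector<int> leaves;
};

// Simulate one genealogy for n lineages. deme_of: 0-based deme per lineage
// (all zero = panmictic). epoch_start: ascending, epoch_start[0] = 0,
// generations. ne: epochs x demes matrix of diploid sizes. mig: per-lineage
// per-generation migration probability (two demes). Returns completed
// branches and fills tmrca/tlen.
void sim_genealogy(const std::vector<int> &deme_of0,
                   const NumericVector &epoch_start,
                   const NumericMatrix &ne, double mig,
                   std::vector<Branch> &branches, double &tmrca,
                   double &tlen) {
  int n = deme_of0.size();
  int n_demes = ne.ncol();
  std::vector<int> deme = deme_of0;
  std::vector<double> born(n, 0.0);           // node time of each lineage
  std::vector<std::vector<int> > leaves(n);
  for (int i = 0; i < n; ++i) leaves[i].assign(1, i);
  int k = n;
  double t = 0.0;
  int ep = 0;
  int n_ep = epoch_start.size();
  branches.clear();
  tlen = 0.0;
  while (k > 1) {
    // per-deme lineage counts
    std::vector<int> kd(n_demes, 0);
    for (int i = 0; i < k; ++i) kd[deme[i]]++;
    double rate = 0.0;
    std::vector<double> coal_rate(n_demes, 0.0);
    for (int d = 0; d < n_demes; ++d) {
      coal_rate[d] = kd[d] * (kd[d] - 1) / 2.0 / (2.0 * ne(ep, d));
      rate += coal_rate[d];
    }
    double mig_rate = (n_demes > 1) ? mig * k : 0.0;
    rate += mig_rate;
    double ep_end = (ep + 1 < n_ep) ? epoch_start[ep + 1] : R_PosInf;
    if (rate <= 0) { t = ep_end; ++ep; continue; }
    double w = ::R::exp_rand() / rate;
    if (t + w >= ep_end) { t = ep_end; ++ep; continue; }
    t += w;
    double u = ::unif_rand() * rate;
    if (u < mig_rate) {
      int pick = (int)(::unif_rand() * k); if (pick >= k) pick = k - 1;
      deme[pick] = 1 - deme[pick];          // two demes
      continue;
    }
    u -= mig_rate;
    int d = 0;
    while (d < n_demes && u >= coal_rate[d]) { u -= coal_rate[d]; ++d; }
    if (d >= n_demes) d = n_demes - 1;
    // choose two distinct lineages in deme d
    int a = -1, b = -1;
    {
      int ia = (int)(::unif_rand() * kd[d]); if (ia >= kd[d]) ia = kd[d] - 1;
      int ib = (int)(::unif_rand() * (kd[d] - 1));
      if (ib >= ia) ++ib;
      int seen = 0;
      for (int i = 0; i < k; ++i) {
        if (deme[i] == d) {
          if (seen == ia) a = i;
          if (seen == ib) b = i;
          ++seen;
        }
      }
    }
    if (a > b) std::swap(a, b);
    // record the two merging branches
    Branch ba; ba.length = t - born[a]; ba.leaves = leaves[a];
    Branch bb; bb.length = t - born[b]; bb.leaves = leaves[b];
    tlen += ba.length + bb.length;
    branches.push_back(ba);
    branches.push_back(bb);
    // merge b into a
    leaves[a].insert(leaves[a].end(), leaves[b].begin(), leaves[b].end());
    born[a] = t;
    // remove b by swapping with last
    leaves[b] = leaves[k - 1];
    born[b] = born[k - 1];
    deme[b] = deme[k - 1];
    leaves.pop_back(); born.pop_back(); deme.pop_back();
    --k;
  }
  tmrca = t;
}

}  // namespace

// [[Rcpp::export]]
List sim_loci_cpp(int n_loci, IntegerVector deme_of, NumericVector epoch_start,
                  NumericMatrix ne, double mig, double mu, int locus_len) {
  int n = deme_of.size();
  std::vector<int> d0(deme_of.begin(), deme_of.end());
  std::vector<Branch> branches;
  // collected mutations
  std::vector<int> mut_locus, mut_pos;
  std::vector<std::vector<int> > mut_leaves;
  NumericVector tmrca(n_loci), tlen(n_loci);
  int dropped = 0;
  for (int l = 0; l < n_loci; ++l) {
    double tm, tl;
    sim_genealogy(d0, epoch_start, ne, mig, branches, tm, tl);
    tmrca[l] = tm; tlen[l] = tl;
    int n_mut = (int)::R::rpois(mu * locus_len * tl);
    if (n_mut <= 0) continue;
    int n_eff = n_mut;
    if (n_eff > locus_len) { dropped += n_eff - locus_len; n_eff = locus_len; }
    // distinct positions 1..locus_len without replacement
    std::vector<int> pos_pool(locus_len);
    for (int i = 0; i < locus_len; ++i) pos_pool[i] = i + 1;
    // cumulative branch lengths for proportional sampling
    int nb = branches.size();
    std::vector<double> cum(nb);
    double acc = 0;
    for (int i = 0; i < nb; ++i) { acc += branches[i].length; cum[i] = acc; }
    for (int m = 0; m < n_eff; ++m) {
      int j = (int)(::unif_rand() * (locus_len - m));
      if (j >= locus_len - m) j = locus_len - m - 1;
      int p = pos_pool[j];
      pos_pool[j] = pos_pool[locus_len - m - 1];
      double u = ::unif_rand() * acc;
      int lo = 0, hi = nb - 1;
      while (lo < hi) { int mid = (lo + hi) / 2; if (cum[mid] < u) lo = mid + 1; else hi = mid; }
      mut_locus.push_back(l + 1);
      mut_pos.push_back(p);
      mut_leaves.push_back(branches[lo].leaves);
    }
  }
  int S = mut_locus.size();
  IntegerMatrix hap(n, S);
  for (int s = 0; s < S; ++s)
    for (size_t q = 0; q < mut_leaves[s].size(); ++q)
      hap(mut_leaves[s][q], s) = 1;
  return List::create(_["hap"] = hap,
                      _["locus"] = wrap(mut_locus),
                      _["pos"] = wrap(mut_pos),
                      _["tmrca"] = tmrca, _["tlen"] = tlen,
                      _["n_mut_truncated"] = dropped);
}

// Branch length subtending i leaves (i = 1..n-1), one row per simulated
// genealogy; single panmictic population under piecewise-constant Ne.
// [[Rcpp::export]]
NumericMatrix sfs_branch_cpp(int n_reps, int n, NumericVector epoch_start,
                             NumericVector ne) {
  NumericMatrix out(n_reps, n - 1);
  NumericMatrix nem(ne.size(), 1);
  for (int i = 0; i < ne.size(); ++i) nem(i, 0) = ne[i];
  std::vector<int> d0(n, 0);
  std::vector<Branch> branches;
  for (int r = 0; r < n_reps; ++r) {
    double tm, tl;
    sim_genealogy(d0, epoch_start, nem, 0.0, branches, tm, tl);
    for (size_t b = 0; b < branches.size(); ++b) {
      int i = branches[b].leaves.size();
      if (i >= 1 && i <= n - 1) out(r, i - 1) += branches[b].length;
    }
  }
  return out;
}
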