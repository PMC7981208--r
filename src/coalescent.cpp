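#include <Rcpp.h>
using namespace Rcpp;

// Structured coalescent for two demes with piecewise-constant relative sizes
// and backward migration, merging into a single ancestral deme at the oldest
// epoch boundary (the divergence time).
//
// Time unit: 2*N_ref generations. In this unit a pair of lineages in a deme
// of relative size N coalesces at rate 1/N, and a lineage currently in deme 1
// jumps (backward in time) into deme 2 at rate m12 (the usual diffusion-scale
// convention, rates in units of 2*N_ref).
//
// `epochs` has one row per epoch ordered from the present backwards with
// columns (t_end, N1, N2, m12, m21); the last row's t_end is the divergence
// time. Older than that, all lineages sit in one deme of size n_anc.
//
// A lineage's (d1, d2) descendant configuration changes only at coalescence,
// so branch time subtending (i, j) is accumulated lazily from per-lineage
// birth times when the lineage dies (O(1) per event instead of O(k)).

struct Lineage {
  int d1; // descendants sampled from deme 1
  int d2; // descendants sampled from deme 2
  double born;
};

// per-deme index lists give O(1) lineage selection; a lineage's (d1, d2)
// configuration changes only at coalescence, so branch time is accumulated
// from per-lineage birth times when the lineage is closed out
static void sim_one(int n1, int n2, const NumericMatrix &epochs, double n_anc,
                    NumericMatrix &T) {
  const int nep = epochs.nrow();
  std::vector<Lineage> lin(n1 + n2);
  std::vector<int> deme[2];
  deme[0].reserve(n1 + n2);
  deme[1].reserve(n1 + n2);
  for (int i = 0; i < n1; ++i) {
    lin[i] = {1, 0, 0.0};
    deme[0].push_back(i);
  }
  for (int i = 0; i < n2; ++i) {
    lin[n1 + i] = {0, 1, 0.0};
    deme[1].push_back(n1 + i);
  }
  int alive = n1 + n2;

  double t = 0.0;
  int ep = 0;

  while (alive > 1) {
    double N1, N2, m12, m21;
    if (ep < nep) {
      N1 = epochs(ep, 1); N2 = epochs(ep, 2);
      m12 = epochs(ep, 3); m21 = epochs(ep, 4);
    } else {
      N1 = n_anc; N2 = n_anc; m12 = 0.0; m21 = 0.0;
    }
    const double k1 = deme[0].size(), k2 = deme[1].size();
    const double rc1 = 0.5 * k1 * (k1 - 1) / N1;
    const double rc2 = 0.5 * k2 * (k2 - 1) / N2;
    const double rm1 = (ep < nep) ? k1 * m12 : 0.0;
    const double rm2 = (ep < nep) ? k2 * m21 : 0.0;
    const double tot = rc1 + rc2 + rm1 + rm2;

    const double bound = (ep < nep) ? epochs(ep, 0) : R_PosInf;
    const double dt = (tot > 0.0) ? R::exp_rand() / tot : R_PosInf;

    if (t + dt >= bound) {
      t = bound;
      ++ep;
      if (ep == nep && !deme[1].empty()) { // divergence: merge demes
        deme[0].insert(deme[0].end(), deme[1].begin(), deme[1].end());
        deme[1].clear();
      }
      continue;
    }
    t += dt;

    double u = R::unif_rand() * tot;
    if (u < rc1 + rc2) {
      const int d = (u < rc1) ? 0 : 1;
      std::vector<int> &idx = deme[d];
      const int kd = idx.size();
      int a = (int)(R::unif_rand() * kd);
      int b = (int)(R::unif_rand() * (kd - 1));
      if (b >= a) ++b;
      if (a >= kd) a = kd - 1; // guard unif_rand() == 1
      if (b >= kd) b = kd - 1;
      const int ia = idx[a], ib = idx[b];
      // close out both children, open the parent in ia's slot
      T(lin[ia].d1, lin[ia].d2) += t - lin[ia].born;
      T(lin[ib].d1, lin[ib].d2) += t - lin[ib].born;
      lin[ia].d1 += lin[ib].d1;
      lin[ia].d2 += lin[ib].d2;
      lin[ia].born = t;
      idx[b] = idx.back();
      idx.pop_back();
      --alive;
    } else {
      const int d = (u < rc1 + rc2 + rm1) ? 0 : 1;
      std::vector<int> &idx = deme[d];
      const int kd = idx.size();
      int a = (int)(R::unif_rand() * kd);
      if (a >= kd) a = kd - 1;
      const int moved = idx[a];
      idx[a] = idx.back();
      idx.pop_back();
      deme[1 - d].push_back(moved);
    }
  }
  // the root lineage subtends every sample (the masked corner); skip it
}

// [[Rcpp::export(name = ".coal_branch_lengths")]]
NumericMatrix coal_branch_lengths(int n1, int n2, NumericMatrix epochs,
                                  double n_anc, int nreps) {
  NumericMatrix T(n1 + 1, n2 + 1);
  for (int r = 0; r < nreps; ++r) sim_one(n1, n2, epochs, n_anc, T);
  // per-genealogy average of the expected branch time subtending (i, j)
  for (int i = 0; i < T.nrow(); ++i)
    for (int j = 0; j < T.ncol(); ++j) T(i, j) /= nreps;
  return T;
}

// One segregating site per retained locus. In the infinitesimal-mutation
// limit a locus is retained (carries a SNP) with probability proportional
// to its genealogy's total branch length, and the site falls on a branch
// with probability proportional to that branch's length; the cell law is
// therefore E[T_c] / E[T_tot] (length-biased genealogy sampling), matching
// the expectation used by the composite likelihood. Genealogies are
// length-bias-selected by rejection against an adaptive envelope.
// Returns an (n1+1) x (n2+1) unfolded count matrix.
// [[Rcpp::export(name = ".coal_sample_jsfs")]]
IntegerMatrix coal_sample_jsfs(int n1, int n2, NumericMatrix epochs,
                               double n_anc, int nloci) {
  IntegerMatrix counts(n1 + 1, n2 + 1);
  NumericMatrix T(n1 + 1, n2 + 1);

  // envelope for the rejection step: generous multiple of the largest
  // total length seen in a pilot sample (lengths beyond it are accepted
  // outright; the envelope only affects efficiency)
  double tmax = 0.0;
  for (int p = 0; p < 200; ++p) {
    std::fill(T.begin(), T.end(), 0.0);
    sim_one(n1, n2, epochs, n_anc, T);
    double tot = std::accumulate(T.begin(), T.end(), 0.0);
    if (tot > tmax) tmax = tot;
  }
  const double env = 2.0 * tmax;

  for (int l = 0; l < nloci; ++l) {
    double tot;
    for (;;) {
      std::fill(T.begin(), T.end(), 0.0);
      sim_one(n1, n2, epochs, n_anc, T);
      tot = std::accumulate(T.begin(), T.end(), 0.0);
      if (R::unif_rand() * env < tot) break;
    }
    double u = R::unif_rand() * tot;
    double acc = 0.0;
    int pick = T.size() - 1;
    for (int c = 0; c < T.size(); ++c) {
      acc += T[c];
      if (u < acc) { pick = c; break; }
    }
    ++counts[pick];
  }
  return counts;
}
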