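#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Multi-population single-mutation Kingman coalescent in ms time units
// (time in units of 4*N0 generations; k lineages in a population coalesce
// at total rate k*(k-1)).  Populations merge (backward in time) at the
// supplied join events.  Exactly one mutation is placed per locus on a
// branch chosen with probability proportional to its length, mirroring
// ms's -s 1 behaviour.  Uses R's RNG so set.seed() governs determinism.

namespace {

struct Lineage {
  uint64_t m0, m1;  // descendant-leaf bitmask (supports up to 128 leaves)
  double birth;
};

struct Branch {
  uint64_t m0, m1;
  double len;
};

// Simulate one genealogy; fill `derived` (size nleaf) with 0/1 and return
// total tree length.
double sim_locus(const std::vector<int> &sizes,
                 const std::vector<double> &jt,
                 const std::vector<int> &jfrom,
                 const std::vector<int> &jto,
                 std::vector<int> &derived) {
  const int npop = (int)sizes.size();
  int nleaf = 0;
  for (int s : sizes) nleaf += s;

  std::vector<std::vector<Lineage> > pools(npop);
  int leaf = 0;
  for (int p = 0; p < npop; ++p) {
    pools[p].reserve(sizes[p] * 2);
    for (int i = 0; i < sizes[p]; ++i, ++leaf) {
      Lineage L;
      L.m0 = (leaf < 64) ? (1ULL << leaf) : 0ULL;
      L.m1 = (leaf >= 64) ? (1ULL << (leaf - 64)) : 0ULL;
      L.birth = 0.0;
      pools[p].push_back(L);
    }
  }

  std::vector<Branch> branches;
  branches.reserve(2 * nleaf);
  double t = 0.0;
  size_t je = 0;
  int ntot = nleaf;

  while (ntot > 1) {
    double rate = 0.0;
    for (int p = 0; p < npop; ++p) {
      double k = (double)pools[p].size();
      rate += k * (k - 1.0);
    }
    double tnext = (je < jt.size()) ? jt[je] : R_PosInf;
    if (rate <= 0.0) {
      if (!R_FINITE(tnext))
        stop("coalescent cannot complete: isolated lineages with no remaining join event");
      t = tnext;
      pools[jto[je]].insert(pools[jto[je]].end(), pools[jfrom[je]].begin(),
                            pools[jfrom[je]].end());
      pools[jfrom[je]].clear();
      ++je;
      continue;
    }
    double dt = R::exp_rand() / rate;
    if (t + dt >= tnext) {
      t = tnext;
      pools[jto[je]].insert(pools[jto[je]].end(), pools[jfrom[je]].begin(),
                            pools[jfrom[je]].end());
      pools[jfrom[je]].clear();
      ++je;
      continue;
    }
    t += dt;
    // choose population proportional to k*(k-1)
    double u = unif_rand() * rate;
    int pp = 0;
    for (; pp < npop; ++pp) {
      double k = (double)pools[pp].size();
      double r = k * (k - 1.0);
      if (u < r) break;
      u -= r;
    }
    if (pp == npop) pp = npop - 1;  // numerical guard
    int k = (int)pools[pp].size();
    int i = (int)(unif_rand() * k);
    if (i >= k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1));
    if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    Lineage &A = pools[pp][i];
    Lineage &B = pools[pp][j];
    Branch ba; ba.m0 = A.m0; ba.m1 = A.m1; ba.len = t - A.birth;
    Branch bb; bb.m0 = B.m0; bb.m1 = B.m1; bb.len = t - B.birth;
    branches.push_back(ba);
    branches.push_back(bb);
    Lineage P;
    P.m0 = A.m0 | B.m0;
    P.m1 = A.m1 | B.m1;
    P.birth = t;
    // replace i with parent, remove j (order within pool is irrelevant)
    pools[pp][i] = P;
    pools[pp][j] = pools[pp].back();
    pools[pp].pop_back();
    --ntot;
  }

  double total = 0.0;
  for (const Branch &b : branches) total += b.len;
  double u = unif_rand() * total;
  const Branch *hit = &branches.back();
  for (const Branch &b : branches) {
    if (u < b.len) { hit = &b; break; }
    u -= b.len;
  }
  for (int l = 0; l < nleaf; ++l) {
    bool d = (l < 64) ? ((hit->m0 >> l) & 1ULL) : ((hit->m1 >> (l - 64)) & 1ULL);
    derived[l] = d ? 1 : 0;
  }
  return total;
}

void check_args(const std::vector<int> &sizes, const std::vector<double> &jt,
                const std::vector<int> &jfrom, const std::vector<int> &jto) {
  int nleaf = 0;
  for (int s : sizes) {
    if (s < 0) stop("negative sample size");
    nleaf += s;
  }
  if (nleaf < 2) stop("need at least 2 sampled chromosomes");
  if (nleaf > 128) stop("engine supports at most 128 sampled chromosomes");
  if (jt.size() != jfrom.size() || jt.size() != jto.size())
    stop("join event vectors must have equal length");
  for (size_t e = 0; e + 1 < jt.size(); ++e)
    if (jt[e] > jt[e + 1]) stop("join times must be non-decreasing");
  for (size_t e = 0; e < jt.size(); ++e) {
    if (jt[e] < 0) stop("join times must be non-negative");
    if (jfrom[e] < 0 || jfrom[e] >= (int)sizes.size() || jto[e] < 0 ||
        jto[e] >= (int)sizes.size() || jfrom[e] == jto[e])
      stop("invalid join event populations");
  }
}

}  // namespace

// [[Rcpp::export(name = ".sim_split_counts")]]
NumericMatrix sim_split_counts(IntegerVector sizes, NumericVector join_t,
                               IntegerVector join_from, IntegerVector join_to,
                               int n_loci) {
  std::vector<int> sz = as<std::vector<int> >(sizes);
  std::vector<double> jt = as<std::vector<double> >(join_t);
  std::vector<int> jf = as<std::vector<int> >(join_from);
  std::vector<int> jo = as<std::vector<int> >(join_to);
  check_args(sz, jt, jf, jo);
  const int npop = (int)sz.size();
  for (int p = 0; p < npop; ++p)
    if (sz[p] % 2 != 0)
      stop("diploid summaries require an even chromosome count per population");
  int nleaf = 0;
  for (int s : sz) nleaf += s;
  std::vector<int> der(nleaf);
  NumericMatrix out(n_loci, 2 * npop + 1);
  for (int l = 0; l < n_loci; ++l) {
    double len = sim_locus(sz, jt, jf, jo, der);
    int off = 0;
    for (int p = 0; p < npop; ++p) {
      int d = 0, het = 0;
      for (int i = 0; i < sz[p]; i += 2) {
        int a = der[off + i], b = der[off + i + 1];
        d += a + b;
        if (a != b) ++het;
      }
      out(l, p) = d;
      out(l, npop + p) = het;
      off += sz[p];
    }
    out(l, 2 * npop) = len;
  }
  return out;
}

// [[Rcpp::export(name = ".sim_split_alleles")]]
IntegerMatrix sim_split_alleles(IntegerVector sizes, NumericVector join_t,
                                IntegerVector join_from, IntegerVector join_to,
                                int n_loci) {
  std::vector<int> sz = as<std::vector<int> >(sizes);
  std::vector<double> jt = as<std::vector<double> >(join_t);
  std::vector<int> jf = as<std::vector<int> >(join_from);
  std::vector<int> jo = as<std::vector<int> >(join_to);
  check_args(sz, jt, jf, jo);
  int nleaf = 0;
  for (int s : sz) nleaf += s;
  std::vector<int> der(nleaf);
  IntegerMatrix out(n_loci, nleaf);
  for (int l = 0; l < n_loci; ++l) {
    sim_locus(sz, jt, jf, jo, der);
    for (int i = 0; i < nleaf; ++i) out(l, i) = der[i];
  }
  return out;
}

// [[Rcpp::export(name = ".sim_tree_lengths")]]
NumericVector sim_tree_lengths(IntegerVector sizes, NumericVector join_t,
                               IntegerVector join_from, IntegerVector join_to,
                               int n_loci) {
  std::vector<int> sz = as<std::vector<int> >(sizes);
  std::vector<double> jt = as<std::vector<double> >(join_t);
  std::vector<int> jf = as<std::vector<int> >(join_from);
  std::vector<int> jo = as<std::vector<int> >(join_to);
  check_args(sz, jt, jf, jo);
  int nleaf = 0;
  for (int s : sz) nleaf += s;
  std::vector<int> der(nleaf);
  NumericVector out(n_loci);
  for (int l = 0; l < n_loci; ++l) out[l] = sim_locus(sz, jt, jf, jo, der);
  return out;
}
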