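#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured coalescent of sampled haploid lineages under a symmetric
// n-island model with infinite-alleles mutation, simulated backwards in
// time with the standard "killing" device: a mutation is the most recent
// mutation on a lineage, so it terminates the lineage and assigns a fresh
// allele to all its sampled descendants. Rates (coalescent time units of
// one haploid deme size): pairwise coalescence 1 within a deme, migration
// M/2 per lineage, mutation theta/2 per lineage.
//
// Returns a two-column integer matrix: sampled deme (1-based) and allele id.
// Uses R's RNG, so results are reproducible under set.seed().

// [[Rcpp::export]]
IntegerMatrix sim_island_locus_cpp(int n_demes, IntegerVector sample_sizes,
                                   double M, double theta) {
  int nsd = sample_sizes.size();
  if (nsd > n_demes) stop("more sampled demes than demes");
  int total = 0;
  for (int d = 0; d < nsd; ++d) total += sample_sizes[d];
  std::vector<int> deme;
  std::vector<std::vector<int>> desc;
  IntegerVector allele(total), demeOut(total);
  int idx = 0;
  for (int d = 0; d < nsd; ++d)
    for (int i = 0; i < sample_sizes[d]; ++i) {
      deme.push_back(d);
      desc.push_back(std::vector<int>(1, idx));
      demeOut[idx] = d + 1;
      ++idx;
    }
  std::vector<int> count(n_demes, 0);
  for (size_t i = 0; i < deme.size(); ++i) count[deme[i]]++;
  // pair count maintained incrementally: coal rate = sum_d C(count_d, 2)
  double coal = 0.0;
  for (int d = 0; d < n_demes; ++d)
    coal += 0.5 * count[d] * (count[d] - 1);
  int next_allele = 1;
  long guard = 0;
  while (deme.size() > 1) {
    if (++guard > 100000000L) stop("island coalescent: event limit exceeded");
    int k = (int)deme.size();
    double mig = 0.5 * k * M;
    double mut = 0.5 * k * theta;
    double u = unif_rand() * (coal + mig + mut);
    if (u < mut) { // mutation: kill lineage, fresh allele for descendants
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      for (size_t s = 0; s < desc[i].size(); ++s)
        allele[desc[i][s]] = next_allele;
      ++next_allele;
      coal -= count[deme[i]] - 1;
      count[deme[i]]--;
      deme[i] = deme.back(); deme.pop_back();
      desc[i].swap(desc.back()); desc.pop_back();
    } else if (u < mut + mig) { // migration to a uniformly chosen other deme
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int nd = (int)(unif_rand() * (n_demes - 1));
      if (nd >= n_demes - 1) nd = n_demes - 2;
      if (nd >= deme[i]) ++nd;
      coal -= count[deme[i]] - 1;
      count[deme[i]]--;
      coal += count[nd];
      count[nd]++;
      deme[i] = nd;
    } else { // within-deme coalescence, deme chosen by its pair count
      double v = unif_rand() * coal;
      int d = 0; double acc = 0.0;
      for (; d < n_demes - 1; ++d) {
        acc += 0.5 * count[d] * (count[d] - 1);
        if (v < acc) break;
      }
      std::vector<int> in_d;
      for (int i = 0; i < k; ++i) if (deme[i] == d) in_d.push_back(i);
      int a = (int)(unif_rand() * in_d.size());
      if (a >= (int)in_d.size()) a = in_d.size() - 1;
      int b = (int)(unif_rand() * (in_d.size() - 1));
      if (b >= (int)in_d.size() - 1) b = in_d.size() - 2;
      if (b >= a) ++b;
      int li = in_d[a], lj = in_d[b];
      if (li > lj) std::swap(li, lj);
      desc[li].insert(desc[li].end(), desc[lj].begin(), desc[lj].end());
      coal -= count[d] - 1;
      count[d]--;
      deme[lj] = deme.back(); deme.pop_back();
      desc[lj].swap(desc.back()); desc.pop_back();
    }
  }
  if (deme.size() == 1) // root: ancestral allele
    for (size_t s = 0; s < desc[0].size(); ++s)
      allele[desc[0][s]] = next_allele;
  IntegerMatrix out(total, 2);
  for (int i = 0; i < total; ++i) {
    out(i, 0) = demeOut[i];
    out(i, 1) = allele[i];
  }
  return out;
}
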