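#include <Rcpp.h>
using namespace Rcpp;

// Multispecies-coalescent gene-tree simulation on a rooted metric species
// tree, one sampled lineage per taxon.
//
// The species tree is passed in post-order: `children[j]` lists the node
// ids (0-based; leaves are 0..nTaxa-1, internal nodes follow in post-order
// starting at nTaxa) of the j-th internal node's children, and `blen[j]`
// is the length (coalescent units) of the branch above it.  The last
// internal node is the root; its branch length is ignored and coalescence
// above the root continues until a single lineage remains.
//
// Within a branch entered by k lineages, waiting times between coalescent
// events are exponential with rate k(k-1)/2 and the coalescing pair is
// uniform.  `nodeAge[j]` is the age (time above the leaves' reference
// level) of internal node j, so recorded event times are absolute ages.
//
// Returns, for each of the m genes, the clade bitmasks created by its
// nTaxa-1 coalescent events (masks, row-major m x (nTaxa-1)) and the
// corresponding event ages (times).  Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".simCoalescentClades")]]
List simCoalescentClades(int nTaxa, List children, NumericVector blen,
                         NumericVector nodeAge, int m) {
  const int nInternal = children.size();
  const int nMerge = nTaxa - 1;
  IntegerMatrix masks(m, nMerge);
  NumericMatrix times(m, nMerge);

  // flatten children lists
  std::vector< std::vector<int> > kids(nInternal);
  for (int j = 0; j < nInternal; ++j) {
    IntegerVector cj = children[j];
    kids[j].assign(cj.begin(), cj.end());
  }

  std::vector< std::vector<int> > surv(nTaxa + nInternal);
  std::vector<int> pool;
  pool.reserve(nTaxa);

  for (int g = 0; g < m; ++g) {
    int cnt = 0;
    for (int j = 0; j < nInternal; ++j) {
      const int node = nTaxa + j;
      const bool isRoot = (j == nInternal - 1);
      pool.clear();
      for (size_t c = 0; c < kids[j].size(); ++c) {
        const int ch = kids[j][c];
        if (ch < nTaxa) {
          pool.push_back(1 << ch);
        } else {
          const std::vector<int> &s = surv[ch];
          pool.insert(pool.end(), s.begin(), s.end());
        }
      }
      double elapsed = 0.0;
      const double L = blen[j];
      int k = (int) pool.size();
      while (k > 1) {
        const double rate = 0.5 * k * (k - 1);
        elapsed += exp_rand() / rate;
        if (!isRoot && elapsed > L) break;
        int i1 = (int) (unif_rand() * k);
        if (i1 == k) i1 = k - 1;
        int i2 = (int) (unif_rand() * (k - 1));
        if (i2 == k - 1) i2 = k - 2;
        if (i2 >= i1) ++i2;
        const int merged = pool[i1] | pool[i2];
        masks(g, cnt) = merged;
        times(g, cnt) = nodeAge[j] + elapsed;
        ++cnt;
        // remove i1 and i2, append merged
        if (i1 > i2) std::swap(i1, i2);
        pool.erase(pool.begin() + i2);
        pool.erase(pool.begin() + i1);
        pool.push_back(merged);
        --k;
      }
      surv[node] = pool;
    }
  }
  return List::create(_["masks"] = masks, _["times"] = times);
}
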