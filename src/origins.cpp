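#include <Rcpp.h>
using namespace Rcpp;

// Parsimony machinery for homoplasy inference on a guide tree.
//
// States are coded 0 = missing (gap/N/excluded genome, treated as fully
// ambiguous) and 1..4 = A,C,G,T.  The minimum number of independent
// mutational origins of an allele X is the small-parsimony score of the
// binary carrier-vs-rest character (Hartigan/Fitch on the tree, exact for
// any node degree), floored at 1: the fewest state changes that can explain
// the carriers of X, which is invariant to where the (arbitrary) root sits.
// origins >= 2 means the carriers are incompatible with a single origin
// under vertical inheritance -- the allele is homoplasic.

// preferred-state sets as bitmasks: 1 = X, 2 = not-X, 3 = either
static int hartigan_origins(const IntegerVector& parent,
                            const IntegerVector& child, int ntip, int nnode,
                            const int* site_states, int allele,
                            std::vector<int>& set, std::vector<int>& k1,
                            std::vector<int>& k2, std::vector<int>& deg) {
  for (int v = 0; v < nnode; ++v) { set[v] = 0; k1[v] = 0; k2[v] = 0; deg[v] = 0; }
  for (int leaf = 0; leaf < ntip; ++leaf) {
    int s = site_states[leaf];
    set[leaf] = (s == 0) ? 3 : (s == allele ? 1 : 2);
  }
  int score = 0;
  int nedge = parent.size();
  // postorder: child sets are final before their parent edge is seen
  for (int e = 0; e < nedge; ++e) {
    int c = child[e] - 1, p = parent[e] - 1;
    if (c >= ntip) { // finalize internal child from its accumulated counts
      int K = std::max(k1[c], k2[c]);
      set[c] = ((k1[c] == K) ? 1 : 0) | ((k2[c] == K) ? 2 : 0);
      score += deg[c] - K;
    }
    if (set[c] & 1) k1[p]++;
    if (set[c] & 2) k2[p]++;
    deg[p]++;
  }
  int root = ntip; // node ntip+1, 0-based
  score += deg[root] - std::max(k1[root], k2[root]);
  return score > 0 ? score : 1;
}

// [[Rcpp::export(name = ".origins_cpp")]]
IntegerVector origins_cpp(IntegerVector parent, IntegerVector child, int ntip,
                          int nnode, IntegerVector states, int allele) {
  std::vector<int> set(nnode), k1(nnode), k2(nnode), deg(nnode);
  int o = hartigan_origins(parent, child, ntip, nnode, &states[0], allele,
                           set, k1, k2, deg);
  return IntegerVector::create(_["origins"] = o);
}

// Tally homoplasic (h) and non-homoplasic (m) minor alleles over the columns
// of `S` (ntip x nsites, codes 0..4).  `exclude` (1-based leaf id, 0 = none)
// masks one genome: its states become missing and it is dropped from allele
// counts -- equivalent to pruning the leaf under parsimony.
// [[Rcpp::export(name = ".hm_count_cpp")]]
IntegerVector hm_count_cpp(IntegerVector parent, IntegerVector child, int ntip,
                           int nnode, IntegerMatrix S, int exclude,
                           bool count_singletons) {
  int nsites = S.ncol();
  std::vector<int> set(nnode), k1(nnode), k2(nnode), deg(nnode);
  std::vector<int> site(ntip);
  int h = 0, m = 0;
  for (int j = 0; j < nsites; ++j) {
    int counts[5] = {0, 0, 0, 0, 0};
    for (int i = 0; i < ntip; ++i) {
      int s = S(i, j);
      if (i == exclude - 1) s = 0;
      site[i] = s;
      counts[s]++;
    }
    int nalleles = 0, modal = 0, modal_n = -1;
    for (int a = 1; a <= 4; ++a) {
      if (counts[a] > 0) nalleles++;
      if (counts[a] > modal_n) { modal_n = counts[a]; modal = a; } // tie: smaller code
    }
    if (nalleles < 2) continue;
    for (int a = 1; a <= 4; ++a) {
      if (a == modal || counts[a] == 0) continue;
      if (counts[a] == 1) {
        if (count_singletons) m++;
        continue;
      }
      int o = hartigan_origins(parent, child, ntip, nnode, site.data(), a,
                               set, k1, k2, deg);
      if (o >= 2) h++; else m++;
    }
  }
  return IntegerVector::create(_["h"] = h, _["m"] = m);
}
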