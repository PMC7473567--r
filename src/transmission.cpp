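// Forward discrete-generation simulator of host-structured endosymbiont
// inheritance.  Hosts reproduce by Wright-Fisher sampling; each offspring
// host's symbiont population is founded by `bottleneck` cells drawn (with
// replacement) from its parent host's NS symbionts and instantly regrown
// to NS by multinomial resampling of the founders.  Horizontal acquisition
// is folded into offspring formation: with probability H an offspring
// symbiont instead copies a uniformly random cell from a uniformly random
// host of the parental generation, bypassing the oocyte bottleneck.
//
// Mutation is tracked as counts on an implicit genealogy: each offspring
// lineage gains Poisson(mu) mutations per generation, recorded as nodes
// (parent, nmut, cumulative count).  Pairwise differences between two
// cells are cum[x] + cum[y] - 2*cum[mrca(x, y)], with the MRCA found by
// walking parent pointers (node indices increase through time).

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct MutTree {
  std::vector<int> parent{-1};
  std::vector<int> nmut{0};
  std::vector<double> cum{0.0};

  int add(int src, int k) {
    parent.push_back(src);
    nmut.push_back(k);
    cum.push_back(cum[src] + k);
    return (int)parent.size() - 1;
  }
  double diff(int x, int y) const {
    double cx = cum[x], cy = cum[y];
    while (x != y) {
      if (x > y) x = parent[x]; else y = parent[y];
    }
    return cx + cy - 2.0 * cum[x];
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_transmission(int NH, int NS, double H, double mu, int B, int G,
                      int n_within_pairs, int n_between_pairs,
                      bool sample_tree, int hosts_sampled, int symb_per_host) {
  if (NH < 2) stop("n_hosts must be >= 2");
  if (NS < 1) stop("n_symbionts must be >= 1");
  if (B < 1 || B > NS) stop("bottleneck must be in [1, n_symbionts]");
  const int P = NH * NS;

  MutTree tree;
  std::vector<int> cur(P, 0), nxt(P);
  std::vector<int> ph(NH), founders(B);

  for (int g = 0; g < G; ++g) {
    if (tree.parent.size() > (size_t)2e7)
      stop("mutation genealogy too large; lower mu or n_generations");
    for (int i = 0; i < NH; ++i) ph[i] = runif_int(NH);
    for (int i = 0; i < NH; ++i) {
      const int poff = ph[i] * NS;
      for (int b = 0; b < B; ++b) founders[b] = cur[poff + runif_int(NS)];
      for (int j = 0; j < NS; ++j) {
        int src;
        if (H > 0 && unif_rand() < H) {
          src = cur[runif_int(NH) * NS + runif_int(NS)];
        } else {
          src = founders[runif_int(B)];
        }
        int k = (int)R::rpois(mu);
        nxt[i * NS + j] = k > 0 ? tree.add(src, k) : src;
      }
    }
    std::swap(cur, nxt);
  }

  // two symbionts from two distinct random hosts
  int h1 = runif_int(NH), h2 = runif_int(NH - 1);
  if (h2 >= h1) ++h2;
  double d_pair = tree.diff(cur[h1 * NS + runif_int(NS)],
                            cur[h2 * NS + runif_int(NS)]);

  double mean_within = NA_REAL;
  if (NS >= 2 && n_within_pairs > 0) {
    double acc = 0;
    for (int r = 0; r < n_within_pairs; ++r) {
      int h = runif_int(NH);
      int c1 = runif_int(NS), c2 = runif_int(NS - 1);
      if (c2 >= c1) ++c2;
      acc += tree.diff(cur[h * NS + c1], cur[h * NS + c2]);
    }
    mean_within = acc / n_within_pairs;
  }
  double mean_between = NA_REAL;
  if (n_between_pairs > 0) {
    double acc = 0;
    for (int r = 0; r < n_between_pairs; ++r) {
      int a = runif_int(NH), b = runif_int(NH - 1);
      if (b >= a) ++b;
      acc += tree.diff(cur[a * NS + runif_int(NS)], cur[b * NS + runif_int(NS)]);
    }
    mean_between = acc / n_between_pairs;
  }

  List out = List::create(_["d_pair"] = d_pair,
                          _["mean_within"] = mean_within,
                          _["mean_between"] = mean_between);

  if (sample_tree) {
    if (hosts_sampled > NH) stop("hosts_sampled exceeds n_hosts");
    if (symb_per_host > NS) stop("symbionts_per_host exceeds n_symbionts");
    // distinct hosts by partial Fisher-Yates
    std::vector<int> hosts(NH);
    for (int i = 0; i < NH; ++i) hosts[i] = i;
    for (int i = 0; i < hosts_sampled; ++i)
      std::swap(hosts[i], hosts[i + runif_int(NH - i)]);
    IntegerVector node_id(hosts_sampled * symb_per_host);
    IntegerVector host_of(hosts_sampled * symb_per_host);
    std::vector<int> cells(NS);
    int k = 0;
    for (int i = 0; i < hosts_sampled; ++i) {
      for (int c = 0; c < NS; ++c) cells[c] = c;
      for (int c = 0; c < symb_per_host; ++c)
        std::swap(cells[c], cells[c + runif_int(NS - c)]);
      for (int c = 0; c < symb_per_host; ++c, ++k) {
        node_id[k] = cur[hosts[i] * NS + cells[c]];
        host_of[k] = hosts[i] + 1;
      }
    }
    out["sample_nodes"] = node_id;
    out["sample_hosts"] = host_of;
    out["tree_parent"] = IntegerVector(tree.parent.begin(), tree.parent.end());
    out["tree_nmut"] = IntegerVector(tree.nmut.begin(), tree.nmut.end());
  }
  return out;
}

// Decode samtools pileup base-call strings.  Returns for each input string
// the decoded calls (one character per aligned read: A/C/G/T/N/*) and the
// number of indel events (+n/-n tokens) observed at the column.
// [[Rcpp::export]]
List cpp_decode_pileup(CharacterVector calls, CharacterVector ref) {
  int n = calls.size();
  CharacterVector decoded(n);
  IntegerVector n_indel(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(calls[i]);
    char rb = toupper(as<std::string>(ref[i % ref.size()])[0]);
    std::string out;
    int indels = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      char c = s[p];
      if (c == '^') { ++p; continue; }          // mapping-quality char consumed
      if (c == '$') continue;
      if (c == '+' || c == '-') {
        ++p;
        if (p >= s.size() || !isdigit(s[p]))
          stop("malformed indel token in pileup record %d", i + 1);
        size_t q = p;
        int len = 0;
        while (q < s.size() && isdigit(s[q])) { len = len * 10 + (s[q] - '0'); ++q; }
        if (q + len > s.size())
          stop("malformed indel token in pileup record %d", i + 1);
        p = q + len - 1;
        ++indels;
        continue;
      }
      if (c == '.' || c == ',') { out.push_back(rb); continue; }
      if (c == '*') { out.push_back('*'); continue; }
      if (c == '>' || c == '<') { out.push_back('N'); continue; }
      out.push_back(toupper(c));
    }
    decoded[i] = out;
    n_indel[i] = indels;
  }
  return List::create(_["decoded"] = decoded, _["n_indel"] = n_indel);
}
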