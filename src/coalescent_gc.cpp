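// Exact ancestral-recombination-graph simulator for a neutral coalescent
// with bacterial gene conversion (fixed tract length, no clonal frame).
//
// Time is measured in units of 2*Ne generations: a pair of lineages
// coalesces at rate 1, mutation strikes a lineage at rate theta/2 per
// carried (unresolved) site, and gene conversion initiates at rate rho/2
// per genome site.  An initiation at site s replaces the tract
// [s, min(s + l - 1, L)]; on the ancestral process this splits a lineage
// into the material inside and outside the tract.  Initiations whose
// tract does not properly split the lineage's ancestral material leave
// every marginal genealogy unchanged, so they are thinned away exactly
// by restricting initiation to the admissible positions.
//
// Segments carry descendant bitmasks (n <= 64) so mutations can be
// dropped on edges directly; material whose marginal MRCA has been
// reached is trimmed, which is what keeps the ARG walk finite in
// practice even at high rho.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Seg {
  int a, b;            // inclusive 1-based site range
  uint64_t mask;       // sample descendants at these sites
};

struct Iv { int a, b; };

struct Lineage {
  std::vector<Seg> segs;          // sorted, disjoint, unresolved sites only
  std::vector<Iv> admiss;         // admissible gene-conversion start sites
  double matlen = 0;              // total unresolved sites carried
  double W = 0;                   // total admissible start positions
};

double seg_length(const std::vector<Seg>& segs) {
  double t = 0;
  for (const Seg& s : segs) t += s.b - s.a + 1;
  return t;
}

// Admissible initiation positions: tract [s, min(s+l-1, L)] must
// intersect the material and must not cover all of it.
void compute_admissible(Lineage& lin, int l, int L) {
  lin.admiss.clear();
  lin.W = 0;
  if (lin.segs.empty()) return;
  // union of [a_j - l + 1, b_j] clipped to [1, L]
  std::vector<Iv> hit;
  for (const Seg& s : lin.segs) {
    int lo = std::max(1, s.a - l + 1);
    int hi = std::min(L, s.b);
    if (!hit.empty() && lo <= hit.back().b + 1) {
      if (hi > hit.back().b) hit.back().b = hi;
    } else {
      hit.push_back({lo, hi});
    }
  }
  // positions whose tract covers every carried site
  int afirst = lin.segs.front().a, blast = lin.segs.back().b;
  int clo = std::max(1, blast - l + 1), chi = afirst;  // may be empty
  for (const Iv& iv : hit) {
    if (clo > chi || iv.b < clo || iv.a > chi) {       // no overlap with cover
      lin.admiss.push_back(iv);
    } else {
      if (iv.a < clo) lin.admiss.push_back({iv.a, clo - 1});
      if (iv.b > chi) lin.admiss.push_back({chi + 1, iv.b});
    }
  }
  for (const Iv& iv : lin.admiss) lin.W += iv.b - iv.a + 1;
}

void refresh(Lineage& lin, int l, int L) {
  lin.matlen = seg_length(lin.segs);
  compute_admissible(lin, l, L);
}

int runif_int(int n) {  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate_gc(int n, int L, double theta, double rho, int tract,
                     double event_budget) {
  if (n < 2 || n > 64) stop("sample size must be between 2 and 64");
  if (L < 1) stop("genome length must be positive");
  const int l = std::max(1, tract);

  std::vector<Lineage> lin(n);
  for (int i = 0; i < n; ++i) {
    lin[i].segs.push_back({1, L, (uint64_t)1 << i});
    refresh(lin[i], l, L);
  }
  std::vector<int> cnt(L + 1, n);  // carriers per site

  double total_mat = (double)n * L;
  double total_W = 0;
  for (const Lineage& x : lin) total_W += x.W;

  std::vector<int> mut_pos;
  std::vector<uint64_t> mut_mask;
  std::set<int> used_pos;
  int n_recomb = 0, n_skipped_mut = 0;
  double events = 0;

  while (total_mat > 0.5) {
    if (++events > event_budget)
      stop("event budget exceeded (theta=%g, rho=%g, tract=%d, L=%d): "
           "increase event_budget or reduce rho*genome_length", theta, rho, l, L);
    int k = (int)lin.size();
    double Rcoal = k * (k - 1) / 2.0;
    double Rmut = 0.5 * theta * total_mat;
    double Rgc = 0.5 * rho * total_W;
    double u = unif_rand() * (Rcoal + Rmut + Rgc);

    if (u < Rcoal) {
      // ---- coalescence of a uniform pair ----
      int i = runif_int(k), j = runif_int(k - 1);
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      std::vector<Seg> A = lin[i].segs;  // working copies
      std::vector<Seg> B = lin[j].segs;
      std::vector<Seg> out;
      auto push = [&out](Seg s) {
        if (!out.empty() && out.back().b == s.a - 1 && out.back().mask == s.mask)
          out.back().b = s.b;
        else
          out.push_back(s);
      };
      size_t ia = 0, ib = 0;
      while (ia < A.size() && ib < B.size()) {
        if (A[ia].b < B[ib].a) { push(A[ia]); ++ia; continue; }
        if (B[ib].b < A[ia].a) { push(B[ib]); ++ib; continue; }
        // overlap: emit any leading non-overlapping prefix, align starts
        if (A[ia].a < B[ib].a) {
          push({A[ia].a, B[ib].a - 1, A[ia].mask});
          A[ia].a = B[ib].a;
        } else if (B[ib].a < A[ia].a) {
          push({B[ib].a, A[ia].a - 1, B[ib].mask});
          B[ib].a = A[ia].a;
        }
        int oend = std::min(A[ia].b, B[ib].b);
        uint64_t m = A[ia].mask | B[ib].mask;
        // joint stretch: carriers drop by one; trim sites reaching MRCA
        int run = -1;
        for (int s = A[ia].a; s <= oend; ++s) {
          if (--cnt[s] == 1) {
            if (run >= 0) { push({run, s - 1, m}); run = -1; }
          } else if (run < 0) run = s;
        }
        if (run >= 0) push({run, oend, m});
        if (A[ia].b > oend) A[ia].a = oend + 1; else ++ia;
        if (B[ib].b > oend) B[ib].a = oend + 1; else ++ib;
      }
      for (; ia < A.size(); ++ia) push(A[ia]);
      for (; ib < B.size(); ++ib) push(B[ib]);
      total_mat -= lin[i].matlen + lin[j].matlen;
      total_W -= lin[i].W + lin[j].W;
      Lineage merged;
      merged.segs = std::move(out);
      refresh(merged, l, L);
      lin.erase(lin.begin() + j);
      lin.erase(lin.begin() + i);
      if (!merged.segs.empty()) {
        total_mat += merged.matlen;
        total_W += merged.W;
        lin.push_back(std::move(merged));
      }
    } else if (u < Rcoal + Rmut) {
      // ---- mutation on a lineage chosen in proportion to material ----
      double r = unif_rand() * total_mat;
      int i = 0;
      for (; i < k - 1; ++i) { if (r < lin[i].matlen) break; r -= lin[i].matlen; }
      bool placed = false;
      for (int attempt = 0; attempt < 200 && !placed; ++attempt) {
        double rr = unif_rand() * lin[i].matlen;
        for (const Seg& s : lin[i].segs) {
          double len = s.b - s.a + 1;
          if (rr < len) {
            int pos = s.a + (int)rr;
            if (pos > s.b) pos = s.b;
            if (used_pos.insert(pos).second) {
              mut_pos.push_back(pos);
              mut_mask.push_back(s.mask);
              placed = true;
            }
            break;
          }
          rr -= len;
        }
      }
      if (!placed) ++n_skipped_mut;  // infinite-sites collision guard
    } else {
      // ---- gene conversion: split at an admissible initiation site ----
      double r = unif_rand() * total_W;
      int i = 0;
      for (; i < k - 1; ++i) { if (r < lin[i].W) break; r -= lin[i].W; }
      double rr = unif_rand() * lin[i].W;
      int s0 = -1;
      for (const Iv& iv : lin[i].admiss) {
        double len = iv.b - iv.a + 1;
        if (rr < len) { s0 = iv.a + (int)rr; if (s0 > iv.b) s0 = iv.b; break; }
        rr -= len;
      }
      if (s0 < 0) continue;
      int t1 = s0, t2 = std::min(s0 + l - 1, L);
      Lineage inside, outside;
      for (const Seg& s : lin[i].segs) {
        if (s.b < t1 || s.a > t2) { outside.segs.push_back(s); continue; }
        if (s.a < t1) outside.segs.push_back({s.a, t1 - 1, s.mask});
        inside.segs.push_back({std::max(s.a, t1), std::min(s.b, t2), s.mask});
        if (s.b > t2) outside.segs.push_back({t2 + 1, s.b, s.mask});
      }
      if (inside.segs.empty() || outside.segs.empty()) continue;  // guarded by admissibility
      std::sort(outside.segs.begin(), outside.segs.end(),
                [](const Seg& x, const Seg& y) { return x.a < y.a; });
      total_mat -= lin[i].matlen;
      total_W -= lin[i].W;
      refresh(inside, l, L);
      refresh(outside, l, L);
      lin.erase(lin.begin() + i);
      total_mat += inside.matlen + outside.matlen;
      total_W += inside.W + outside.W;
      lin.push_back(std::move(inside));
      lin.push_back(std::move(outside));
      ++n_recomb;
    }
  }

  // order mutations by position
  int S = (int)mut_pos.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int x, int y) { return mut_pos[x] < mut_pos[y]; });
  IntegerVector pos(S);
  IntegerMatrix derived(n, S);
  for (int c = 0; c < S; ++c) {
    pos[c] = mut_pos[ord[c]];
    uint64_t m = mut_mask[ord[c]];
    for (int r = 0; r < n; ++r)
      derived(r, c) = (m >> r) & 1 ? 1 : 0;
  }
  return List::create(_["positions"] = pos,
                      _["derived"] = derived,
                      _["n_recomb_events"] = n_recomb,
                      _["n_events"] = events,
                      _["n_skipped_mutations"] = n_skipped_mut);
}
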