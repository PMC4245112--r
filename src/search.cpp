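// Parsimony kernels: tree-length scoring, exact branch-and-bound search and
// random-addition + TBR heuristic search over unrooted binary trees.
//
// Conventions shared with the R side:
//   * taxa are 0-based 0..n-1 (leaf node ids), internal node ids n..2n-3;
//   * a cell is a bitmask over states 0..9 (bit k set <=> state k allowed);
//   * trees are undirected edge arrays; scoring roots virtually on edge 0;
//   * taxon subsets (constraints, splits) are bitmasks over taxa.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <set>
#include <array>
#include <algorithm>

using namespace Rcpp;

static const int BIG = 1000000;         // saturating "infinity" for state DP
static const long long PEN = 1000000;   // per-violated-constraint penalty
static const int NSTATE = 10;

static inline int popcount32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// ---------------------------------------------------------------------------
// scoring / search engine on binary unrooted trees
// ---------------------------------------------------------------------------

struct Engine {
  int n = 0, nchar = 0;
  std::vector<uint32_t> leafMask;      // n x nchar, row-major by taxon
  std::vector<int> weights;
  std::vector<int> unordChars, ordChars;
  std::vector<int> maxState;           // per character, highest observed state

  // current tree (branch-and-bound workspace)
  int eu[96], ev[96], m = 0, nextInternal = 0;

  // postorder scratch, rebuilt by score()
  int poNode[96], poC1[96], poC2[96], poLen = 0;
  int parentOf[96];
  uint32_t below[96];
  int deg[96]; int nbr[96][3];

  // directional-set workspace for the branch and bound (indexed node*nchar+c
  // for unordered characters; cost vectors for ordered characters)
  std::vector<uint32_t> downS, upS;
  std::vector<int> downC, upC;      // [(node * nOrd + oi) * NSTATE + s]
  std::vector<long long> ordCur;    // current length per ordered character

  long long nodesVisited = 0;

  // constraints
  std::vector<uint32_t> reqG, forbG;

  // branch-and-bound state
  long long incumbent = 0;
  int slack = 0, maxTrees = 0;
  bool truncated = false;
  std::vector<int> mAll;               // per character: min steps on ANY tree
  std::vector<int> stepsArr;           // per character steps of current tree
  std::vector<int> pairA, pairB;       // disjoint incompatible char pairs
  std::vector<int> childS;             // scratch: per-char child step bound
  std::vector<std::vector<int>> outEU, outEV;
  std::vector<long long> outLen;

  void setData(const IntegerMatrix& masks, const LogicalVector& ordered,
               const IntegerVector& w) {
    n = masks.nrow(); nchar = masks.ncol();
    leafMask.assign((size_t)n * nchar, 0u);
    weights.assign(w.begin(), w.end());
    maxState.assign(nchar, 0);
    unordChars.clear(); ordChars.clear();
    for (int c = 0; c < nchar; ++c) {
      uint32_t un = 0;
      for (int t = 0; t < n; ++t) {
        leafMask[(size_t)t * nchar + c] = (uint32_t)masks(t, c);
        un |= (uint32_t)masks(t, c);
      }
      int hi = 0; for (int s = 0; s < NSTATE; ++s) if (un >> s & 1u) hi = s;
      maxState[c] = hi;
      if (ordered[c]) ordChars.push_back(c); else unordChars.push_back(c);
    }
  }

  // --- postorder over an arbitrary binary edge array, virtual root on edge 0
  void dfs(int node, int parent) {
    parentOf[node] = parent;
    int c1 = -1, c2 = -1;
    for (int j = 0; j < deg[node]; ++j) {
      int nb = nbr[node][j];
      if (nb == parent) continue;
      if (c1 < 0) c1 = nb; else c2 = nb;
    }
    if (c1 >= 0) dfs(c1, node);
    if (c2 >= 0) dfs(c2, node);
    poNode[poLen] = node; poC1[poLen] = c1; poC2[poLen] = c2; ++poLen;
    below[node] = (c1 < 0) ? (1u << node) : (below[c1] | below[c2]);
  }

  void buildPostorder(const int* EU, const int* EV, int mm) {
    for (int i = 0; i < mm; ++i) { deg[EU[i]] = 0; deg[EV[i]] = 0; }
    for (int i = 0; i < mm; ++i) {
      nbr[EU[i]][deg[EU[i]]++] = EV[i];
      nbr[EV[i]][deg[EV[i]]++] = EU[i];
    }
    poLen = 0;
    dfs(EU[0], EV[0]);
    dfs(EV[0], EU[0]);
  }

  // weighted length of the binary tree in (EU,EV); fills below[] as side effect
  long long score(const int* EU, const int* EV, int mm) {
    buildPostorder(EU, EV, mm);
    const int rootA = EU[0], rootB = EV[0];
    long long total = 0;
    uint32_t fs[96];
    for (size_t ui = 0; ui < unordChars.size(); ++ui) {
      const int c = unordChars[ui];
      if (weights[c] == 0) continue;
      int steps = 0;
      for (int i = 0; i < poLen; ++i) {
        const int nd = poNode[i];
        if (poC1[i] < 0) { fs[nd] = leafMask[(size_t)nd * nchar + c]; continue; }
        uint32_t x = fs[poC1[i]] & fs[poC2[i]];
        if (!x) { x = fs[poC1[i]] | fs[poC2[i]]; ++steps; }
        fs[nd] = x;
      }
      if (!(fs[rootA] & fs[rootB])) ++steps;
      total += (long long)weights[c] * steps;
    }
    if (!ordChars.empty()) {
      int cost[96][NSTATE];
      for (size_t oi = 0; oi < ordChars.size(); ++oi) {
        const int c = ordChars[oi];
        if (weights[c] == 0) continue;
        const int S = maxState[c] + 1;
        for (int i = 0; i < poLen; ++i) {
          const int nd = poNode[i];
          if (poC1[i] < 0) {
            const uint32_t mk = leafMask[(size_t)nd * nchar + c];
            for (int s = 0; s < S; ++s) cost[nd][s] = (mk >> s & 1u) ? 0 : BIG;
            continue;
          }
          for (int s = 0; s < S; ++s) {
            int b1 = BIG, b2 = BIG;
            for (int t = 0; t < S; ++t) {
              const int d = s > t ? s - t : t - s;
              b1 = std::min(b1, cost[poC1[i]][t] + d);
              b2 = std::min(b2, cost[poC2[i]][t] + d);
            }
            cost[nd][s] = std::min(b1 + b2, BIG);
          }
        }
        int best = BIG;
        for (int s = 0; s < S; ++s)
          for (int t = 0; t < S; ++t) {
            const int d = s > t ? s - t : t - s;
            best = std::min(best, cost[rootA][s] + cost[rootB][t] + d);
          }
        total += (long long)weights[c] * best;
      }
    }
    return total;
  }

  // --- incremental scoring for the branch and bound -----------------------
  // One pass computes, for every edge, the state sets (unordered) / cost
  // vectors (ordered) of BOTH components the edge separates. The length of
  // the tree obtained by inserting the next leaf on an edge then follows in
  // O(1) per character (Fitch edge-set rule; DP combination for ordered),
  // instead of a full rescore per candidate edge.

  static inline uint32_t fcomb(uint32_t a, uint32_t b) {
    const uint32_t x = a & b;
    return x ? x : (a | b);
  }

  void ensureWorkspace() {
    if ((int)downS.size() < 96 * nchar) {
      downS.assign((size_t)96 * nchar, 0u);
      upS.assign((size_t)96 * nchar, 0u);
    }
    if ((int)stepsArr.size() < nchar) stepsArr.assign(nchar, 0);
    if ((int)childS.size() < nchar) childS.assign(nchar, 0);
    const int nOrd = (int)ordChars.size();
    if (nOrd && (int)downC.size() < 96 * nOrd * NSTATE) {
      downC.assign((size_t)96 * nOrd * NSTATE, 0);
      upC.assign((size_t)96 * nOrd * NSTATE, 0);
    }
    ordCur.assign(nOrd ? nOrd : 1, 0);
  }

  // full down+up pass over the current tree; returns its weighted length
  long long fullPass(const int* EU, const int* EV, int mm) {
    buildPostorder(EU, EV, mm);
    ensureWorkspace();
    const int rootA = EU[0], rootB = EV[0];
    long long total = 0;
    for (size_t ui = 0; ui < unordChars.size(); ++ui) {
      const int c = unordChars[ui];
      if (weights[c] == 0) continue;
      int steps = 0;
      for (int i = 0; i < poLen; ++i) {
        const int nd = poNode[i];
        if (poC1[i] < 0) { downS[(size_t)nd * nchar + c] =
            leafMask[(size_t)nd * nchar + c]; continue; }
        uint32_t x = downS[(size_t)poC1[i] * nchar + c] &
                     downS[(size_t)poC2[i] * nchar + c];
        if (!x) { x = downS[(size_t)poC1[i] * nchar + c] |
                      downS[(size_t)poC2[i] * nchar + c]; ++steps; }
        downS[(size_t)nd * nchar + c] = x;
      }
      if (!(downS[(size_t)rootA * nchar + c] &
            downS[(size_t)rootB * nchar + c])) ++steps;
      stepsArr[c] = steps;
      total += (long long)weights[c] * steps;
      // uppass (reverse postorder keeps parents before children)
      upS[(size_t)rootA * nchar + c] = downS[(size_t)rootB * nchar + c];
      upS[(size_t)rootB * nchar + c] = downS[(size_t)rootA * nchar + c];
      for (int i = poLen - 1; i >= 0; --i) {
        if (poC1[i] < 0) continue;
        const int v = poNode[i], c1 = poC1[i], c2 = poC2[i];
        const uint32_t uv = upS[(size_t)v * nchar + c];
        upS[(size_t)c1 * nchar + c] =
          fcomb(uv, downS[(size_t)c2 * nchar + c]);
        upS[(size_t)c2 * nchar + c] =
          fcomb(uv, downS[(size_t)c1 * nchar + c]);
      }
    }
    const int nOrd = (int)ordChars.size();
    for (int oi = 0; oi < nOrd; ++oi) {
      const int c = ordChars[oi];
      if (weights[c] == 0) { ordCur[oi] = 0; continue; }
      const int S = maxState[c] + 1;
      int* dC = &downC[0];
      int* uC = &upC[0];
      #define DC(v) (dC + ((size_t)(v) * nOrd + oi) * NSTATE)
      #define UC(v) (uC + ((size_t)(v) * nOrd + oi) * NSTATE)
      for (int i = 0; i < poLen; ++i) {
        const int nd = poNode[i];
        int* out = DC(nd);
        if (poC1[i] < 0) {
          const uint32_t mk = leafMask[(size_t)nd * nchar + c];
          for (int s = 0; s < S; ++s) out[s] = (mk >> s & 1u) ? 0 : BIG;
          continue;
        }
        const int* a = DC(poC1[i]); const int* b = DC(poC2[i]);
        for (int s = 0; s < S; ++s) {
          int b1 = BIG, b2 = BIG;
          for (int t = 0; t < S; ++t) {
            const int d = s > t ? s - t : t - s;
            b1 = std::min(b1, a[t] + d);
            b2 = std::min(b2, b[t] + d);
          }
          out[s] = std::min(b1 + b2, BIG);
        }
      }
      int best = BIG;
      {
        const int* a = DC(rootA); const int* b = DC(rootB);
        for (int s = 0; s < S; ++s)
          for (int t = 0; t < S; ++t) {
            const int d = s > t ? s - t : t - s;
            best = std::min(best, a[s] + b[t] + d);
          }
      }
      ordCur[oi] = best;
      total += (long long)weights[c] * best;
      for (int s = 0; s < S; ++s) {
        UC(rootA)[s] = DC(rootB)[s];
        UC(rootB)[s] = DC(rootA)[s];
      }
      for (int i = poLen - 1; i >= 0; --i) {
        if (poC1[i] < 0) continue;
        const int v = poNode[i], c1 = poC1[i], c2 = poC2[i];
        const int* uv = UC(v);
        for (int two = 0; two < 2; ++two) {
          const int ch = two ? c2 : c1;
          const int* sib = DC(two ? c1 : c2);
          int* out = UC(ch);
          for (int s = 0; s < S; ++s) {
            int b1 = BIG, b2 = BIG;
            for (int t = 0; t < S; ++t) {
              const int d = s > t ? s - t : t - s;
              b1 = std::min(b1, uv[t] + d);
              b2 = std::min(b2, sib[t] + d);
            }
            out[s] = std::min(b1 + b2, BIG);
          }
        }
      }
      #undef DC
      #undef UC
    }
    return total;
  }

  // extra steps caused by inserting `leaf` on edge e of the current tree;
  // when withBound is set, returns instead an admissible lower bound on the
  // FULL tree length through that child: sum_c w_c * max(s_child_c, m_c)
  // (per-character steps are monotone under leaf addition and never fall
  // below the character's minimum over all trees)
  long long edgeDelta(int e, int leaf, bool withBound = false) {
    // child endpoint of the edge (the one whose parent is the other end)
    int v = ev[e];
    if (parentOf[v] != eu[e]) v = eu[e];
    long long acc = 0;
    for (size_t ui = 0; ui < unordChars.size(); ++ui) {
      const int c = unordChars[ui];
      if (weights[c] == 0) continue;
      const uint32_t F = fcomb(downS[(size_t)v * nchar + c],
                               upS[(size_t)v * nchar + c]);
      int sc = (F & leafMask[(size_t)leaf * nchar + c]) ? 0 : 1;
      if (withBound) {
        sc += stepsArr[c];
        if (sc < mAll[c]) sc = mAll[c];
        childS[c] = sc;
      }
      acc += (long long)weights[c] * sc;
    }
    const int nOrd = (int)ordChars.size();
    for (int oi = 0; oi < nOrd; ++oi) {
      const int c = ordChars[oi];
      if (weights[c] == 0) continue;
      const int S = maxState[c] + 1;
      const int* a = &downC[((size_t)v * nOrd + oi) * NSTATE];
      const int* b = &upC[((size_t)v * nOrd + oi) * NSTATE];
      const uint32_t mk = leafMask[(size_t)leaf * nchar + c];
      int best = BIG;
      for (int s = 0; s < S; ++s) {
        int b1 = BIG, b2 = BIG, bl = BIG;
        for (int t = 0; t < S; ++t) {
          const int d = s > t ? s - t : t - s;
          b1 = std::min(b1, a[t] + d);
          b2 = std::min(b2, b[t] + d);
          if (mk >> t & 1u) bl = std::min(bl, d);
        }
        best = std::min(best, b1 + b2 + bl);
      }
      if (withBound) {
        acc += (long long)weights[c] * std::max(best, mAll[c]);
      } else {
        acc += (long long)weights[c] * (best - ordCur[oi]);
      }
    }
    if (withBound) {
      // pairwise-incompatibility correction: an incompatible pair (a, b)
      // needs at least m_a + m_b + 1 steps jointly on any tree
      for (size_t p = 0; p < pairA.size(); ++p) {
        const int a = pairA[p], b = pairB[p];
        if (childS[a] == mAll[a] && childS[b] == mAll[b]) {
          acc += std::min(weights[a], weights[b]);
        }
      }
    }
    return acc;
  }

  // --- split helpers (valid right after score()) -------------------------
  bool hasSplit(uint32_t grp, uint32_t placed) const {
    for (int i = 0; i < poLen; ++i) {
      const uint32_t b = below[poNode[i]];
      if (b == grp || (placed & ~b) == grp) return true;
    }
    return false;
  }

  int constraintViolations(uint32_t placed) const {
    int v = 0;
    for (size_t i = 0; i < reqG.size(); ++i) {
      const uint32_t gp = reqG[i] & placed;
      if (popcount32(gp) >= 2 && gp != placed && !hasSplit(gp, placed)) ++v;
    }
    for (size_t i = 0; i < forbG.size(); ++i) {
      const uint32_t gp = forbG[i];
      if ((gp & placed) == gp && placed == (uint32_t)((1u << n) - 1) &&
          hasSplit(gp, placed)) ++v;
    }
    return v;
  }

  // --- leaf insertion on the branch-and-bound workspace -------------------
  void insertLeaf(int leaf, int e) {
    const int w = nextInternal++;
    const int b = ev[e];
    ev[e] = w;
    eu[m] = w; ev[m] = b;   ++m;
    eu[m] = w; ev[m] = leaf; ++m;
  }
  void undoInsert(int e) {
    m -= 2;
    ev[e] = ev[m];
    --nextInternal;
  }

  void initTriplet(int t0, int t1, int t2) {
    nextInternal = n;
    const int w = nextInternal++;
    eu[0] = w; ev[0] = t0;
    eu[1] = w; ev[1] = t1;
    eu[2] = w; ev[2] = t2;
    m = 3;
  }

  // --- exact branch and bound ---------------------------------------------
  void record(long long len) {
    if (len < incumbent) {
      incumbent = len;
      size_t keep = 0;
      for (size_t i = 0; i < outLen.size(); ++i)
        if (outLen[i] <= incumbent + slack) {
          if (keep != i) {
            outEU[keep] = outEU[i]; outEV[keep] = outEV[i];
            outLen[keep] = outLen[i];
          }
          ++keep;
        }
      outEU.resize(keep); outEV.resize(keep); outLen.resize(keep);
    }
    if (len <= incumbent + slack) {
      if ((int)outLen.size() >= maxTrees) { truncated = true; return; }
      outEU.push_back(std::vector<int>(eu, eu + m));
      outEV.push_back(std::vector<int>(ev, ev + m));
      outLen.push_back(len);
    }
  }

  void bnb(int k) {
    ++nodesVisited;
    if (nodesVisited % 65536 == 0) Rcpp::checkUserInterrupt();
    const long long len = fullPass(eu, ev, m);
    const uint32_t placed = (uint32_t)((1u << k) - 1);
    for (size_t i = 0; i < reqG.size(); ++i) {
      const uint32_t gp = reqG[i] & placed;
      if (popcount32(gp) >= 2 && gp != placed && !hasSplit(gp, placed)) return;
    }
    if (k == n) {
      for (size_t i = 0; i < forbG.size(); ++i)
        if (hasSplit(forbG[i], placed)) return;
      record(len);
      return;
    }
    // bound every child from the directional sets, then prune before
    // descending (the recursion reuses the workspace)
    (void)len;
    const int mcur = m;
    long long childBound[96];
    for (int e = 0; e < mcur; ++e) childBound[e] = edgeDelta(e, k, true);
    for (int e = 0; e < mcur; ++e) {
      if (childBound[e] > incumbent + slack) continue;
      insertLeaf(k, e);
      bnb(k + 1);
      undoInsert(e);
    }
  }

  // greedy sequential-addition tree, used as the initial incumbent
  long long greedyLength() {
    initTriplet(0, 1, 2);
    for (int k = 3; k < n; ++k) {
      const int mcur = m;
      long long best = -1; int bestE = 0;
      for (int e = 0; e < mcur; ++e) {
        insertLeaf(k, e);
        const long long s = score(eu, ev, m);
        undoInsert(e);
        if (best < 0 || s < best) { best = s; bestE = e; }
      }
      insertLeaf(k, bestE);
    }
    return score(eu, ev, m);
  }
};

static List enginesOut(Engine& E) {
  const int nt = (int)E.outLen.size();
  List eus(nt), evs(nt);
  NumericVector lens(nt);
  for (int i = 0; i < nt; ++i) {
    eus[i] = IntegerVector(E.outEU[i].begin(), E.outEU[i].end());
    evs[i] = IntegerVector(E.outEV[i].begin(), E.outEV[i].end());
    lens[i] = (double)E.outLen[i];
  }
  long long best = -1;
  for (int i = 0; i < nt; ++i)
    if (best < 0 || E.outLen[i] < best) best = E.outLen[i];
  return List::create(_["best_length"] = (double)best,
                      _["eu"] = eus, _["ev"] = evs, _["lengths"] = lens,
                      _["nodes_visited"] = (double)E.nodesVisited,
                      _["truncated"] = E.truncated);
}

// [[Rcpp::export]]
List cpp_exact_search(IntegerMatrix masks, LogicalVector ordered,
                      IntegerVector weights, int slack, IntegerVector minSteps,
                      IntegerMatrix incompatPairs,
                      IntegerVector reqGroups, IntegerVector forbGroups,
                      int maxTrees, double upperInit) {
  Engine E;
  E.setData(masks, ordered, weights);
  E.slack = slack; E.maxTrees = maxTrees;
  E.mAll.assign(minSteps.begin(), minSteps.end());
  for (int i = 0; i < incompatPairs.nrow(); ++i) {
    E.pairA.push_back(incompatPairs(i, 0));
    E.pairB.push_back(incompatPairs(i, 1));
  }
  for (int i = 0; i < reqGroups.size(); ++i) E.reqG.push_back((uint32_t)reqGroups[i]);
  for (int i = 0; i < forbGroups.size(); ++i) E.forbG.push_back((uint32_t)forbGroups[i]);
  if (E.reqG.empty() && E.forbG.empty()) {
    E.incumbent = E.greedyLength();
  } else {
    E.incumbent = (long long)1 << 60;
  }
  // a known-valid upper bound (e.g. from a heuristic run) tightens pruning;
  // completeness is unaffected because pruning is strict (>)
  if (upperInit >= 0 && (long long)upperInit < E.incumbent) {
    E.incumbent = (long long)upperInit;
  }
  E.initTriplet(0, 1, 2);
  E.bnb(3);
  return enginesOut(E);
}

// check of the incremental edge-delta rule against full rescoring (test hook)
// [[Rcpp::export]]
List cpp_debug_deltas(IntegerMatrix masks, LogicalVector ordered,
                      IntegerVector weights, IntegerVector eu,
                      IntegerVector ev, int leaf) {
  Engine E;
  E.setData(masks, ordered, weights);
  const int mm = eu.size();
  for (int i = 0; i < mm; ++i) { E.eu[i] = eu[i]; E.ev[i] = ev[i]; }
  E.m = mm;
  const long long len = E.fullPass(E.eu, E.ev, mm);
  NumericVector pred(mm), truev(mm);
  for (int e = 0; e < mm; ++e) pred[e] = (double)(len + E.edgeDelta(e, leaf));
  E.nextInternal = 2 * E.n; // scratch ids above any in use
  for (int e = 0; e < mm; ++e) {
    E.insertLeaf(leaf, e);
    truev[e] = (double)E.score(E.eu, E.ev, E.m);
    E.undoInsert(e);
  }
  return List::create(_["len"] = (double)len, _["pred"] = pred,
                      _["true"] = truev);
}

// [[Rcpp::export]]
NumericVector cpp_score_edges(IntegerMatrix masks, LogicalVector ordered,
                              IntegerVector weights, IntegerVector eu,
                              IntegerVector ev) {
  Engine E;
  E.setData(masks, ordered, weights);
  std::vector<int> EU(eu.begin(), eu.end()), EV(ev.begin(), ev.end());
  const long long s = E.score(EU.data(), EV.data(), (int)EU.size());
  return NumericVector::create((double)s);
}

// ---------------------------------------------------------------------------
// TBR neighborhood
// ---------------------------------------------------------------------------

typedef std::pair<std::vector<int>, std::vector<int>> EdgeVecs;

// remove node's (exactly two) incident edges and splice them into one
static bool suppressNode(std::vector<int>& EU, std::vector<int>& EV, int node) {
  int i1 = -1, i2 = -1;
  for (size_t i = 0; i < EU.size(); ++i)
    if (EU[i] == node || EV[i] == node) { if (i1 < 0) i1 = (int)i; else i2 = (int)i; }
  if (i2 < 0) return false;
  const int a = (EU[i1] == node) ? EV[i1] : EU[i1];
  const int b = (EU[i2] == node) ? EV[i2] : EU[i2];
  EU[i1] = a; EV[i1] = b;
  EU.erase(EU.begin() + i2); EV.erase(EV.begin() + i2);
  return true;
}

template <typename CB>
static void tbrNeighbors(const std::vector<int>& EU0, const std::vector<int>& EV0,
                         int nTip, CB cb) {
  const int m = (int)EU0.size();
  for (int i = 0; i < m; ++i) {
    const int a = EU0[i], b = EV0[i];
    std::vector<int> EU, EV;
    for (int j = 0; j < m; ++j)
      if (j != i) { EU.push_back(EU0[j]); EV.push_back(EV0[j]); }
    std::vector<int> freed;
    const bool aLeaf = a < nTip, bLeaf = b < nTip;
    if (!aLeaf) { suppressNode(EU, EV, a); freed.push_back(a); }
    if (!bLeaf) { suppressNode(EU, EV, b); freed.push_back(b); }
    // component membership via BFS from the a-side representative
    std::set<int> compA;
    if (aLeaf) compA.insert(a);
    else {
      // a's former neighbours are now joined; find any node that was adjacent
      // to a in the original tree (other than b)
      int start = -1;
      for (int j = 0; j < m; ++j) {
        if (j == i) continue;
        if (EU0[j] == a) { start = EV0[j]; break; }
        if (EV0[j] == a) { start = EU0[j]; break; }
      }
      std::vector<int> st(1, start);
      compA.insert(start);
      while (!st.empty()) {
        const int u = st.back(); st.pop_back();
        for (size_t j = 0; j < EU.size(); ++j) {
          int v = -1;
          if (EU[j] == u) v = EV[j]; else if (EV[j] == u) v = EU[j];
          if (v >= 0 && !compA.count(v)) { compA.insert(v); st.push_back(v); }
        }
      }
    }
    std::vector<int> edgesA, edgesB;
    for (size_t j = 0; j < EU.size(); ++j) {
      if (compA.count(EU[j])) edgesA.push_back((int)j); else edgesB.push_back((int)j);
    }
    // enumerate reattachments
    std::vector<int> candEU, candEV;
    if (aLeaf && bLeaf) continue; // only possible for n < 4
    if (aLeaf) {
      const int y = freed[0];
      for (size_t qi = 0; qi < edgesB.size(); ++qi) {
        candEU = EU; candEV = EV;
        const int q = edgesB[qi];
        const int q2 = candEV[q];
        candEV[q] = y;
        candEU.push_back(y); candEV.push_back(q2);
        candEU.push_back(y); candEV.push_back(a);
        cb(candEU, candEV);
      }
    } else if (bLeaf) {
      const int x = freed[0];
      for (size_t pi = 0; pi < edgesA.size(); ++pi) {
        candEU = EU; candEV = EV;
        const int p = edgesA[pi];
        const int p2 = candEV[p];
        candEV[p] = x;
        candEU.push_back(x); candEV.push_back(p2);
        candEU.push_back(x); candEV.push_back(b);
        cb(candEU, candEV);
      }
    } else {
      const int x = freed[0], y = freed[1];
      for (size_t pi = 0; pi < edgesA.size(); ++pi)
        for (size_t qi = 0; qi < edgesB.size(); ++qi) {
          candEU = EU; candEV = EV;
          const int p = edgesA[pi], q = edgesB[qi];
          const int p2 = candEV[p]; candEV[p] = x;
          candEU.push_back(x); candEV.push_back(p2);
          const int q2 = candEV[q]; candEV[q] = y;
          candEU.push_back(y); candEV.push_back(q2);
          candEU.push_back(x); candEV.push_back(y);
          cb(candEU, candEV);
        }
    }
  }
}

// canonical split-set signature of a binary tree (rotation invariant)
static std::vector<uint32_t> treeSignature(Engine& E, const std::vector<int>& EU,
                                           const std::vector<int>& EV) {
  E.score(EU.data(), EV.data(), (int)EU.size()); // fills below[]
  const uint32_t full = (uint32_t)((1u << E.n) - 1);
  std::vector<uint32_t> sig;
  for (int i = 0; i < E.poLen; ++i) {
    uint32_t b = E.below[E.poNode[i]];
    if (b & 1u) b = full & ~b;
    const int pc = popcount32(b);
    if (pc >= 2 && pc <= E.n - 2) sig.push_back(b);
  }
  std::sort(sig.begin(), sig.end());
  sig.erase(std::unique(sig.begin(), sig.end()), sig.end());
  return sig;
}

// [[Rcpp::export]]
List cpp_heuristic_search(IntegerMatrix masks, LogicalVector ordered,
                          IntegerVector weights, int nseq, int slack,
                          IntegerVector reqGroups, IntegerVector forbGroups,
                          int poolCap) {
  Engine E;
  E.setData(masks, ordered, weights);
  for (int i = 0; i < reqGroups.size(); ++i) E.reqG.push_back((uint32_t)reqGroups[i]);
  for (int i = 0; i < forbGroups.size(); ++i) E.forbG.push_back((uint32_t)forbGroups[i]);
  const int n = E.n;
  const uint32_t full = (uint32_t)((1u << n) - 1);
  RNGScope scope;

  // penalised score of a complete tree
  auto pscore = [&](const std::vector<int>& EU, const std::vector<int>& EV) -> long long {
    const long long len = E.score(EU.data(), EV.data(), (int)EU.size());
    return len + PEN * E.constraintViolations(full);
  };

  std::vector<std::vector<int>> poolEU, poolEV;
  std::vector<long long> poolScore;
  std::set<std::vector<uint32_t>> seen;
  long long best = (long long)1 << 60;

  auto addToPool = [&](const std::vector<int>& EU, const std::vector<int>& EV,
                       long long sc) -> int {
    const std::vector<uint32_t> sig = treeSignature(E, EU, EV);
    if (seen.count(sig)) return -1;
    seen.insert(sig);
    poolEU.push_back(EU); poolEV.push_back(EV); poolScore.push_back(sc);
    return (int)poolEU.size() - 1;
  };

  for (int rep = 0; rep < nseq; ++rep) {
    // random addition order from R's RNG
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) {
      const int j = (int)(unif_rand() * (i + 1));
      std::swap(ord[i], ord[std::min(j, i)]);
    }
    E.initTriplet(ord[0], ord[1], ord[2]);
    for (int k = 3; k < n; ++k) {
      const int mcur = E.m;
      long long bestS = -1; int bestE = 0;
      const uint32_t placed0 = [&]{ uint32_t p = 0; for (int t = 0; t <= k; ++t) p |= 1u << ord[t]; return p; }();
      for (int e = 0; e < mcur; ++e) {
        E.insertLeaf(ord[k], e);
        long long s = E.score(E.eu, E.ev, E.m);
        s += PEN * E.constraintViolations(placed0);
        E.undoInsert(e);
        if (bestS < 0 || s < bestS) { bestS = s; bestE = e; }
      }
      E.insertLeaf(ord[k], bestE);
    }
    std::vector<int> curEU(E.eu, E.eu + E.m), curEV(E.ev, E.ev + E.m);
    long long cur = pscore(curEU, curEV);
    // first-improvement TBR hill climb
    bool improved = true;
    while (improved) {
      improved = false;
      tbrNeighbors(curEU, curEV, n, [&](std::vector<int>& cu, std::vector<int>& cv) {
        if (improved) return;
        const long long s = pscore(cu, cv);
        if (s < cur) { cur = s; curEU = cu; curEV = cv; improved = true; }
      });
      Rcpp::checkUserInterrupt();
    }
    addToPool(curEU, curEV, cur);
    if (cur < best) best = cur;
  }

  // plateau / slack sweep: closure of the pool under TBR moves that stay
  // within best + slack (collects co-optimal and near-optimal trees)
  size_t qi = 0;
  while (qi < poolEU.size() && (int)poolEU.size() < poolCap) {
    const std::vector<int> EU = poolEU[qi], EV = poolEV[qi];
    if (poolScore[qi] <= best + slack) {
      tbrNeighbors(EU, EV, n, [&](std::vector<int>& cu, std::vector<int>& cv) {
        if ((int)poolEU.size() >= poolCap) return;
        const long long s = pscore(cu, cv);
        if (s > best + slack) return;
        if (s < best) best = s;
        addToPool(cu, cv, s);
      });
    }
    ++qi;
    Rcpp::checkUserInterrupt();
  }

  // keep feasible trees within slack of the best
  List eus, evs;
  std::vector<double> lens;
  for (size_t i = 0; i < poolEU.size(); ++i) {
    if (poolScore[i] >= PEN) continue;               // violates a constraint
    if (poolScore[i] > best + slack) continue;
    eus.push_back(IntegerVector(poolEU[i].begin(), poolEU[i].end()));
    evs.push_back(IntegerVector(poolEV[i].begin(), poolEV[i].end()));
    lens.push_back((double)poolScore[i]);
  }
  return List::create(_["best_length"] = (double)(best >= PEN ? -1 : best),
                      _["eu"] = eus, _["ev"] = evs,
                      _["lengths"] = NumericVector(lens.begin(), lens.end()),
                      _["nodes_visited"] = (double)E.nodesVisited,
                      _["truncated"] = (int)poolEU.size() >= poolCap);
}

// ---------------------------------------------------------------------------
// general scorer: arbitrary rooted edge matrix (polytomies allowed)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_score_tree_general(IntegerMatrix edge, int ntip,
                                     IntegerMatrix masks, LogicalVector ordered) {
  const int ne = edge.nrow();
  int maxNode = 0;
  for (int i = 0; i < ne; ++i)
    maxNode = std::max(maxNode, std::max(edge(i, 0), edge(i, 1)));
  std::vector<std::vector<int>> kids(maxNode + 1);
  std::vector<bool> isChild(maxNode + 1, false);
  for (int i = 0; i < ne; ++i) {
    kids[edge(i, 0)].push_back(edge(i, 1));
    isChild[edge(i, 1)] = true;
  }
  int root = -1;
  for (int v = 1; v <= maxNode; ++v)
    if (!isChild[v] && (v > ntip || !kids[v].empty() || ne == 0)) {
      if (!kids[v].empty()) { root = v; break; }
    }
  if (root < 0) stop("could not locate tree root");
  // postorder
  std::vector<int> po; po.reserve(maxNode);
  std::vector<int> stack(1, root);
  while (!stack.empty()) {
    const int u = stack.back(); stack.pop_back();
    po.push_back(u);
    for (size_t j = 0; j < kids[u].size(); ++j) stack.push_back(kids[u][j]);
  }
  std::reverse(po.begin(), po.end());

  const int nchar = masks.ncol();
  IntegerVector out(nchar);
  std::vector<std::array<int, NSTATE>> cost(maxNode + 1);
  for (int c = 0; c < nchar; ++c) {
    uint32_t un = 0;
    for (int t = 0; t < masks.nrow(); ++t) un |= (uint32_t)masks(t, c);
    int S = 0; for (int s = 0; s < NSTATE; ++s) if (un >> s & 1u) S = s + 1;
    if (S == 0) { out[c] = 0; continue; }
    const bool ord = ordered[c];
    for (size_t pi = 0; pi < po.size(); ++pi) {
      const int u = po[pi];
      if (kids[u].empty()) {
        const uint32_t mk = (uint32_t)masks(u - 1, c); // tips are 1..ntip
        for (int s = 0; s < S; ++s) cost[u][s] = (mk >> s & 1u) ? 0 : BIG;
        continue;
      }
      for (int s = 0; s < S; ++s) cost[u][s] = 0;
      for (size_t j = 0; j < kids[u].size(); ++j) {
        const int v = kids[u][j];
        int mn = BIG;
        for (int t = 0; t < S; ++t) mn = std::min(mn, cost[v][t]);
        for (int s = 0; s < S; ++s) {
          int b;
          if (ord) {
            b = BIG;
            for (int t = 0; t < S; ++t) {
              const int d = s > t ? s - t : t - s;
              b = std::min(b, cost[v][t] + d);
            }
          } else {
            b = std::min(cost[v][s], mn + 1);
          }
          cost[u][s] = std::min(cost[u][s] + b, BIG);
        }
      }
    }
    int best = BIG;
    for (int s = 0; s < S; ++s) best = std::min(best, cost[root][s]);
    out[c] = best;
  }
  return out;
}
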