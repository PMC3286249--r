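// Core parsimony machinery: generalized Sankoff dynamic programming over
// integer cost matrices, plus unrooted-tree rearrangement (SPR/TBR),
// stepwise addition and branch-and-bound enumeration.
//
// Trees are unrooted and binary inside the search engine: nodes are
// 0-based, tips 0..ntip-1, internals ntip..2*ntip-3, adjacency stored as
// three neighbour slots per node (-1 = empty).  Leaf state sets (including
// ambiguity from missing/polymorphic cells) arrive pre-encoded from R as
// per-character leaf cost vectors, so the engine never needs to know the
// difference between a '?' and a bracketed polymorphism.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int BIG = 1 << 28;

struct CharData {
  int k;                  // number of states (0..k-1)
  std::vector<int> cost;  // k*k step costs, cost[a*k+b]
  std::vector<int> leaf;  // ntip*k leaf cost vectors
};

struct Problem {
  int ntip, ncha, kmax;
  std::vector<CharData> chars;
  std::vector<long long> w;  // per-character weights
};

typedef std::vector<std::array<int, 3> > Adj;

static Problem makeProblem(List chars, IntegerVector weights, int ntip) {
  Problem P;
  P.ntip = ntip;
  P.ncha = chars.size();
  P.kmax = 1;
  for (int j = 0; j < P.ncha; j++) {
    List cj = chars[j];
    CharData cd;
    cd.k = as<int>(cj["k"]);
    IntegerMatrix cm = cj["cost"];
    IntegerMatrix lf = cj["leaf"];
    cd.cost.assign(cd.k * cd.k, 0);
    for (int a = 0; a < cd.k; a++)
      for (int b = 0; b < cd.k; b++) cd.cost[a * cd.k + b] = cm(a, b);
    cd.leaf.assign(ntip * cd.k, 0);
    for (int t = 0; t < ntip; t++)
      for (int s = 0; s < cd.k; s++) cd.leaf[t * cd.k + s] = lf(t, s);
    if (cd.k > P.kmax) P.kmax = cd.k;
    P.chars.push_back(cd);
  }
  P.w.assign(weights.begin(), weights.end());
  return P;
}

static inline int slotOf(const Adj &A, int v, int nb) {
  for (int i = 0; i < 3; i++)
    if (A[v][i] == nb) return i;
  return -1;
}

static inline void replaceNb(Adj &A, int v, int oldn, int newn) {
  for (int i = 0; i < 3; i++)
    if (A[v][i] == oldn) { A[v][i] = newn; return; }
}

static inline bool isTip(int v, int ntip) { return v < ntip; }

// ---------------------------------------------------------------------------
// Traversal orders within a connected component of the adjacency structure.

struct Order {
  // nodes in preorder; parent[i] gives the predecessor of nodes[i] (-1 for root)
  std::vector<int> nodes, parent;
  // undirected edges (a,b) of the component in discovery order
  std::vector<std::pair<int, int> > edges;
};

static Order computeOrder(const Adj &A, int start, int ntip) {
  Order O;
  std::vector<std::pair<int, int> > stack;  // (node, parent)
  stack.push_back(std::make_pair(start, -1));
  while (!stack.empty()) {
    std::pair<int, int> np = stack.back();
    stack.pop_back();
    O.nodes.push_back(np.first);
    O.parent.push_back(np.second);
    if (np.second >= 0) O.edges.push_back(std::make_pair(np.second, np.first));
    for (int i = 2; i >= 0; i--) {
      int nb = A[np.first][i];
      if (nb >= 0 && nb != np.second) stack.push_back(std::make_pair(nb, np.first));
    }
  }
  return O;
}

// ---------------------------------------------------------------------------
// Directed subtree cost vectors.
//
// U[v][slot] (flattened v*3+slot, each of length k) is the minimal cost of
// the part of the component containing v once the edge towards neighbour
// A[v][slot] is removed, conditional on the state of v.

static void computeU(const Adj &A, const Order &O, const CharData &cd,
                     int ntip, std::vector<int> &U) {
  const int k = cd.k;
  const int n = (int)O.nodes.size();
  // down pass: postorder = reverse preorder
  for (int idx = n - 1; idx >= 1; idx--) {
    int v = O.nodes[idx], p = O.parent[idx];
    int sp = slotOf(A, v, p);
    int *uv = &U[(v * 3 + sp) * k];
    if (isTip(v, ntip)) {
      for (int s = 0; s < k; s++) uv[s] = cd.leaf[v * k + s];
    } else {
      for (int s = 0; s < k; s++) uv[s] = 0;
      for (int i = 0; i < 3; i++) {
        int c = A[v][i];
        if (i == sp || c < 0) continue;
        const int *uc = &U[(c * 3 + slotOf(A, c, v)) * k];
        for (int s = 0; s < k; s++) {
          int best = BIG;
          const int *row = &cd.cost[s * k];
          for (int t = 0; t < k; t++) {
            int val = row[t] + uc[t];
            if (val < best) best = val;
          }
          uv[s] += best;
        }
      }
    }
  }
  // up pass: preorder, fill all remaining slots
  for (int idx = 0; idx < n; idx++) {
    int v = O.nodes[idx], p = O.parent[idx];
    int sp = (p >= 0) ? slotOf(A, v, p) : -1;
    for (int j = 0; j < 3; j++) {
      if (A[v][j] < 0 || j == sp) continue;
      int *uv = &U[(v * 3 + j) * k];
      if (isTip(v, ntip)) {
        for (int s = 0; s < k; s++) uv[s] = cd.leaf[v * k + s];
        continue;
      }
      for (int s = 0; s < k; s++) uv[s] = 0;
      for (int i = 0; i < 3; i++) {
        int c = A[v][i];
        if (i == j || c < 0) continue;
        const int *uc = &U[(c * 3 + slotOf(A, c, v)) * k];
        for (int s = 0; s < k; s++) {
          int best = BIG;
          const int *row = &cd.cost[s * k];
          for (int t = 0; t < k; t++) {
            int val = row[t] + uc[t];
            if (val < best) best = val;
          }
          uv[s] += best;
        }
      }
    }
  }
}

// Midpoint profile of edge (x,y): P(s) = cost of the whole component when a
// new node with state s is inserted on that edge.
static void edgeProfile(const Adj &A, const CharData &cd,
                        const std::vector<int> &U, int x, int y,
                        std::vector<int> &out) {
  const int k = cd.k;
  const int *ux = &U[(x * 3 + slotOf(A, x, y)) * k];
  const int *uy = &U[(y * 3 + slotOf(A, y, x)) * k];
  for (int s = 0; s < k; s++) {
    int bx = BIG, by = BIG;
    const int *row = &cd.cost[s * k];
    for (int t = 0; t < k; t++) {
      int vx = row[t] + ux[t];
      if (vx < bx) bx = vx;
      int vy = row[t] + uy[t];
      if (vy < by) by = vy;
    }
    out[s] = bx + by;
  }
}

// minimal cost of joining two state profiles by a single edge
static inline long long joinProfiles(const CharData &cd, const std::vector<int> &P1,
                                     const std::vector<int> &P2) {
  const int k = cd.k;
  int best = BIG;
  for (int s = 0; s < k; s++) {
    const int *row = &cd.cost[s * k];
    for (int t = 0; t < k; t++) {
      int val = P1[s] + row[t] + P2[t];
      if (val < best) best = val;
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Whole-tree score (weighted) and per-character scores of the current
// binary unrooted adjacency.  Rooted at tip `root0`.

static void scoreAdj(const Adj &A, const Problem &P, int root0,
                     std::vector<long long> &perchar) {
  int r = A[root0][0];
  Order O = computeOrder(A, root0, P.ntip);
  std::vector<int> U;
  perchar.assign(P.ncha, 0);
  for (int j = 0; j < P.ncha; j++) {
    const CharData &cd = P.chars[j];
    const int k = cd.k;
    U.assign(A.size() * 3 * k, 0);
    // down pass only, rooted at tip root0 (its neighbour r carries the rest)
    const int n = (int)O.nodes.size();
    for (int idx = n - 1; idx >= 1; idx--) {
      int v = O.nodes[idx], p = O.parent[idx];
      int sp = slotOf(A, v, p);
      int *uv = &U[(v * 3 + sp) * k];
      if (isTip(v, P.ntip)) {
        for (int s = 0; s < k; s++) uv[s] = cd.leaf[v * k + s];
      } else {
        for (int s = 0; s < k; s++) uv[s] = 0;
        for (int i = 0; i < 3; i++) {
          int c = A[v][i];
          if (i == sp || c < 0) continue;
          const int *uc = &U[(c * 3 + slotOf(A, c, v)) * k];
          for (int s = 0; s < k; s++) {
            int best = BIG;
            const int *row = &cd.cost[s * k];
            for (int t = 0; t < k; t++) {
              int val = row[t] + uc[t];
              if (val < best) best = val;
            }
            uv[s] += best;
          }
        }
      }
    }
    const int *ur = &U[(r * 3 + slotOf(A, r, root0)) * k];
    int best = BIG;
    for (int s = 0; s < k; s++) {
      int leafc = cd.leaf[root0 * k + s];
      if (leafc >= BIG) continue;
      const int *row = &cd.cost[s * k];
      for (int t = 0; t < k; t++) {
        int val = leafc + row[t] + ur[t];
        if (val < best) best = val;
      }
    }
    perchar[j] = best;
  }
}

static long long totalScore(const Adj &A, const Problem &P) {
  std::vector<long long> pc;
  scoreAdj(A, P, 0, pc);
  long long s = 0;
  for (int j = 0; j < P.ncha; j++) s += P.w[j] * pc[j];
  return s;
}

// ---------------------------------------------------------------------------
// ape interchange

static Adj edgeToAdj(IntegerMatrix edge, int nnode) {
  Adj A(nnode);
  for (int v = 0; v < nnode; v++) A[v] = { { -1, -1, -1 } };
  for (int e = 0; e < edge.nrow(); e++) {
    int a = edge(e, 0) - 1, b = edge(e, 1) - 1;
    for (int i = 0; i < 3; i++) if (A[a][i] < 0) { A[a][i] = b; break; }
    for (int i = 0; i < 3; i++) if (A[b][i] < 0) { A[b][i] = a; break; }
  }
  return A;
}

// Export as an ape edge matrix: root the unrooted tree at the internal node
// adjacent to tip 0 (giving the conventional basal trifurcation), renumber
// internals in preorder.
static IntegerMatrix adjToEdge(const Adj &A, int ntip) {
  int root = A[0][0];
  Order O = computeOrder(A, root, ntip);
  std::vector<int> newid(A.size(), -1);
  int nxt = ntip + 1;
  for (size_t i = 0; i < O.nodes.size(); i++) {
    int v = O.nodes[i];
    newid[v] = isTip(v, ntip) ? v + 1 : nxt++;
  }
  IntegerMatrix edge((int)O.edges.size(), 2);
  for (size_t e = 0; e < O.edges.size(); e++) {
    edge((int)e, 0) = newid[O.edges[e].first];
    edge((int)e, 1) = newid[O.edges[e].second];
  }
  return edge;
}

// ---------------------------------------------------------------------------
// One first-improvement rearrangement sweep (SPR or TBR).

struct Side {
  bool single;                  // component is a lone tip
  int tip;                      // that tip if single
  int repr;                     // any node inside the component otherwise
  int mergedIdx;                // index (in edges) of the edge created by
                                // suppressing the cut endpoint, -1 if single
  Order O;
  std::vector<std::pair<int, int> > edges;
};

static void validateAdj(const Adj &A, int ntip, int u, int v, int fi, int gi) {
  for (int x = 0; x < (int)A.size(); x++) {
    int deg = 0;
    for (int i = 0; i < 3; i++) {
      int nb = A[x][i];
      if (nb < 0) continue;
      deg++;
      if (nb >= (int)A.size())
        Rcpp::stop("node %d neighbour %d out of range (cut %d-%d f=%d g=%d)", x, nb, u, v, fi, gi);
      if (slotOf(A, nb, x) < 0)
        Rcpp::stop("asymmetric link %d->%d (cut %d-%d f=%d g=%d)", x, nb, u, v, fi, gi);
    }
    if (x < ntip && deg != 1 && deg != 0)
      Rcpp::stop("tip %d degree %d (cut %d-%d f=%d g=%d)", x, deg, u, v, fi, gi);
    if (x >= ntip && deg != 3 && deg != 0)
      Rcpp::stop("internal %d degree %d (cut %d-%d f=%d g=%d)", x, deg, u, v, fi, gi);
  }
}

static bool sweepOnce(Adj &A, const Problem &P, long long &curLen, bool tbr,
                      std::vector<int> &Ubuf) {
  Order full = computeOrder(A, 0, P.ntip);
  std::vector<std::pair<int, int> > cutEdges = full.edges;
  const int nnode = (int)A.size();

  std::vector<int> PAf, PBf;
  std::vector<long long> totals;

  for (size_t ce = 0; ce < cutEdges.size(); ce++) {
    int u = cutEdges[ce].first, v = cutEdges[ce].second;
    // build the cut-and-suppressed adjacency
    Adj Acut = A;
    replaceNb(Acut, u, v, -1);
    replaceNb(Acut, v, u, -1);
    int ua = -1, ub = -1, va = -1, vb = -1;
    Side SA, SB;
    if (isTip(u, P.ntip)) {
      SA.single = true; SA.tip = u; SA.mergedIdx = -1;
    } else {
      for (int i = 0; i < 3; i++) {
        int nb = Acut[u][i];
        if (nb >= 0) { if (ua < 0) ua = nb; else ub = nb; }
      }
      replaceNb(Acut, ua, u, ub);
      replaceNb(Acut, ub, u, ua);
      Acut[u] = { { -1, -1, -1 } };
      SA.single = false;
      SA.O = computeOrder(Acut, ua, P.ntip);
      SA.edges = SA.O.edges;
      // a 2-node component has the single merged edge; otherwise find (ua,ub)
      SA.mergedIdx = -1;
      for (size_t i = 0; i < SA.edges.size(); i++) {
        std::pair<int, int> &f = SA.edges[i];
        if ((f.first == ua && f.second == ub) || (f.first == ub && f.second == ua)) {
          SA.mergedIdx = (int)i;
          break;
        }
      }
    }
    if (isTip(v, P.ntip)) {
      SB.single = true; SB.tip = v; SB.mergedIdx = -1;
    } else {
      for (int i = 0; i < 3; i++) {
        int nb = Acut[v][i];
        if (nb >= 0) { if (va < 0) va = nb; else vb = nb; }
      }
      replaceNb(Acut, va, v, vb);
      replaceNb(Acut, vb, v, va);
      Acut[v] = { { -1, -1, -1 } };
      SB.single = false;
      SB.O = computeOrder(Acut, va, P.ntip);
      SB.edges = SB.O.edges;
      SB.mergedIdx = -1;
      for (size_t i = 0; i < SB.edges.size(); i++) {
        std::pair<int, int> &g = SB.edges[i];
        if ((g.first == va && g.second == vb) || (g.first == vb && g.second == va)) {
          SB.mergedIdx = (int)i;
          break;
        }
      }
    }
    if (SA.single && SB.single) continue;  // 2-taxon tree, nothing to do

    int nA = SA.single ? 1 : (int)SA.edges.size();
    int nB = SB.single ? 1 : (int)SB.edges.size();

    // enumerate candidate reconnections
    std::vector<std::pair<int, int> > cand;  // (fIdx or -1, gIdx or -1)
    for (int fi = 0; fi < nA; fi++) {
      int f = SA.single ? -1 : fi;
      for (int gi = 0; gi < nB; gi++) {
        int g = SB.single ? -1 : gi;
        if (f == SA.mergedIdx || SA.single) {
          if (g == SB.mergedIdx || SB.single) continue;  // identity
        }
        if (!tbr) {
          bool aKeep = SA.single || f == SA.mergedIdx;
          bool bKeep = SB.single || g == SB.mergedIdx;
          if (!aKeep && !bKeep) continue;  // TBR-only move
        }
        cand.push_back(std::make_pair(f, g));
      }
    }
    if (cand.empty()) continue;
    totals.assign(cand.size(), 0);

    for (int j = 0; j < P.ncha; j++) {
      const CharData &cd = P.chars[j];
      if (P.w[j] == 0 || cd.k == 1) continue;
      const int k = cd.k;
      Ubuf.assign(nnode * 3 * k, 0);
      std::vector<std::vector<int> > profA(nA, std::vector<int>(k));
      std::vector<std::vector<int> > profB(nB, std::vector<int>(k));
      if (SA.single) {
        for (int s = 0; s < k; s++) profA[0][s] = cd.leaf[SA.tip * k + s];
      } else {
        computeU(Acut, SA.O, cd, P.ntip, Ubuf);
        for (int i = 0; i < nA; i++)
          edgeProfile(Acut, cd, Ubuf, SA.edges[i].first, SA.edges[i].second, profA[i]);
      }
      if (SB.single) {
        for (int s = 0; s < k; s++) profB[0][s] = cd.leaf[SB.tip * k + s];
      } else {
        computeU(Acut, SB.O, cd, P.ntip, Ubuf);
        for (int i = 0; i < nB; i++)
          edgeProfile(Acut, cd, Ubuf, SB.edges[i].first, SB.edges[i].second, profB[i]);
      }
      for (size_t c = 0; c < cand.size(); c++) {
        int fi = cand[c].first < 0 ? 0 : cand[c].first;
        int gi = cand[c].second < 0 ? 0 : cand[c].second;
        totals[c] += P.w[j] * joinProfiles(cd, profA[fi], profB[gi]);
      }
    }

    for (size_t c = 0; c < cand.size(); c++) {
      if (totals[c] < curLen) {
        // apply the move on the original adjacency
        replaceNb(A, u, v, -1);
        replaceNb(A, v, u, -1);
        int attachA, attachB;
        if (SA.single) {
          attachA = SA.tip;
        } else {
          replaceNb(A, ua, u, ub);
          replaceNb(A, ub, u, ua);
          A[u] = { { -1, -1, -1 } };
          std::pair<int, int> f = SA.edges[cand[c].first];
          replaceNb(A, f.first, f.second, u);
          replaceNb(A, f.second, f.first, u);
          A[u][0] = f.first; A[u][1] = f.second;
          attachA = u;
        }
        if (SB.single) {
          attachB = SB.tip;
        } else {
          replaceNb(A, va, v, vb);
          replaceNb(A, vb, v, va);
          A[v] = { { -1, -1, -1 } };
          std::pair<int, int> g = SB.edges[cand[c].second];
          replaceNb(A, g.first, g.second, v);
          replaceNb(A, g.second, g.first, v);
          A[v][0] = g.first; A[v][1] = g.second;
          attachB = v;
        }
        for (int i = 0; i < 3; i++) if (A[attachA][i] < 0) { A[attachA][i] = attachB; break; }
        for (int i = 0; i < 3; i++) if (A[attachB][i] < 0) { A[attachB][i] = attachA; break; }
        validateAdj(A, P.ntip, u, v, cand[c].first, cand[c].second);
        curLen = totals[c];
        return true;
      }
    }
  }
  return false;
}

// ---------------------------------------------------------------------------
// Exported functions

// [[Rcpp::export]]
IntegerVector cpp_score_tree(IntegerMatrix edge, int ntip, int nnode,
                             List chars, IntegerVector weights) {
  Problem P = makeProblem(chars, weights, ntip);
  // children lists; works for arbitrary degrees and rootings
  std::vector<std::vector<int> > kids(nnode);
  std::vector<bool> isChild(nnode, false);
  for (int e = 0; e < edge.nrow(); e++) {
    kids[edge(e, 0) - 1].push_back(edge(e, 1) - 1);
    isChild[edge(e, 1) - 1] = true;
  }
  int root = -1;
  for (int v = 0; v < nnode; v++)
    if (!isChild[v] && (!kids[v].empty() || nnode == 1)) { root = v; break; }
  // postorder
  std::vector<int> order, stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t i = 0; i < kids[v].size(); i++) stack.push_back(kids[v][i]);
  }
  std::reverse(order.begin(), order.end());
  IntegerVector out(P.ncha);
  for (int j = 0; j < P.ncha; j++) {
    const CharData &cd = P.chars[j];
    const int k = cd.k;
    std::vector<int> V(nnode * k, 0);
    for (size_t oi = 0; oi < order.size(); oi++) {
      int v = order[oi];
      int *vv = &V[v * k];
      if (kids[v].empty()) {
        for (int s = 0; s < k; s++) vv[s] = cd.leaf[v * k + s];
        continue;
      }
      for (int s = 0; s < k; s++) vv[s] = 0;
      for (size_t ci = 0; ci < kids[v].size(); ci++) {
        const int *vc = &V[kids[v][ci] * k];
        for (int s = 0; s < k; s++) {
          int best = BIG;
          const int *row = &cd.cost[s * k];
          for (int t = 0; t < k; t++) {
            int val = row[t] + vc[t];
            if (val < best) best = val;
          }
          vv[s] += best;
        }
      }
    }
    int best = BIG;
    for (int s = 0; s < k; s++) {
      int val = V[root * k + s];
      if (root < ntip) val += cd.leaf[root * k + s];
      if (val < best) best = val;
    }
    out[j] = best;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_search(IntegerMatrix edge, int ntip, List chars, IntegerVector weights,
                bool tbr, int maxMoves) {
  Problem P = makeProblem(chars, weights, ntip);
  Adj A = edgeToAdj(edge, 2 * ntip - 2);
  long long curLen = totalScore(A, P);
  std::vector<int> Ubuf;
  int moves = 0;
  while (moves < maxMoves) {
    Rcpp::checkUserInterrupt();
    if (!sweepOnce(A, P, curLen, tbr, Ubuf)) break;
    moves++;
  }
  return List::create(_["edge"] = adjToEdge(A, ntip),
                      _["length"] = (double)curLen,
                      _["moves"] = moves);
}

// [[Rcpp::export]]
List cpp_random_addition(IntegerVector order0, List chars, IntegerVector weights) {
  const int ntip = order0.size();
  Problem P = makeProblem(chars, weights, ntip);
  Adj A(2 * ntip - 2);
  for (size_t i = 0; i < A.size(); i++) A[i] = { { -1, -1, -1 } };
  int h = ntip;  // first internal node
  int t0 = order0[0], t1 = order0[1], t2 = order0[2];
  A[h] = { { t0, t1, t2 } };
  A[t0][0] = h; A[t1][0] = h; A[t2][0] = h;
  for (int nxt = 3; nxt < ntip; nxt++) {
    int tip = order0[nxt];
    int newInt = ntip + nxt - 2;
    Order O = computeOrder(A, t0, ntip);
    long long bestLen = -1;
    int bestE = -1;
    for (size_t e = 0; e < O.edges.size(); e++) {
      int x = O.edges[e].first, y = O.edges[e].second;
      // insert
      replaceNb(A, x, y, newInt);
      replaceNb(A, y, x, newInt);
      A[newInt] = { { x, y, tip } };
      A[tip][0] = newInt;
      long long len = totalScore(A, P);
      // undo
      replaceNb(A, x, newInt, y);
      replaceNb(A, y, newInt, x);
      A[newInt] = { { -1, -1, -1 } };
      A[tip][0] = -1;
      if (bestE < 0 || len < bestLen) { bestLen = len; bestE = (int)e; }
    }
    int x = O.edges[bestE].first, y = O.edges[bestE].second;
    replaceNb(A, x, y, newInt);
    replaceNb(A, y, x, newInt);
    A[newInt] = { { x, y, tip } };
    A[tip][0] = newInt;
  }
  return List::create(_["edge"] = adjToEdge(A, ntip),
                      _["length"] = (double)totalScore(A, P));
}

struct BabState {
  Problem *P;
  int ntip;
  long long best;
  std::vector<IntegerMatrix> trees;
};

static void babRec(Adj &A, int nextTip, BabState &st) {
  long long partial = totalScore(A, *st.P);
  if (partial > st.best) return;
  if (nextTip == st.ntip) {
    if (partial < st.best) {
      st.best = partial;
      st.trees.clear();
    }
    st.trees.push_back(adjToEdge(A, st.ntip));
    return;
  }
  Rcpp::checkUserInterrupt();
  int tip = nextTip;
  int newInt = st.ntip + nextTip - 2;
  Order O = computeOrder(A, 0, st.ntip);
  std::vector<std::pair<int, int> > edges = O.edges;
  for (size_t e = 0; e < edges.size(); e++) {
    int x = edges[e].first, y = edges[e].second;
    replaceNb(A, x, y, newInt);
    replaceNb(A, y, x, newInt);
    A[newInt] = { { x, y, tip } };
    A[tip][0] = newInt;
    babRec(A, nextTip + 1, st);
    replaceNb(A, x, newInt, y);
    replaceNb(A, y, newInt, x);
    A[newInt] = { { -1, -1, -1 } };
    A[tip][0] = -1;
  }
}

// [[Rcpp::export]]
List cpp_bab(int ntip, List chars, IntegerVector weights) {
  Problem P = makeProblem(chars, weights, ntip);
  Adj A(2 * ntip - 2);
  for (size_t i = 0; i < A.size(); i++) A[i] = { { -1, -1, -1 } };
  int h = ntip;
  A[h] = { { 0, 1, 2 } };
  A[0][0] = h; A[1][0] = h; A[2][0] = h;
  BabState st;
  st.P = &P;
  st.ntip = ntip;
  st.best = (long long)BIG * 4;
  babRec(A, 3, st);
  List trees(st.trees.size());
  for (size_t i = 0; i < st.trees.size(); i++) trees[i] = st.trees[i];
  return List::create(_["edges"] = trees, _["length"] = (double)st.best);
}
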