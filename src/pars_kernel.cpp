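#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Parsimony length of a binary tree over a set of discrete characters.
//
// Node ids are arbitrary positive integers; a node id <= nrow(tip_bits) is a
// terminal and indexes its data row directly.  `edge` holds one row per
// branch in either orientation; the tree is oriented internally away from
// `root` (an internal node of degree 2 or 3).  Unordered characters use
// Fitch state-set folding on bitmasks; ordered characters use Farris
// interval folding with |i - j| costs.  Children are folded pairwise, which
// is exact for binary trees (a degree-3 root is equivalent to rooting along
// one of its edges).
//
// tip_bits: bitmask of admissible states per cell (missing = full range).
// tip_lo / tip_hi: interval bounds per cell for the ordered model.

// [[Rcpp::export]]
List C_pars_length(IntegerMatrix edge, int root,
                   IntegerMatrix tip_bits,
                   IntegerMatrix tip_lo, IntegerMatrix tip_hi,
                   LogicalVector ordered, NumericVector weights) {
  const int ntip = tip_bits.nrow();
  const int nchar = tip_bits.ncol();
  const int nedge = edge.nrow();

  int max_id = root;
  for (int i = 0; i < nedge; ++i) {
    if (edge(i, 0) > max_id) max_id = edge(i, 0);
    if (edge(i, 1) > max_id) max_id = edge(i, 1);
  }

  // undirected adjacency in CSR form
  std::vector<int> deg(max_id + 1, 0);
  for (int i = 0; i < nedge; ++i) { deg[edge(i, 0)]++; deg[edge(i, 1)]++; }
  std::vector<int> off(max_id + 2, 0);
  for (int v = 0; v <= max_id; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(2 * nedge);
  {
    std::vector<int> fill(max_id + 1, 0);
    for (int i = 0; i < nedge; ++i) {
      int a = edge(i, 0), b = edge(i, 1);
      adj[off[a] + fill[a]++] = b;
      adj[off[b] + fill[b]++] = a;
    }
  }

  // DFS from root: record postorder (children before parents) and parents
  std::vector<int> order;
  order.reserve(max_id + 1);
  std::vector<int> parent(max_id + 1, 0);
  {
    std::vector<int> stack;
    stack.push_back(root);
    parent[root] = -1;
    std::vector<int> pre;
    pre.reserve(max_id + 1);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      pre.push_back(v);
      for (int k = off[v]; k < off[v + 1]; ++k) {
        int u = adj[k];
        if (u != parent[v]) { parent[u] = v; stack.push_back(u); }
      }
    }
    order.assign(pre.rbegin(), pre.rend());
  }

  IntegerVector steps(nchar);
  double total = 0.0;
  std::vector<uint32_t> mask(max_id + 1);
  std::vector<int> lo(max_id + 1), hi(max_id + 1);

  for (int c = 0; c < nchar; ++c) {
    int s = 0;
    if (!ordered[c]) {
      for (size_t idx = 0; idx < order.size(); ++idx) {
        int v = order[idx];
        if (v <= ntip) {
          mask[v] = (uint32_t) tip_bits(v - 1, c);
        } else {
          uint32_t acc = 0;
          bool first = true;
          for (int k = off[v]; k < off[v + 1]; ++k) {
            int u = adj[k];
            if (u == parent[v]) continue;
            uint32_t m = mask[u];
            if (first) { acc = m; first = false; }
            else {
              uint32_t inter = acc & m;
              if (inter) acc = inter; else { acc = acc | m; ++s; }
            }
          }
          mask[v] = acc;
        }
      }
    } else {
      for (size_t idx = 0; idx < order.size(); ++idx) {
        int v = order[idx];
        if (v <= ntip) {
          lo[v] = tip_lo(v - 1, c);
          hi[v] = tip_hi(v - 1, c);
        } else {
          int alo = 0, ahi = 0;
          bool first = true;
          for (int k = off[v]; k < off[v + 1]; ++k) {
            int u = adj[k];
            if (u == parent[v]) continue;
            int blo = lo[u], bhi = hi[u];
            if (first) { alo = blo; ahi = bhi; first = false; }
            else {
              int ilo = alo > blo ? alo : blo;
              int ihi = ahi < bhi ? ahi : bhi;
              if (ilo <= ihi) { alo = ilo; ahi = ihi; }
              else {
                s += ilo - ihi;  // gap between the two intervals
                int nlo = ahi < bhi ? ahi : bhi;
                int nhi = alo > blo ? alo : blo;
                alo = nlo; ahi = nhi;
              }
            }
          }
          lo[v] = alo; hi[v] = ahi;
        }
      }
    }
    steps[c] = s;
    total += weights[c] * s;
  }

  return List::create(_["per_char_steps"] = steps, _["total_length"] = total);
}

// ---------------------------------------------------------------------
// Shared internal evaluator with early abort: returns the (penalized)
// tree length, or `bound` as soon as the partial sum reaches it.  The
// optional constraint column (binary split marker) adds `penalty` when
// the tree contains the marked bipartition (its Fitch steps equal 1).

namespace {

struct TipData {
  const IntegerMatrix *bits, *lo, *hi;
  const LogicalVector *ordered;
  const NumericVector *weights;
  const std::vector<int> *constraint;  // empty if unused
  double penalty;
};

double eval_edges(const std::vector<int> &e1, const std::vector<int> &e2,
                  int root, const TipData &td, double bound) {
  const int ntip = td.bits->nrow();
  const int nchar = td.bits->ncol();
  const int nedge = (int) e1.size();

  int max_id = root;
  for (int i = 0; i < nedge; ++i) {
    if (e1[i] > max_id) max_id = e1[i];
    if (e2[i] > max_id) max_id = e2[i];
  }
  std::vector<int> deg(max_id + 1, 0);
  for (int i = 0; i < nedge; ++i) { deg[e1[i]]++; deg[e2[i]]++; }
  std::vector<int> off(max_id + 2, 0);
  for (int v = 0; v <= max_id; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(2 * nedge);
  std::vector<int> fill(max_id + 1, 0);
  for (int i = 0; i < nedge; ++i) {
    adj[off[e1[i]] + fill[e1[i]]++] = e2[i];
    adj[off[e2[i]] + fill[e2[i]]++] = e1[i];
  }
  std::vector<int> parent(max_id + 1, 0), order;
  order.reserve(max_id + 1);
  {
    std::vector<int> stack;
    stack.push_back(root);
    parent[root] = -1;
    std::vector<int> pre;
    pre.reserve(max_id + 1);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      pre.push_back(v);
      for (int k = off[v]; k < off[v + 1]; ++k)
        if (adj[k] != parent[v]) { parent[adj[k]] = v; stack.push_back(adj[k]); }
    }
    order.assign(pre.rbegin(), pre.rend());
  }

  std::vector<uint32_t> mask(max_id + 1);
  std::vector<int> lo(max_id + 1), hi(max_id + 1);
  double total = 0.0;

  for (int c = 0; c < nchar; ++c) {
    int s = 0;
    if (!(*td.ordered)[c]) {
      for (size_t idx = 0; idx < order.size(); ++idx) {
        int v = order[idx];
        if (v <= ntip) mask[v] = (uint32_t)(*td.bits)(v - 1, c);
        else {
          uint32_t acc = 0; bool first = true;
          for (int k = off[v]; k < off[v + 1]; ++k) {
            int u = adj[k];
            if (u == parent[v]) continue;
            if (first) { acc = mask[u]; first = false; }
            else {
              uint32_t in = acc & mask[u];
              if (in) acc = in; else { acc |= mask[u]; ++s; }
            }
          }
          mask[v] = acc;
        }
      }
    } else {
      for (size_t idx = 0; idx < order.size(); ++idx) {
        int v = order[idx];
        if (v <= ntip) { lo[v] = (*td.lo)(v - 1, c); hi[v] = (*td.hi)(v - 1, c); }
        else {
          int alo = 0, ahi = 0; bool first = true;
          for (int k = off[v]; k < off[v + 1]; ++k) {
            int u = adj[k];
            if (u == parent[v]) continue;
            if (first) { alo = lo[u]; ahi = hi[u]; first = false; }
            else {
              int ilo = alo > lo[u] ? alo : lo[u];
              int ihi = ahi < hi[u] ? ahi : hi[u];
              if (ilo <= ihi) { alo = ilo; ahi = ihi; }
              else {
                s += ilo - ihi;
                int nlo = ahi < hi[u] ? ahi : hi[u];
                int nhi = alo > lo[u] ? alo : lo[u];
                alo = nlo; ahi = nhi;
              }
            }
          }
          lo[v] = alo; hi[v] = ahi;
        }
      }
    }
    total += (*td.weights)[c] * s;
    if (total >= bound) return bound;
  }

  if (td.constraint && !td.constraint->empty()) {
    // Fitch steps of the constraint split: 1 iff the tree contains it
    int s = 0;
    for (size_t idx = 0; idx < order.size(); ++idx) {
      int v = order[idx];
      if (v <= ntip) mask[v] = (uint32_t)(*td.constraint)[v - 1];
      else {
        uint32_t acc = 0; bool first = true;
        for (int k = off[v]; k < off[v + 1]; ++k) {
          int u = adj[k];
          if (u == parent[v]) continue;
          if (first) { acc = mask[u]; first = false; }
          else {
            uint32_t in = acc & mask[u];
            if (in) acc = in; else { acc |= mask[u]; ++s; }
          }
        }
        mask[v] = acc;
      }
    }
    if (s == 1) {
      total += td.penalty;
      if (total >= bound) return bound;
    }
  }
  return total;
}

}  // namespace

// Score inserting `tip` on every branch of the tree: returns one length
// per edge row.  Used by stepwise addition.

// [[Rcpp::export]]
NumericVector C_insertion_lengths(IntegerMatrix edge, int root, int tip,
                                  int new_internal,
                                  IntegerMatrix tip_bits,
                                  IntegerMatrix tip_lo, IntegerMatrix tip_hi,
                                  LogicalVector ordered,
                                  NumericVector weights) {
  const int nedge = edge.nrow();
  TipData td{&tip_bits, &tip_lo, &tip_hi, &ordered, &weights, nullptr, 0.0};
  std::vector<int> e1(nedge + 2), e2(nedge + 2);
  NumericVector out(nedge);
  for (int k = 0; k < nedge; ++k) {
    for (int i = 0; i < nedge; ++i) { e1[i] = edge(i, 0); e2[i] = edge(i, 1); }
    // replace edge k = (u,v) with (u,w), add (w,v), (w,tip)
    int u = edge(k, 0), v = edge(k, 1);
    e1[k] = u; e2[k] = new_internal;
    e1[nedge] = new_internal; e2[nedge] = v;
    e1[nedge + 1] = new_internal; e2[nedge + 1] = tip;
    out[k] = eval_edges(e1, e2, root, td, R_PosInf);
  }
  return out;
}

// Full first-improvement TBR descent.  Sweeps every bisection of every
// branch and every reconnection of the two parts, adopts the first
// strictly better neighbor, and repeats until no neighbor improves.
// Candidate evaluation aborts as soon as the running length reaches the
// current best.  An optional constraint bipartition (values 1/2 per tip)
// adds `penalty` to any tree containing it (converse-constraint Bremer
// searches).

// [[Rcpp::export]]
List C_tbr_descend(IntegerMatrix edge, int root,
                   IntegerMatrix tip_bits,
                   IntegerMatrix tip_lo, IntegerMatrix tip_hi,
                   LogicalVector ordered, NumericVector weights,
                   IntegerVector constraint, double penalty) {
  const int ntip = tip_bits.nrow();
  std::vector<int> cons(constraint.begin(), constraint.end());
  TipData td{&tip_bits, &tip_lo, &tip_hi, &ordered, &weights,
             &cons, penalty};

  int nedge = edge.nrow();
  std::vector<int> e1(nedge), e2(nedge);
  for (int i = 0; i < nedge; ++i) { e1[i] = edge(i, 0); e2[i] = edge(i, 1); }
  int cur_root = root;
  double cur_len = eval_edges(e1, e2, cur_root, td, R_PosInf);

  bool improved = true;
  std::vector<int> comp;     // component id per vertex
  while (improved) {
    improved = false;
    for (int k = 0; k < nedge && !improved; ++k) {
      int x = e1[k], y = e2[k];
      // partition vertices by BFS from x avoiding edge k
      int max_id = 0;
      for (int i = 0; i < nedge; ++i) {
        if (e1[i] > max_id) max_id = e1[i];
        if (e2[i] > max_id) max_id = e2[i];
      }
      comp.assign(max_id + 1, 0);
      comp[x] = 1;
      bool grew = true;
      while (grew) {
        grew = false;
        for (int i = 0; i < nedge; ++i) {
          if (i == k) continue;
          int a = e1[i], b = e2[i];
          if (comp[a] && !comp[b]) { comp[b] = 1; grew = true; }
          else if (comp[b] && !comp[a]) { comp[a] = 1; grew = true; }
        }
      }
      // collect the two parts (excluding edge k), suppressing x and y
      std::vector<int> a1, a2, b1, b2;
      int amerged = -1, bmerged = -1;
      bool a_tip = (x <= ntip), b_tip = (y <= ntip);
      {
        // part A (contains x)
        if (!a_tip) {
          int n1 = -1, n2 = -1;
          for (int i = 0; i < nedge; ++i) {
            if (i == k) continue;
            if (!comp[e1[i]]) continue;
            if (e1[i] == x || e2[i] == x) {
              int nb = (e1[i] == x) ? e2[i] : e1[i];
              if (n1 < 0) n1 = nb; else n2 = nb;
            } else { a1.push_back(e1[i]); a2.push_back(e2[i]); }
          }
          a1.push_back(n1); a2.push_back(n2);
          amerged = (int) a1.size() - 1;
        }
        // part B (contains y)
        if (!b_tip) {
          int n1 = -1, n2 = -1;
          for (int i = 0; i < nedge; ++i) {
            if (i == k) continue;
            if (comp[e1[i]]) continue;
            if (e1[i] == y || e2[i] == y) {
              int nb = (e1[i] == y) ? e2[i] : e1[i];
              if (n1 < 0) n1 = nb; else n2 = nb;
            } else { b1.push_back(e1[i]); b2.push_back(e2[i]); }
          }
          b1.push_back(n1); b2.push_back(n2);
          bmerged = (int) b1.size() - 1;
        }
      }
      if (a_tip && b_tip) continue;  // cannot happen for n >= 3

      int na = a_tip ? 1 : (int) a1.size();
      int nb_ = b_tip ? 1 : (int) b1.size();
      std::vector<int> c1, c2;
      for (int ai = 0; ai < na && !improved; ++ai) {
        for (int bi = 0; bi < nb_ && !improved; ++bi) {
          if (!a_tip && !b_tip && ai == amerged && bi == bmerged)
            continue;  // recreates the original tree
          c1.clear(); c2.clear();
          int new_root;
          if (a_tip) {
            // reattach tip x onto edge bi of part B
            for (int i = 0; i < (int) b1.size(); ++i)
              if (i != bi) { c1.push_back(b1[i]); c2.push_back(b2[i]); }
            c1.push_back(y); c2.push_back(b1[bi]);
            c1.push_back(y); c2.push_back(b2[bi]);
            c1.push_back(y); c2.push_back(x);
            new_root = y;
          } else if (b_tip) {
            for (int i = 0; i < (int) a1.size(); ++i)
              if (i != ai) { c1.push_back(a1[i]); c2.push_back(a2[i]); }
            c1.push_back(x); c2.push_back(a1[ai]);
            c1.push_back(x); c2.push_back(a2[ai]);
            c1.push_back(x); c2.push_back(y);
            new_root = x;
          } else {
            for (int i = 0; i < (int) a1.size(); ++i)
              if (i != ai) { c1.push_back(a1[i]); c2.push_back(a2[i]); }
            for (int i = 0; i < (int) b1.size(); ++i)
              if (i != bi) { c1.push_back(b1[i]); c2.push_back(b2[i]); }
            c1.push_back(x); c2.push_back(a1[ai]);
            c1.push_back(x); c2.push_back(a2[ai]);
            c1.push_back(y); c2.push_back(b1[bi]);
            c1.push_back(y); c2.push_back(b2[bi]);
            c1.push_back(x); c2.push_back(y);
            new_root = x;
          }
          double len = eval_edges(c1, c2, new_root, td, cur_len);
          if (len < cur_len) {
            e1 = c1; e2 = c2;
            cur_root = new_root;
            cur_len = len;
            nedge = (int) e1.size();
            improved = true;
          }
        }
      }
    }
  }

  IntegerMatrix out(nedge, 2);
  for (int i = 0; i < nedge; ++i) { out(i, 0) = e1[i]; out(i, 1) = e2[i]; }
  return List::create(_["edge"] = out, _["root"] = cur_root,
                      _["length"] = cur_len);
}
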