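// Annotated suffix tree (online Ukkonen construction), minimal absent word
// enumeration, and the avoided-word routines.
//
// The tree is built over the rank-mapped word x followed by a unique sentinel
// (rank sigma, outside the alphabet) so that every suffix of x ends at a leaf.
// All counts, depths and words reported to R are sentinel-free: the subtree
// terminal count C(v) excludes the sentinel-only suffix, and leaf word-depths
// are reported without the trailing sentinel.

#include <Rcpp.h>

#include <algorithm>
#include <cmath>
#include <limits>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

struct SuffixTree {
  int n = 0;      // |x|, sentinel excluded
  int sigma = 0;  // alphabet size; the sentinel has rank sigma
  std::vector<int> s;  // rank-mapped x followed by the sentinel; |s| = n + 1

  struct Node {
    int start, end;  // incoming edge label = s[start, end)
    int slink;
    std::map<int, int> next;
  };
  std::vector<Node> t;

  // annotations, filled by finalize()
  std::vector<int> parent;
  std::vector<int> depth;    // word-depth including a trailing sentinel on leaves
  std::vector<int> cnt;      // sentinel-free terminal nodes in the subtree
  std::vector<int> minterm;  // smallest suffix index in the subtree
  std::vector<int> sufidx;   // leaves: suffix start index; internal: -1

  // --- Ukkonen construction state ---
  int pos = -1, needSL = 0, rem = 0, activeNode = 0, activeE = 0, activeLen = 0;
  static constexpr int OPEN = std::numeric_limits<int>::max();

  int newNode(int start, int end) {
    t.push_back(Node{start, end, 0, {}});
    return static_cast<int>(t.size()) - 1;
  }
  int edgeLen(int v) const { return std::min(t[v].end, pos + 1) - t[v].start; }
  void addSL(int node) {
    if (needSL > 0) t[needSL].slink = node;
    needSL = node;
  }
  bool walkDown(int node) {
    if (activeLen >= edgeLen(node)) {
      activeE += edgeLen(node);
      activeLen -= edgeLen(node);
      activeNode = node;
      return true;
    }
    return false;
  }
  void extend(int c) {
    s.push_back(c);
    ++pos;
    needSL = 0;
    ++rem;
    while (rem > 0) {
      if (activeLen == 0) activeE = pos;
      std::map<int, int>::iterator it = t[activeNode].next.find(s[activeE]);
      if (it == t[activeNode].next.end()) {
        t[activeNode].next[s[activeE]] = newNode(pos, OPEN);
        addSL(activeNode);
      } else {
        int nxt = it->second;
        if (walkDown(nxt)) continue;
        if (s[t[nxt].start + activeLen] == c) {
          ++activeLen;
          addSL(activeNode);
          break;
        }
        int split = newNode(t[nxt].start, t[nxt].start + activeLen);
        t[activeNode].next[s[activeE]] = split;
        t[split].next[c] = newNode(pos, OPEN);
        t[nxt].start += activeLen;
        t[split].next[s[t[nxt].start]] = nxt;
        addSL(split);
      }
      --rem;
      if (activeNode == 0 && activeLen > 0) {
        --activeLen;
        activeE = pos - rem + 1;
      } else {
        activeNode = t[activeNode].slink;
      }
    }
  }

  void build(const std::vector<int>& x, int sig) {
    n = static_cast<int>(x.size());
    sigma = sig;
    s.reserve(n + 1);
    t.reserve(2 * (static_cast<size_t>(n) + 2));
    newNode(-1, -1);  // root
    for (size_t i = 0; i < x.size(); ++i) extend(x[i]);
    extend(sigma);  // unique terminal symbol
    finalize();
  }

  // Depth-first annotation: parents, word-depths, terminal counts and the
  // smallest suffix index per subtree.  Iterative to cope with degenerate
  // (single-letter-run) inputs whose tree is a path of length n.
  void finalize() {
    const int N = n + 1;
    const int m = static_cast<int>(t.size());
    parent.assign(m, -1);
    depth.assign(m, 0);
    cnt.assign(m, 0);
    minterm.assign(m, std::numeric_limits<int>::max());
    sufidx.assign(m, -1);

    std::vector<int> order;
    order.reserve(m);
    std::vector<int> stack;
    stack.push_back(0);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      order.push_back(v);
      if (v != 0) {
        int e = std::min(t[v].end, N);
        t[v].end = e;  // close open leaf edges
        depth[v] = depth[parent[v]] + (e - t[v].start);
      }
      for (std::map<int, int>::const_iterator it = t[v].next.begin();
           it != t[v].next.end(); ++it) {
        parent[it->second] = v;
        stack.push_back(it->second);
      }
    }
    for (int idx = m - 1; idx >= 0; --idx) {
      int v = order[idx];
      if (t[v].next.empty()) {
        sufidx[v] = N - depth[v];
        if (sufidx[v] < n) cnt[v] = 1;  // the sentinel-only suffix is excluded
        minterm[v] = sufidx[v];
      }
      if (v != 0) {
        cnt[parent[v]] += cnt[v];
        if (minterm[v] < minterm[parent[v]]) minterm[parent[v]] = minterm[v];
      }
    }
  }

  bool isLeaf(int v) const { return t[v].next.empty(); }
  // word-depth in the sentinel-free tree: leaves drop the trailing sentinel
  int reportedDepth(int v) const { return isLeaf(v) ? depth[v] - 1 : depth[v]; }

  struct Locus {
    bool found;
    int node;       // explicit node at or immediately below the position
    bool explicit_node;
  };

  // Descend from the root along w (ranks; -1 marks a letter absent from the
  // alphabet and can never match).  Absence is a value, not an error.
  Locus locate(const std::vector<int>& w) const {
    Locus L;
    L.found = false;
    L.node = 0;
    L.explicit_node = false;
    int cur = 0;
    size_t i = 0;
    while (i < w.size()) {
      std::map<int, int>::const_iterator it = t[cur].next.find(w[i]);
      if (it == t[cur].next.end()) return L;
      int v = it->second;
      int len = t[v].end - t[v].start;
      int j = 0;
      while (j < len && i < w.size()) {
        if (s[t[v].start + j] != w[i]) return L;
        ++j;
        ++i;
      }
      if (i == w.size()) {
        L.found = true;
        L.node = v;
        // the sentinel-free end of a leaf edge is the terminal node of T(x)
        L.explicit_node =
            (j == len) ||
            (isLeaf(v) && j == len - 1 && s[t[v].start + j] == sigma);
        return L;
      }
      cur = v;
    }
    return L;
  }

  int countWord(const std::vector<int>& w) const {
    Locus L = locate(w);
    return L.found ? cnt[L.node] : 0;
  }

  // occurrence count of s[i..j] (inclusive), optionally extended by alpha
  int countRange(int i, int j, int alpha) const {
    std::vector<int> w;
    w.reserve(j - i + 2);
    for (int p = i; p <= j; ++p) w.push_back(s[p]);
    if (alpha >= 0) w.push_back(alpha);
    return countWord(w);
  }

  // Minimal absent word enumeration.  w = a u b is minimal absent iff
  //   - u b occurs (b labels a child edge of u's explicit locus),
  //   - some occurrence of u is preceded by a,
  //   - no occurrence of u b is preceded by a.
  // With the sentinel every suffix locus is explicit, so u always has an
  // explicit locus and scanning (explicit node, child, letter) triples is
  // exhaustive.  A witness position per (node, preceding letter) yields the
  // tuple <(i, j), alpha> with x[i..j] the longest proper prefix of w.
  void maws(std::vector<int>& oi, std::vector<int>& oj,
            std::vector<int>& oa) const {
    const int m = static_cast<int>(t.size());
    // wit[v * sigma + a]: smallest occurrence start p of L(v) with x[p-1] = a
    std::vector<int> wit(static_cast<size_t>(m) * sigma, -1);
    std::vector<int> order;
    order.reserve(m);
    std::vector<int> stack;
    stack.push_back(0);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      order.push_back(v);
      for (std::map<int, int>::const_iterator it = t[v].next.begin();
           it != t[v].next.end(); ++it)
        stack.push_back(it->second);
    }
    for (int idx = m - 1; idx >= 0; --idx) {
      int v = order[idx];
      if (t[v].next.empty()) {
        int i0 = sufidx[v];
        if (i0 >= 1) wit[static_cast<size_t>(v) * sigma + s[i0 - 1]] = i0;
      }
      if (v != 0) {
        int p = parent[v];
        for (int a = 0; a < sigma; ++a) {
          int wv = wit[static_cast<size_t>(v) * sigma + a];
          if (wv >= 0) {
            int& wp = wit[static_cast<size_t>(p) * sigma + a];
            if (wp < 0 || wv < wp) wp = wv;
          }
        }
      }
    }
    for (int u = 0; u < m; ++u) {
      if (t[u].next.empty()) continue;
      for (std::map<int, int>::const_iterator it = t[u].next.begin();
           it != t[u].next.end(); ++it) {
        int b = it->first;
        if (b >= sigma) continue;  // sentinel edge
        int z = it->second;
        for (int a = 0; a < sigma; ++a) {
          int p = wit[static_cast<size_t>(u) * sigma + a];
          if (p >= 0 && wit[static_cast<size_t>(z) * sigma + a] < 0) {
            oi.push_back(p - 1);
            oj.push_back(p - 1 + depth[u]);
            oa.push_back(b);
          }
        }
      }
    }
  }
};

inline double deviation_score(double f, double E) {
  return (f - E) / std::max(std::sqrt(E), 1.0);
}

}  // namespace

// [[Rcpp::export]]
SEXP st_build_cpp(IntegerVector x, int sigma) {
  if (x.size() == 0) stop("empty sequence");
  XPtr<SuffixTree> p(new SuffixTree(), true);
  std::vector<int> v(x.begin(), x.end());
  p->build(v, sigma);
  return p;
}

// [[Rcpp::export]]
List st_stats_cpp(SEXP ptr) {
  XPtr<SuffixTree> p(ptr);
  const SuffixTree& T = *p;
  const int m = static_cast<int>(T.t.size());
  int leaves = 0, internal = 0, dollar_leaves = 0, merged = 0, max_int = 0;
  for (int v = 0; v < m; ++v) {
    if (T.t[v].next.empty()) {
      ++leaves;
      // a leaf whose whole edge is the sentinel disappears from T(x)
      if (T.t[v].end - T.t[v].start == 1 && T.s[T.t[v].start] == T.sigma) {
        ++dollar_leaves;
        int pa = T.parent[v];
        if (pa != 0 && static_cast<int>(T.t[pa].next.size()) == 2) ++merged;
      }
    } else {
      ++internal;
      if (v != 0 && T.depth[v] > max_int) max_int = T.depth[v];
    }
  }
  return List::create(
      _["n"] = T.n, _["sigma"] = T.sigma, _["n_nodes"] = m,
      _["n_edges"] = m - 1, _["n_leaves"] = leaves, _["n_internal"] = internal,
      _["essential_edges"] = (m - 1) - dollar_leaves - merged,
      _["longest_repeated_factor"] = max_int);
}

// [[Rcpp::export]]
List st_locate_cpp(SEXP ptr, IntegerVector w) {
  XPtr<SuffixTree> p(ptr);
  std::vector<int> v(w.begin(), w.end());
  SuffixTree::Locus L = p->locate(v);
  if (!L.found)
    return List::create(_["found"] = false);
  return List::create(
      _["found"] = true, _["node"] = L.node, _["depth"] = (int)w.size(),
      _["explicit"] = L.explicit_node,
      _["node_depth"] = p->reportedDepth(L.node),
      _["count"] = p->cnt[L.node],
      _["label_start"] = p->minterm[L.node]);
}

// [[Rcpp::export]]
int st_count_cpp(SEXP ptr, IntegerVector w) {
  XPtr<SuffixTree> p(ptr);
  std::vector<int> v(w.begin(), w.end());
  return p->countWord(v);
}

// Suffix link of the explicit internal node path-labelled w.
// [[Rcpp::export]]
List st_slink_cpp(SEXP ptr, IntegerVector w) {
  XPtr<SuffixTree> p(ptr);
  std::vector<int> v(w.begin(), w.end());
  SuffixTree::Locus L = p->locate(v);
  if (!L.found || !L.explicit_node || p->isLeaf(L.node))
    stop("suffix link is defined only for explicit internal nodes");
  if (L.node == 0 || p->reportedDepth(L.node) != (int)w.size())
    stop("suffix link is defined only for explicit internal nodes");
  int u = p->t[L.node].slink;
  return List::create(_["node"] = u, _["depth"] = p->reportedDepth(u),
                      _["label_start"] = p->minterm[u],
                      _["count"] = p->cnt[u]);
}

// [[Rcpp::export]]
DataFrame st_nodes_cpp(SEXP ptr) {
  XPtr<SuffixTree> p(ptr);
  const SuffixTree& T = *p;
  const int m = static_cast<int>(T.t.size());
  IntegerVector id(m), par(m), dep(m), cntv(m), suf(m), slink(m), estart(m),
      elen(m);
  LogicalVector leaf(m), sentinel_only(m);
  for (int v = 0; v < m; ++v) {
    id[v] = v;
    par[v] = (v == 0) ? NA_INTEGER : T.parent[v];
    bool lf = T.t[v].next.empty();
    leaf[v] = lf;
    dep[v] = T.reportedDepth(v);
    cntv[v] = T.cnt[v];
    suf[v] = lf ? T.sufidx[v] : NA_INTEGER;
    slink[v] = (lf || v == 0) ? NA_INTEGER : T.t[v].slink;
    estart[v] = (v == 0) ? NA_INTEGER : T.t[v].start;
    int el = (v == 0) ? 0 : T.t[v].end - T.t[v].start;
    if (lf && v != 0) --el;  // drop the trailing sentinel
    elen[v] = el;
    sentinel_only[v] = lf && T.sufidx[v] == T.n;
  }
  return DataFrame::create(
      _["id"] = id, _["parent"] = par, _["depth"] = dep, _["count"] = cntv,
      _["leaf"] = leaf, _["suffix_index"] = suf, _["slink"] = slink,
      _["edge_start"] = estart, _["edge_length"] = elen,
      _["sentinel_only"] = sentinel_only);
}

// [[Rcpp::export]]
List maw_cpp(SEXP ptr) {
  XPtr<SuffixTree> p(ptr);
  std::vector<int> i, j, a;
  p->maws(i, j, a);
  return List::create(_["i"] = wrap(i), _["j"] = wrap(j),
                      _["alpha"] = wrap(a));
}

// Routine for absent avoided words: each minimal absent word tuple
// <(i, j), alpha> of the requested length has w_p = x[i..j], w_i = x[i+1..j]
// and w_s = x[i+1..j] alpha, all of which occur; f(w) = 0.
// [[Rcpp::export]]
List absent_avoided_cpp(SEXP ptr, IntegerVector mi, IntegerVector mj,
                        IntegerVector ma, int k, bool all_lengths, double rho) {
  XPtr<SuffixTree> p(ptr);
  std::vector<int> oi, olen, oa, ofp, ofs, ofi;
  std::vector<double> oE, od;
  long long candidates = 0;
  for (R_xlen_t q = 0; q < mi.size(); ++q) {
    int i = mi[q], j = mj[q], alpha = ma[q];
    int len = j - i + 2;
    if (len < 3) continue;  // deviation is defined for |w| > 2 only
    if (!all_lengths && len != k) continue;
    ++candidates;
    int fp = p->countRange(i, j, -1);
    int fi = p->countRange(i + 1, j, -1);
    int fs = p->countRange(i + 1, j, alpha);
    if (fi <= 0) stop("internal error: infix of a minimal absent word must occur");
    double E = static_cast<double>(fp) * fs / fi;
    double dev = deviation_score(0.0, E);
    if (dev <= rho) {
      oi.push_back(i);
      olen.push_back(len - 1);  // prefix length
      oa.push_back(alpha);
      ofp.push_back(fp);
      ofs.push_back(fs);
      ofi.push_back(fi);
      oE.push_back(E);
      od.push_back(dev);
    }
  }
  return List::create(_["start"] = wrap(oi), _["plen"] = wrap(olen),
                      _["alpha"] = wrap(oa), _["f_p"] = wrap(ofp),
                      _["f_s"] = wrap(ofs), _["f_i"] = wrap(ofi),
                      _["E"] = wrap(oE), _["dev"] = wrap(od),
                      _["candidates"] = static_cast<double>(candidates));
}

// Routine for occurring avoided words: every candidate is w = L(v) alpha for
// an explicit internal node v (word-depth k - 1 in fixed-length mode, any
// word-depth >= 2 otherwise); words whose longest proper prefix sits at an
// implicit node have dev >= 0 and are pruned wholesale.  f(w_i) is read off
// the suffix-link target of v and f(w_s) off that target's alpha-child.
// [[Rcpp::export]]
List occurring_avoided_cpp(SEXP ptr, int k, bool all_lengths, double rho) {
  XPtr<SuffixTree> p(ptr);
  const SuffixTree& T = *p;
  const int m = static_cast<int>(T.t.size());
  std::vector<int> os, olen, oa, ofw, ofp, ofs, ofi;
  std::vector<double> oE, od;
  long long candidates = 0;
  for (int v = 1; v < m; ++v) {
    if (T.t[v].next.empty()) continue;
    int d = T.depth[v];
    if (all_lengths ? (d < 2) : (d != k - 1)) continue;
    int sl = T.t[v].slink;
    if (sl <= 0 || T.depth[sl] != d - 1)
      stop("internal error: suffix link missing on an internal node");
    for (std::map<int, int>::const_iterator it = T.t[v].next.begin();
         it != T.t[v].next.end(); ++it) {
      int alpha = it->first;
      if (alpha >= T.sigma) continue;  // sentinel edge
      ++candidates;
      int z = it->second;
      int fw = T.cnt[z];
      int fp = T.cnt[v];
      int fi = T.cnt[sl];
      std::map<int, int>::const_iterator jt = T.t[sl].next.find(alpha);
      if (jt == T.t[sl].next.end())
        stop("internal error: suffix of an occurring word must occur");
      int fs = T.cnt[jt->second];
      double E = static_cast<double>(fp) * fs / fi;
      double dev = deviation_score(static_cast<double>(fw), E);
      if (dev <= rho) {
        os.push_back(T.minterm[v]);
        olen.push_back(d);  // prefix length; the word is L(v) alpha
        oa.push_back(alpha);
        ofw.push_back(fw);
        ofp.push_back(fp);
        ofs.push_back(fs);
        ofi.push_back(fi);
        oE.push_back(E);
        od.push_back(dev);
      }
    }
  }
  return List::create(_["start"] = wrap(os), _["plen"] = wrap(olen),
                      _["alpha"] = wrap(oa), _["f"] = wrap(ofw),
                      _["f_p"] = wrap(ofp), _["f_s"] = wrap(ofs),
                      _["f_i"] = wrap(ofi), _["E"] = wrap(oE),
                      _["dev"] = wrap(od),
                      _["candidates"] = static_cast<double>(candidates));
}
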