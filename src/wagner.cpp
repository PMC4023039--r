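#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Wagner (linearly ordered) parsimony length on a rooted binary tree via the
// Farris interval algorithm: in postorder each internal node carries a state
// interval; disjoint child intervals contribute their gap to the length.

struct TreeIdx {
  int nnode;                       // total nodes
  std::vector<int> left, right;    // children (-1 for tips)
  std::vector<int> post;           // postorder node ids
};

// edge: 1-based ape-style matrix (tips 1..ntip, internals ntip+1..)
static TreeIdx index_tree(const IntegerMatrix& edge, int ntip) {
  int nnode = 0;
  for (int r = 0; r < edge.nrow(); ++r) {
    nnode = std::max(nnode, std::max(edge(r, 0), edge(r, 1)));
  }
  TreeIdx T;
  T.nnode = nnode;
  T.left.assign(nnode, -1);
  T.right.assign(nnode, -1);
  std::vector<int> indeg(nnode, 0);
  for (int r = 0; r < edge.nrow(); ++r) {
    int p = edge(r, 0) - 1, c = edge(r, 1) - 1;
    if (T.left[p] < 0) T.left[p] = c;
    else if (T.right[p] < 0) T.right[p] = c;
    else stop("wagner length requires a binary tree");
    indeg[c] += 1;
  }
  int root = -1;
  for (int v = ntip; v < nnode; ++v)
    if (indeg[v] == 0) { root = v; break; }
  if (root < 0) stop("no root found");
  // iterative postorder
  T.post.reserve(nnode);
  std::vector<int> stack{root}, out;
  out.reserve(nnode);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    out.push_back(v);
    if (T.left[v] >= 0) stack.push_back(T.left[v]);
    if (T.right[v] >= 0) stack.push_back(T.right[v]);
  }
  for (auto it = out.rbegin(); it != out.rend(); ++it) T.post.push_back(*it);
  return T;
}

static void interval_lengths(const TreeIdx& T, const IntegerMatrix& states,
                             int ntip, NumericVector& len) {
  const int nchar = states.ncol();
  std::vector<int> lo((size_t)T.nnode * nchar), hi((size_t)T.nnode * nchar);
  for (int v : T.post) {
    if (T.left[v] < 0) {  // tip
      for (int c = 0; c < nchar; ++c) {
        lo[(size_t)v * nchar + c] = states(v, c);
        hi[(size_t)v * nchar + c] = states(v, c);
      }
      continue;
    }
    int a = T.left[v], b = T.right[v];
    if (b < 0) stop("wagner length requires a binary tree");
    for (int c = 0; c < nchar; ++c) {
      int l1 = lo[(size_t)a * nchar + c], h1 = hi[(size_t)a * nchar + c];
      int l2 = lo[(size_t)b * nchar + c], h2 = hi[(size_t)b * nchar + c];
      int l = std::max(l1, l2), h = std::min(h1, h2);
      if (l <= h) {
        lo[(size_t)v * nchar + c] = l;
        hi[(size_t)v * nchar + c] = h;
      } else {
        len[c] += l - h;
        lo[(size_t)v * nchar + c] = h;
        hi[(size_t)v * nchar + c] = l;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector wagner_length_cpp(IntegerMatrix edge, int ntip,
                                IntegerMatrix states) {
  if (states.nrow() != ntip) stop("states must have one row per tip");
  TreeIdx T = index_tree(edge, ntip);
  NumericVector len(states.ncol());
  interval_lengths(T, states, ntip, len);
  return len;
}

// Lengths of uniformly sampled rooted labelled topologies (sequential random
// attachment), used for the g1 tree-length skewness statistic. Uses R's RNG.
// [[Rcpp::export]]
NumericVector sample_topology_lengths_cpp(IntegerMatrix states, int nsamples) {
  const int ntip = states.nrow(), nchar = states.ncol();
  if (ntip < 2) stop("need at least 2 taxa");
  NumericVector out(nsamples);
  const int nnode = 2 * ntip - 1;
  std::vector<int> left(nnode), right(nnode), epar, echi;
  for (int s = 0; s < nsamples; ++s) {
    epar.clear();
    echi.clear();
    int root = ntip;              // first internal node id (0-based)
    int next_internal = ntip + 1;
    epar.push_back(root); echi.push_back(0);
    epar.push_back(root); echi.push_back(1);
    for (int tip = 2; tip < ntip; ++tip) {
      int nedge = (int)epar.size();
      int choice = (int)(unif_rand() * (nedge + 1));
      if (choice >= nedge + 1) choice = nedge;  // guard unif_rand()==1
      int x = next_internal++;
      if (choice == nedge) {       // new root above the old one
        epar.push_back(x); echi.push_back(root);
        epar.push_back(x); echi.push_back(tip);
        root = x;
      } else {
        int c = echi[choice];
        echi[choice] = x;
        epar.push_back(x); echi.push_back(c);
        epar.push_back(x); echi.push_back(tip);
      }
    }
    std::fill(left.begin(), left.end(), -1);
    std::fill(right.begin(), right.end(), -1);
    for (size_t r = 0; r < epar.size(); ++r) {
      int p = epar[r], c = echi[r];
      if (left[p] < 0) left[p] = c; else right[p] = c;
    }
    // postorder + interval lengths inline
    std::vector<int> stack{root}, order;
    order.reserve(nnode);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      order.push_back(v);
      if (left[v] >= 0) { stack.push_back(left[v]); stack.push_back(right[v]); }
    }
    std::vector<int> lo((size_t)nnode * nchar), hi((size_t)nnode * nchar);
    double len = 0.0;
    for (auto it = order.rbegin(); it != order.rend(); ++it) {
      int v = *it;
      if (left[v] < 0) {
        for (int c = 0; c < nchar; ++c) {
          lo[(size_t)v * nchar + c] = states(v, c);
          hi[(size_t)v * nchar + c] = states(v, c);
        }
        continue;
      }
      int a = left[v], b = right[v];
      for (int c = 0; c < nchar; ++c) {
        int l = std::max(lo[(size_t)a * nchar + c], lo[(size_t)b * nchar + c]);
        int h = std::min(hi[(size_t)a * nchar + c], hi[(size_t)b * nchar + c]);
        if (l <= h) {
          lo[(size_t)v * nchar + c] = l;
          hi[(size_t)v * nchar + c] = h;
        } else {
          len += l - h;
          lo[(size_t)v * nchar + c] = h;
          hi[(size_t)v * nchar + c] = l;
        }
      }
    }
    out[s] = len;
  }
  return out;
}
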