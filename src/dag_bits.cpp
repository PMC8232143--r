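// Exhaustive verification kernels over bitmask-encoded digraphs.
//
// A digraph on n <= 6 labelled nodes is a 36-bit mask: bit (i*n + j) set
// means edge i -> j (0-based node indices).  Masks fit exactly in a
// double, which is how they cross the R boundary.  Enumeration walks all
// assignments of {none, ->, <-} to the n(n-1)/2 unordered pairs, so no
// digraph with a 2-cycle is ever generated and every DAG appears exactly
// once.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static bool mask_acyclic(uint64_t m, int n) {
  bool removed[6] = {false, false, false, false, false, false};
  for (int step = 0; step < n; ++step) {
    int pick = -1;
    for (int j = 0; j < n && pick < 0; ++j) {
      if (removed[j]) continue;
      bool indeg0 = true;
      for (int i = 0; i < n; ++i) {
        if (removed[i]) continue;
        if (m & (1ULL << (i * n + j))) { indeg0 = false; break; }
      }
      if (indeg0) pick = j;
    }
    if (pick < 0) return false;
    removed[pick] = true;
  }
  return true;
}

// reverse every out-edge of x (the Leaf operator at bit level)
static uint64_t leaf_bits(uint64_t m, int n, int x) {
  uint64_t out = m;
  for (int j = 0; j < n; ++j) {
    if (j == x) continue;
    uint64_t b = 1ULL << (x * n + j);
    if (m & b) {
      out &= ~b;
      out |= 1ULL << (j * n + x);
    }
  }
  return out;
}

// reverse every in-edge of x (the Root operator at bit level)
static uint64_t root_bits(uint64_t m, int n, int x) {
  uint64_t out = m;
  for (int i = 0; i < n; ++i) {
    if (i == x) continue;
    uint64_t b = 1ULL << (i * n + x);
    if (m & b) {
      out &= ~b;
      out |= 1ULL << (x * n + i);
    }
  }
  return out;
}

static void check_n(int n) {
  if (n < 2 || n > 6) stop("n must be between 2 and 6");
}

// visit every DAG mask on n nodes; f(mask) is called once per DAG
template <typename F>
static void for_each_dag(int n, F f) {
  std::vector<int> pi, pj;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) { pi.push_back(i); pj.push_back(j); }
  const int np = (int)pi.size();
  std::vector<int> st(np, 0);  // 0 none, 1 i->j, 2 j->i
  for (;;) {
    uint64_t m = 0;
    for (int k = 0; k < np; ++k) {
      if (st[k] == 1) m |= 1ULL << (pi[k] * n + pj[k]);
      else if (st[k] == 2) m |= 1ULL << (pj[k] * n + pi[k]);
    }
    if (mask_acyclic(m, n)) f(m);
    int k = 0;
    while (k < np && st[k] == 2) st[k++] = 0;
    if (k == np) break;
    ++st[k];
  }
}

// [[Rcpp::export]]
List leaf_root_exhaustive(int n) {
  check_n(n);
  double n_dags = 0, leaf_bad = 0, root_bad = 0;
  for_each_dag(n, [&](uint64_t m) {
    ++n_dags;
    for (int x = 0; x < n; ++x) {
      if (!mask_acyclic(leaf_bits(m, n, x), n)) ++leaf_bad;
      if (!mask_acyclic(root_bits(m, n, x), n)) ++root_bad;
    }
  });
  return List::create(_["n_dags"] = n_dags,
                      _["leaf_violations"] = leaf_bad,
                      _["root_violations"] = root_bad);
}

// [[Rcpp::export]]
NumericVector enumerate_dag_masks_cpp(int n) {
  check_n(n);
  std::vector<double> out;
  for_each_dag(n, [&](uint64_t m) { out.push_back((double)m); });
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
double leaf_mask_cpp(double mask, int n, int x) {
  check_n(n);
  return (double)leaf_bits((uint64_t)mask, n, x);
}

// [[Rcpp::export]]
double root_mask_cpp(double mask, int n, int x) {
  check_n(n);
  return (double)root_bits((uint64_t)mask, n, x);
}

// [[Rcpp::export]]
bool acyclic_mask_cpp(double mask, int n) {
  check_n(n);
  return mask_acyclic((uint64_t)mask, n);
}
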