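#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Inside/outside DP over the carrier subtree of one gene for candidate
// multiplicities m <= 2.  Symbols are 0..A-1 (observed signed adjacencies
// plus O); symbol A is the wildcard and never matches.  Size-2 candidate
// multisets (i <= j) are enumerated row-wise: index(i,j) = i*Aq -
// i*(i-1)/2 + (j-i), Aq = A+1.  Messages max_Y [ match(X,Y) + D(Y) ] are
// evaluated in O(1) per candidate from the global maximum, the per-symbol
// maxima best1[s] = max_{Y containing s} D(Y), and the pair entries
// themselves; match counts are doubled on the parent side of WGD branches.

static inline int pidx(int i, int j, int Aq) {
  return i * Aq - i * (i - 1) / 2 + (j - i);
}

typedef std::vector<double> vec;

static double vmax(const vec &v) {
  double m = R_NegInf;
  for (double x : v) m = std::max(m, x);
  return m;
}

// best over size-2 candidates containing symbol s (s < A)
static void pair_best1(const vec &d, int A, vec &best1) {
  int Aq = A + 1;
  best1.assign(A, R_NegInf);
  for (int i = 0; i < Aq; ++i)
    for (int j = i; j < Aq; ++j) {
      double v = d[pidx(i, j, Aq)];
      if (i < A && v > best1[i]) best1[i] = v;
      if (j < A && j != i && v > best1[j]) best1[j] = v;
    }
}

// message to a parent with multiplicity pm from a leaf with observed
// counts cnt (length Aq; wildcard count 0)
static vec leaf_msg(int pm, bool wgd, const IntegerVector &cnt, int A) {
  int Aq = A + 1;
  int w = wgd ? 2 : 1;
  if (pm == 1) {
    vec out(Aq, 0.0);
    for (int x = 0; x < A; ++x) out[x] = std::min(w, cnt[x]);
    return out;
  }
  vec out(Aq * (Aq + 1) / 2, 0.0);
  for (int i = 0; i < Aq; ++i)
    for (int j = i; j < Aq; ++j) {
      double v = 0.0;
      if (i == j) { if (i < A) v = std::min(2 * w, cnt[i]); }
      else {
        if (i < A) v += std::min(w, cnt[i]);
        if (j < A) v += std::min(w, cnt[j]);
      }
      out[pidx(i, j, Aq)] = v;
    }
  return out;
}

// message to a parent with multiplicity pm from an internal child with
// multiplicity cm and score vector d
static vec inner_msg(int pm, int cm, bool wgd, const vec &d, int A) {
  int Aq = A + 1;
  double dmax = vmax(d);
  if (cm == 1) {
    if (pm == 1) {
      vec out(Aq, dmax);
      for (int x = 0; x < A; ++x) out[x] = std::max(dmax, d[x] + 1.0);
      return out;  // doubling cannot raise a size-1 intersection
    }
    vec out(Aq * (Aq + 1) / 2);
    for (int i = 0; i < Aq; ++i)
      for (int j = i; j < Aq; ++j) {
        double v = dmax;
        if (i < A) v = std::max(v, d[i] + 1.0);
        if (j < A) v = std::max(v, d[j] + 1.0);
        out[pidx(i, j, Aq)] = v;
      }
    return out;
  }
  // child multiplicity 2
  vec best1;
  pair_best1(d, A, best1);
  if (pm == 1) {
    vec out(Aq, dmax);
    for (int x = 0; x < A; ++x) {
      double v = std::max(dmax, best1[x] + 1.0);
      if (wgd) v = std::max(v, d[pidx(x, x, Aq)] + 2.0);
      out[x] = v;
    }
    return out;
  }
  vec out(Aq * (Aq + 1) / 2);
  for (int i = 0; i < Aq; ++i)
    for (int j = i; j < Aq; ++j) {
      double v = dmax;
      if (i < A) v = std::max(v, best1[i] + 1.0);
      if (j < A) v = std::max(v, best1[j] + 1.0);
      if (i < A && j < A) {
        v = std::max(v, d[pidx(i, j, Aq)] + 2.0);
        if (wgd) {
          v = std::max(v, d[pidx(i, i, Aq)] + 2.0);
          v = std::max(v, d[pidx(j, j, Aq)] + 2.0);
        }
      }
      out[pidx(i, j, Aq)] = v;
    }
  return out;
}

// outside transition: U_child(Y) = max_X [ match(X, Y) + T(X) ], parent
// multiplicity pm, child multiplicity cm, doubling on the parent side
static vec outside_msg(int pm, int cm, bool wgd, const vec &t, int A) {
  int Aq = A + 1;
  double tmax = vmax(t);
  if (pm == 1) {
    if (cm == 1) {
      vec out(Aq, tmax);
      for (int y = 0; y < A; ++y) out[y] = std::max(tmax, t[y] + 1.0);
      return out;
    }
    vec out(Aq * (Aq + 1) / 2);
    for (int i = 0; i < Aq; ++i)
      for (int j = i; j < Aq; ++j) {
        double v = tmax;
        if (i < A) v = std::max(v, t[i] + 1.0);
        if (j < A) v = std::max(v, t[j] + 1.0);
        if (wgd && i == j && i < A) v = std::max(v, t[i] + 2.0);
        out[pidx(i, j, Aq)] = v;
      }
    return out;
  }
  // parent multiplicity 2
  vec best1;
  pair_best1(t, A, best1);
  if (cm == 1) {
    vec out(Aq, tmax);
    for (int y = 0; y < A; ++y) out[y] = std::max(tmax, best1[y] + 1.0);
    return out;
  }
  vec out(Aq * (Aq + 1) / 2);
  for (int i = 0; i < Aq; ++i)
    for (int j = i; j < Aq; ++j) {
      double v = tmax;
      if (i < A) v = std::max(v, best1[i] + 1.0);
      if (j < A) v = std::max(v, best1[j] + 1.0);
      if (i < A && j < A) {
        v = std::max(v, t[pidx(i, j, Aq)] + 2.0);
        if (wgd && i == j) v = std::max(v, best1[i] + 2.0);
      }
      out[pidx(i, j, Aq)] = v;
    }
  return out;
}

// [[Rcpp::export]]
NumericVector score_gene_cpp(IntegerVector parent, IntegerVector postorder,
                             IntegerVector kind, IntegerVector m,
                             IntegerMatrix obs_cnt, int A, int query,
                             bool wgd_double) {
  int n = parent.size();
  int Aq = A + 1;
  std::vector<vec> D(n), U(n), msg(n);
  std::vector<bool> carrier(n);
  for (int i = 0; i < n; ++i) carrier[i] = m[i] > 0;
  auto nsize = [&](int u) {
    return m[u] == 1 ? Aq : Aq * (Aq + 1) / 2;
  };
  std::vector<int> po;
  for (int k = 0; k < n; ++k)
    if (carrier[postorder[k]]) po.push_back(postorder[k]);
  // inside
  for (int u : po) {
    if (kind[u] == 0) continue;  // leaf
    bool wgd = (kind[u] == 2) && wgd_double;
    D[u].assign(nsize(u), 0.0);
    // children of u = carriers whose parent is u
    for (int v : po) {
      if (parent[v] != u) continue;
      if (kind[v] == 0) msg[v] = leaf_msg(m[u], wgd, obs_cnt(_, v), A);
      else msg[v] = inner_msg(m[u], m[v], wgd, D[v], A);
      for (size_t t = 0; t < D[u].size(); ++t) D[u][t] += msg[v][t];
    }
  }
  // outside
  for (auto it = po.rbegin(); it != po.rend(); ++it) {
    int u = *it;
    if (kind[u] == 0) continue;
    int p = parent[u];
    if (p < 0 || !carrier[p]) U[u].assign(nsize(u), 0.0);
    bool wgd = (kind[u] == 2) && wgd_double;
    for (int v : po) {
      if (parent[v] != u || kind[v] == 0) continue;
      vec t(D[u].size());
      for (size_t s = 0; s < t.size(); ++s) t[s] = U[u][s] + D[u][s] - msg[v][s];
      U[v] = outside_msg(m[u], m[v], wgd, t, A);
    }
  }
  if (kind[query] == 0) stop("query node must be internal");
  NumericVector out(nsize(query));
  for (size_t s = 0; s < D[query].size(); ++s) out[s] = D[query][s] + U[query][s];
  return out;
}
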