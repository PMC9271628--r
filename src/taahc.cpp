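// Topographic atomize-and-agglomerate hierarchical clustering (T-AAHC) core.
//
// Input maps are zero-mean (average-reference space), unit-L2 columns, so the
// polarity-invariant spatial correlation between a map and a unit-norm
// prototype is |dot product|. Each map carries a weight (its squared GFP at
// extraction time); a cluster's explained-variance contribution is
// sum_i w_i * corr_i^2 over its members. At every step the cluster with the
// smallest contribution is atomized and its members are reassigned to the
// surviving cluster of maximal |correlation|; a cluster's prototype is the
// first principal component of its member maps.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec first_pc(const mat& members) {
  if (members.n_cols == 1) return normalise(members.col(0));
  mat scatter = members * members.t();
  vec eigval;
  mat eigvec;
  eig_sym(eigval, eigvec, scatter);
  vec p = eigvec.col(eigvec.n_cols - 1); // largest eigenvalue last
  return normalise(p);
}

// sign-align a prototype to its heaviest member
static void align_sign(vec& proto, const mat& members, const vec& w_mem) {
  vec d = members.t() * proto;
  uword ref = index_max(w_mem % arma::abs(d));
  if (d(ref) < 0) proto = -proto;
}

// [[Rcpp::export(name = ".taahc_core")]]
Rcpp::List taahc_core(const arma::mat& M, const arma::vec& w, int k) {
  const uword n = M.n_cols;
  if (k < 1 || (uword)k > n) Rcpp::stop("need 1 <= k <= number of maps");

  uvec assign_(n);
  std::vector<std::vector<uword>> members(n);
  mat protos = M; // column j = prototype of cluster j (inactive cols stale)
  vec corr2(n);   // per-map squared correlation to its prototype
  vec gev(n);     // per-cluster contribution
  std::vector<bool> active(n, true);

  for (uword i = 0; i < n; ++i) {
    assign_(i) = i;
    members[i].push_back(i);
    corr2(i) = 1.0;
    gev(i) = w(i);
  }

  uword n_active = n;
  while (n_active > (uword)k) {
    // atomize the cluster contributing least explained variance
    uword worst = n; // sentinel
    double worst_gev = datum::inf;
    for (uword c = 0; c < n; ++c) {
      if (active[c] && gev(c) < worst_gev) {
        worst_gev = gev(c);
        worst = c;
      }
    }
    active[worst] = false;
    --n_active;
    std::vector<uword> orphans;
    orphans.swap(members[worst]);

    std::vector<uword> touched;
    for (uword idx : orphans) {
      vec s = arma::abs(protos.t() * M.col(idx));
      double best_val = -1.0;
      uword best = 0;
      for (uword c = 0; c < n; ++c) {
        if (active[c] && s(c) > best_val) {
          best_val = s(c);
          best = c;
        }
      }
      assign_(idx) = best;
      members[best].push_back(idx);
      touched.push_back(best);
    }
    std::sort(touched.begin(), touched.end());
    touched.erase(std::unique(touched.begin(), touched.end()), touched.end());

    // refresh prototypes and contributions of receiving clusters
    for (uword c : touched) {
      uvec mem = conv_to<uvec>::from(members[c]);
      mat sub = M.cols(mem);
      vec proto = first_pc(sub);
      vec w_mem = w.elem(mem);
      align_sign(proto, sub, w_mem);
      protos.col(c) = proto;
      vec d = sub.t() * proto;
      vec c2 = square(d);
      for (uword j = 0; j < mem.n_elem; ++j) corr2(mem(j)) = c2(j);
      gev(c) = dot(w_mem, c2);
    }
  }

  // compact to k clusters ordered by descending contribution
  std::vector<uword> ids;
  for (uword c = 0; c < n; ++c)
    if (active[c]) ids.push_back(c);
  std::sort(ids.begin(), ids.end(),
            [&](uword a, uword b) { return gev(a) > gev(b); });

  uvec relabel(n, fill::zeros);
  mat out_protos(M.n_rows, ids.size());
  vec out_gev(ids.size());
  for (uword j = 0; j < ids.size(); ++j) {
    relabel(ids[j]) = j + 1; // 1-based for R
    out_protos.col(j) = protos.col(ids[j]);
    out_gev(j) = gev(ids[j]);
  }
  uvec out_assign(n);
  for (uword i = 0; i < n; ++i) out_assign(i) = relabel(assign_(i));

  return Rcpp::List::create(
      Rcpp::Named("assignment") = out_assign,
      Rcpp::Named("prototypes") = out_protos,
      Rcpp::Named("fit") = sqrt(corr2),
      Rcpp::Named("gev") = out_gev);
}
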