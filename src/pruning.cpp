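// Felsenstein pruning over 61 codon states for site-class mixture models.
//
// The R side supplies, per distinct rate matrix (one per unique
// class/partition omega combination), the reversible eigensystem
// (right, values, left) such that P(t) = right * diag(exp(values * t)) * left,
// already on the scaled-rate time scale, plus the unscaled generator for
// gradient work. This file builds the per-edge transition matrices, runs
// one pruning pass per site class with per-pattern rescaling against
// underflow, and (optionally) an outside/preorder pass giving the exact
// derivative of the mixture log-likelihood with respect to every scaled
// branch length in one sweep.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct EigenSys {
  arma::mat right, left;
  arma::vec values;
};

static std::vector<EigenSys> unpack_systems(const List& eigensystems) {
  const int n_q = eigensystems.size();
  std::vector<EigenSys> es(n_q);
  for (int q = 0; q < n_q; ++q) {
    List e = eigensystems[q];
    es[q].right = as<arma::mat>(e["right"]);
    es[q].left = as<arma::mat>(e["left"]);
    es[q].values = as<arma::vec>(e["values"]);
  }
  return es;
}

static arma::mat trans_prob(const EigenSys& es, const double t) {
  const arma::vec ev = arma::exp(es.values * t);
  arma::mat P = es.right * (es.left.each_col() % ev);
  P.clamp(0.0, arma::datum::inf);
  return P;
}

// Down (postorder) pass for one site class. Fills:
//  - edge_factor[e]: the 61 x npat factor each edge contributes to its
//    parent partial (rescaled per pattern for internal children);
//  - node partials and log-scale accumulators;
//  - loglik column (npat) for this class.
static void down_pass(const arma::imat& edge, const arma::vec& lengths,
                      const arma::irowvec& qidx,
                      const std::vector<EigenSys>& es,
                      const arma::imat& tipstates, const arma::vec& pi,
                      const int n_tip, const int n_node, const int root,
                      std::vector<arma::mat>& edge_factor,
                      std::vector<arma::mat>& node_partial,
                      arma::vec& loglik) {
  const int n_state = pi.n_elem;
  const int n_edge = edge.n_rows;
  const int n_pat = tipstates.n_cols;
  std::vector<arma::rowvec> node_scale(n_node + 1);
  for (int nd = n_tip + 1; nd <= n_node; ++nd) {
    node_partial[nd].ones(n_state, n_pat);
    node_scale[nd].zeros(n_pat);
  }
  for (int e = 0; e < n_edge; ++e) {
    const int parent = edge(e, 0);
    const int child = edge(e, 1);
    const arma::mat P = trans_prob(es[qidx(e) - 1], lengths[e]);
    arma::mat& F = edge_factor[e];
    if (child <= n_tip) {
      F.set_size(n_state, n_pat);
      for (int j = 0; j < n_pat; ++j) {
        const int s = tipstates(child - 1, j);
        if (s == 0) {
          F.col(j).ones();
        } else {
          F.col(j) = P.col(s - 1);
        }
      }
      node_partial[parent] %= F;
    } else {
      F = P * node_partial[child];
      arma::rowvec m = arma::max(F, 0);
      m.elem(arma::find(m <= 0)).ones();
      F.each_row() /= m;
      node_partial[parent] %= F;
      node_scale[parent] += node_scale[child] + arma::log(m);
    }
  }
  const arma::rowvec site_l = pi.t() * node_partial[root];
  for (int j = 0; j < n_pat; ++j) {
    const double l = site_l(j);
    loglik(j) = (l > 0 ? std::log(l) : -arma::datum::inf) +
      node_scale[root](j);
  }
}

// edge: nedge x 2 (parent, child), 1-based ape node ids, in postorder
// (children before parents). tip states: ntip x npat, 1..61, 0 = missing.
// qindex: nclass x nedge, 1-based index into the eigensystem list.
// Returns npat x nclass matrix of per-pattern log-likelihoods.
// [[Rcpp::export]]
arma::mat class_site_loglik_cpp(const arma::imat& edge,
                                const arma::vec& lengths,
                                const arma::imat& qindex,
                                const List& eigensystems,
                                const arma::imat& tipstates,
                                const arma::vec& pi,
                                const int n_tip,
                                const int n_node,
                                const int root) {
  const std::vector<EigenSys> es = unpack_systems(eigensystems);
  const int n_edge = edge.n_rows;
  const int n_pat = tipstates.n_cols;
  const int n_class = qindex.n_rows;
  arma::mat out(n_pat, n_class);
  std::vector<arma::mat> edge_factor(n_edge);
  std::vector<arma::mat> node_partial(n_node + 1);
  arma::vec ll(n_pat);
  for (int k = 0; k < n_class; ++k) {
    down_pass(edge, lengths, qindex.row(k), es, tipstates, pi,
              n_tip, n_node, root, edge_factor, node_partial, ll);
    out.col(k) = ll;
  }
  return out;
}

// As above, but also returns d lnL / d s_e for every edge, where s_e is the
// edge's scaled branch length (the time actually fed to exp(Q s)), lnL the
// mixture log-likelihood with class weights `proportions` and pattern
// multiplicities `weights`. `generators` holds the unscaled rate matrix of
// each eigensystem; the caller divides eigenvalues (not the generators) by
// the global scale factor, so d exp(Q_unscaled * s)/d s needs Q_unscaled
// already folded into the eigensystem scale -- here we take A from
// `generators` on the same scale as `values`, i.e. pre-divided in R.
// [[Rcpp::export]]
List class_site_loglik_grad_cpp(const arma::imat& edge,
                                const arma::vec& lengths,
                                const arma::imat& qindex,
                                const List& eigensystems,
                                const List& generators,
                                const arma::imat& tipstates,
                                const arma::vec& pi,
                                const int n_tip,
                                const int n_node,
                                const int root,
                                const arma::vec& proportions,
                                const arma::vec& weights) {
  const std::vector<EigenSys> es = unpack_systems(eigensystems);
  const int n_q = eigensystems.size();
  std::vector<arma::mat> gen(n_q);
  for (int q = 0; q < n_q; ++q) gen[q] = as<arma::mat>(generators[q]);

  const int n_state = pi.n_elem;
  const int n_edge = edge.n_rows;
  const int n_pat = tipstates.n_cols;
  const int n_class = qindex.n_rows;

  arma::mat loglik(n_pat, n_class);
  arma::cube ratio(n_pat, n_class, n_edge); // g_e / L per pattern, class

  std::vector<arma::mat> edge_factor(n_edge);
  std::vector<arma::mat> node_partial(n_node + 1);
  std::vector<arma::mat> node_out(n_node + 1);
  arma::vec ll(n_pat);

  // children edges of every node, in postorder edge indexing
  std::vector<std::vector<int>> child_edges(n_node + 1);
  for (int e = 0; e < n_edge; ++e) child_edges[edge(e, 0)].push_back(e);

  for (int k = 0; k < n_class; ++k) {
    down_pass(edge, lengths, qindex.row(k), es, tipstates, pi,
              n_tip, n_node, root, edge_factor, node_partial, ll);
    loglik.col(k) = ll;

    // outside (preorder) pass: node_out[v] such that for edge e = (u, v),
    // F_e = node_out[u] % prod_{siblings e'} edge_factor[e'] and
    // sum_i F_e(i, j) * edge_factor[e](i, j) == scaled L_j.
    node_out[root] = arma::repmat(pi, 1, n_pat);
    for (int e = n_edge - 1; e >= 0; --e) { // preorder = reversed postorder
      const int parent = edge(e, 0);
      const int child = edge(e, 1);
      arma::mat F = node_out[parent];
      for (int sib : child_edges[parent]) {
        if (sib != e) F %= edge_factor[sib];
      }
      const int qi = qindex(k, e) - 1;
      // numerator: F . (A * d), denominator: F . d, columnwise
      const arma::mat Ad = gen[qi] * edge_factor[e];
      const arma::rowvec num = arma::sum(F % Ad, 0);
      const arma::rowvec den = arma::sum(F % edge_factor[e], 0);
      for (int j = 0; j < n_pat; ++j) {
        ratio(j, k, e) = den(j) > 0 ? num(j) / den(j) : 0.0;
      }
      if (child > n_tip) {
        const arma::mat P = trans_prob(es[qi], lengths[e]);
        node_out[child] = P.t() * F;
        // keep outside partials in a sane range per pattern
        arma::rowvec m = arma::max(node_out[child], 0);
        m.elem(arma::find(m <= 0)).ones();
        node_out[child].each_row() /= m;
      }
    }
  }

  // mixture posterior weights per pattern/class, from logliks (stable)
  arma::vec grad(n_edge, arma::fill::zeros);
  arma::vec mix(n_pat);
  for (int j = 0; j < n_pat; ++j) {
    const arma::rowvec lw = loglik.row(j) +
      arma::log(proportions.t());
    const double m = lw.max();
    const arma::rowvec post_un = arma::exp(lw - m);
    const double tot = arma::accu(post_un);
    mix(j) = m + std::log(tot);
    for (int e = 0; e < n_edge; ++e) {
      double g = 0;
      for (int k = 0; k < n_class; ++k) {
        g += (post_un(k) / tot) * ratio(j, k, e);
      }
      grad(e) += weights(j) * g;
    }
  }

  return List::create(
    _["loglik"] = loglik,
    _["grad_s"] = grad,
    _["lnL"] = arma::dot(weights, mix)
  );
}
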