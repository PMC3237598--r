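// Felsenstein pruning over a discrete-gamma mixture for a fixed topology.
// Transition matrices are assembled per edge and category from the symmetric
// eigendecomposition of the reversible rate matrix: P(t) = A exp(Lt) B.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// edge: (E x 2) 1-based ape edge matrix in postorder (child edges precede
// the edge above their parent). tip_states: (n_tip x S), 0..19, 20 = missing.
// Returns per-site log-likelihood averaged over equal-weight rate categories.
// [[Rcpp::export]]
arma::vec pruning_sitelik_cpp(const arma::imat& edge, int n_tip,
                              const arma::imat& tip_states,
                              const arma::vec& lengths,
                              const arma::vec& eigval,
                              const arma::mat& A, const arma::mat& B,
                              const arma::vec& pi, const arma::vec& rates) {
  const int S = tip_states.n_cols;
  const int E = edge.n_rows;
  const int n_node = edge.max();
  const int K = rates.n_elem;
  const int root = edge(E - 1, 0) - 1;  // parent of last postorder edge

  arma::mat cat_loglik(K, S);  // per-category per-site log-likelihood

  for (int k = 0; k < K; ++k) {
    std::vector<arma::mat> part(n_node);
    arma::mat logscale(n_node, S, arma::fill::zeros);
    std::vector<bool> started(n_node, false);

    for (int e = 0; e < E; ++e) {
      const int parent = edge(e, 0) - 1;
      const int child = edge(e, 1) - 1;
      const double t = lengths(e) * rates(k);
      arma::mat P = A * arma::diagmat(arma::exp(eigval * t)) * B;
      P.elem(arma::find(P < 0)).zeros();

      arma::mat contrib(20, S);
      if (child < n_tip) {
        for (int s = 0; s < S; ++s) {
          const int st = tip_states(child, s);
          if (st >= 20)
            contrib.col(s) = arma::sum(P, 1);  // missing: integrate all states
          else
            contrib.col(s) = P.col(st);
        }
      } else {
        contrib = P * part[child];
      }

      if (!started[parent]) {
        part[parent] = contrib;
        started[parent] = true;
        if (child >= n_tip) logscale.row(parent) = logscale.row(child);
      } else {
        part[parent] %= contrib;
        if (child >= n_tip) logscale.row(parent) += logscale.row(child);
      }
      // rescale columns drifting toward underflow
      arma::rowvec mx = arma::max(part[parent], 0);
      for (int s = 0; s < S; ++s) {
        if (mx(s) > 0 && mx(s) < 1e-100) {
          part[parent].col(s) /= mx(s);
          logscale(parent, s) += std::log(mx(s));
        }
      }
    }

    arma::rowvec lik = pi.t() * part[root];
    for (int s = 0; s < S; ++s)
      cat_loglik(k, s) = std::log(lik(s)) + logscale(root, s);
  }

  // log-mean-exp over categories
  arma::vec out(S);
  for (int s = 0; s < S; ++s) {
    const double m = cat_loglik.col(s).max();
    out(s) = m + std::log(arma::mean(arma::exp(cat_loglik.col(s) - m)));
  }
  return out;
}

// One coordinate sweep of branch-length optimisation. Down (postorder) and
// up (preorder) partials are computed once from the current lengths; each
// edge is then optimised by golden-section search on its local profile
// likelihood  L(t) = sum_s w_s log sum_k a_k(s) U_k(e,s)' P_k(t) D_k(e,s).
// Per-column rescaling keeps partials in range; the scale factors do not
// depend on the length being optimised, so they enter only through the
// fixed per-site category weights a_k(s). The caller verifies the sweep
// against the exact pruning total.
// [[Rcpp::export]]
arma::vec sweep_branches_cpp(const arma::imat& edge, int n_tip,
                             const arma::imat& tip_states,
                             const arma::vec& weights,
                             const arma::vec& lengths_in,
                             const arma::vec& eigval,
                             const arma::mat& A, const arma::mat& B,
                             const arma::vec& pi, const arma::vec& rates,
                             double min_len, double max_len, double tol) {
  const int S = tip_states.n_cols;
  const int E = edge.n_rows;
  const int n_node = edge.max();
  const int K = rates.n_elem;
  const int root = edge(E - 1, 0) - 1;
  arma::vec lengths = lengths_in;

  // tip contribution matrix (indicator / all-ones) cached per tip
  auto tip_D = [&](int tip) {
    arma::mat D(20, S, arma::fill::zeros);
    for (int s = 0; s < S; ++s) {
      const int st = tip_states(tip, s);
      if (st >= 20) D.col(s).ones(); else D(st, s) = 1.0;
    }
    return D;
  };

  auto pmat = [&](double t, double r) {
    arma::mat P = A * arma::diagmat(arma::exp(eigval * (t * r))) * B;
    P.elem(arma::find(P < 0)).zeros();
    return P;
  };

  // children edges of each node
  std::vector<std::vector<int>> child_edges(n_node);
  std::vector<int> parent_edge(n_node, -1);
  for (int e = 0; e < E; ++e) {
    child_edges[edge(e, 0) - 1].push_back(e);
    parent_edge[edge(e, 1) - 1] = e;
  }

  // per category: contrib per edge, down per node, up per edge, log-scales
  std::vector<std::vector<arma::mat>> contrib(K), up(K);
  std::vector<std::vector<arma::mat>> down(K);
  std::vector<arma::mat> ls_down(K), ls_up(K);  // (n_node|E) x S

  for (int k = 0; k < K; ++k) {
    contrib[k].assign(E, arma::mat());
    down[k].assign(n_node, arma::mat());
    up[k].assign(E, arma::mat());
    ls_down[k].zeros(n_node, S);
    ls_up[k].zeros(E, S);

    // postorder: contrib and down
    for (int e = 0; e < E; ++e) {
      const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      arma::mat P = pmat(lengths(e), rates(k));
      contrib[k][e] = (c < n_tip) ? arma::mat(P * tip_D(c))
                                  : arma::mat(P * down[k][c]);
      if (down[k][p].n_elem == 0) {
        down[k][p] = contrib[k][e];
        if (c >= n_tip) ls_down[k].row(p) = ls_down[k].row(c);
      } else {
        down[k][p] %= contrib[k][e];
        if (c >= n_tip) ls_down[k].row(p) += ls_down[k].row(c);
      }
      arma::rowvec mx = arma::max(down[k][p], 0);
      for (int s = 0; s < S; ++s)
        if (mx(s) > 0 && mx(s) < 1e-120) {
          down[k][p].col(s) /= mx(s);
          ls_down[k](p, s) += std::log(mx(s));
        }
    }
    // preorder: up
    for (int e = E - 1; e >= 0; --e) {
      const int p = edge(e, 0) - 1;
      arma::mat U;
      arma::rowvec ls(S, arma::fill::zeros);
      if (p == root) {
        U = arma::repmat(pi, 1, S);
      } else {
        const int f = parent_edge[p];
        arma::mat Pf = pmat(lengths(f), rates(k));
        U = Pf.t() * up[k][f];
        ls = ls_up[k].row(f);
      }
      for (int sib : child_edges[p]) {
        if (sib == e) continue;
        const int sc = edge(sib, 1) - 1;
        U %= contrib[k][sib];
        if (sc >= n_tip) ls += ls_down[k].row(sc);
      }
      arma::rowvec mx = arma::max(U, 0);
      for (int s = 0; s < S; ++s)
        if (mx(s) > 0 && mx(s) < 1e-120) {
          U.col(s) /= mx(s);
          ls(s) += std::log(mx(s));
        }
      up[k][e] = U;
      ls_up[k].row(e) = ls;
    }
  }

  // optimise each edge on its local profile
  for (int e = 0; e < E; ++e) {
    const int c = edge(e, 1) - 1;
    // fixed per-site category weights from the scale factors
    arma::mat ls_tot(K, S);
    for (int k = 0; k < K; ++k) {
      arma::rowvec lsd = (c >= n_tip) ? ls_down[k].row(c)
                                      : arma::rowvec(S, arma::fill::zeros);
      ls_tot.row(k) = ls_up[k].row(e) + lsd;
    }
    arma::rowvec m = arma::max(ls_tot, 0);
    arma::mat alpha = arma::exp(ls_tot - arma::repmat(m, K, 1));

    std::vector<arma::mat> D(K);
    for (int k = 0; k < K; ++k)
      D[k] = (c < n_tip) ? tip_D(c) : down[k][c];

    auto f = [&](double t) {
      arma::rowvec tot(S, arma::fill::zeros);
      for (int k = 0; k < K; ++k) {
        arma::mat PD = pmat(t, rates(k)) * D[k];
        tot += alpha.row(k) % arma::sum(up[k][e] % PD, 0);
      }
      double ll = 0.0;
      for (int s = 0; s < S; ++s) ll += weights(s) * std::log(tot(s));
      return ll;
    };

    // golden-section on a warm bracket, widened at the boundary
    double lo = std::max(min_len, lengths(e) / 8.0);
    double hi = std::min(max_len, std::max(lengths(e) * 8.0, 0.5));
    const double gr = 0.6180339887498949;
    for (int attempt = 0; attempt < 2; ++attempt) {
      double a = lo, b = hi;
      double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
      double f1 = f(x1), f2 = f(x2);
      while (b - a > tol) {
        if (f1 < f2) { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = f(x2); }
        else { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = f(x1); }
      }
      double t_new = (f1 > f2) ? x1 : x2;
      if (attempt == 0 &&
          (t_new <= lo * 1.05 || t_new >= hi * 0.95) &&
          (lo > min_len * 1.5 || hi < max_len * 0.67)) {
        lo = min_len; hi = max_len;  // boundary hit: search the full range
        continue;
      }
      if (f(t_new) >= f(lengths(e))) lengths(e) = t_new;
      break;
    }
  }
  return lengths;
}
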