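// Hot loops of the codon-model likelihood: transition matrices from a
// precomputed symmetric eigendecomposition, and Felsenstein pruning with
// per-node log scaling.  Everything model-related stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// P(t) = D^{-1/2} V exp(lambda t) V' D^{1/2} for each t, clamped to [0,1].
// [[Rcpp::export]]
arma::cube cpp_transition_matrices(const arma::mat& V,
                                   const arma::vec& lambda,
                                   const arma::vec& sqrtpi,
                                   const arma::vec& t) {
  const uword n = V.n_rows;
  cube out(n, n, t.n_elem);
  vec inv_sq = 1.0 / sqrtpi;
  for (uword k = 0; k < t.n_elem; ++k) {
    mat E = V * diagmat(exp(lambda * t[k])) * V.t();
    mat P = diagmat(inv_sq) * E * diagmat(sqrtpi);
    P.clamp(0.0, 1.0);
    // renormalise rows: clamping can leave row sums a hair off 1
    P.each_col() /= sum(P, 1);
    out.slice(k) = P;
  }
  return out;
}

// Full up-pass: like cpp_prune_loglik but also returns, for every node,
// the rescaled partial-likelihood matrix and its per-site log scale, and
// for every edge the contribution matrix P_e * partial(child).  These feed
// the outside-partial (down-pass) machinery used for per-edge branch
// length optimisation.
// [[Rcpp::export]]
Rcpp::List cpp_prune_all(const arma::imat& edge,
                         const arma::cube& tips,
                         const arma::cube& P,
                         const arma::vec& pi,
                         const int nnode,
                         const int root) {
  const uword nstate = tips.n_rows;
  const uword nsite = tips.n_cols;
  const uword ntip = tips.n_slices;

  cube inhat(nstate, nsite, nnode, fill::zeros);
  mat ls_in(nnode, nsite, fill::zeros);
  cube contrib(nstate, nsite, edge.n_rows);
  std::vector<bool> touched(nnode, false);

  for (uword i = 0; i < ntip; ++i) {
    inhat.slice(i) = tips.slice(i);
    touched[i] = true;
  }
  for (uword e = 0; e < edge.n_rows; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    if ((uword)child >= ntip) {
      // rescale the internal child's accumulated partial
      mat& cp = inhat.slice(child);
      rowvec m = max(cp, 0);
      for (uword s = 0; s < nsite; ++s) {
        if (m[s] > 0 && m[s] != 1.0) {
          cp.col(s) /= m[s];
          ls_in(child, s) += std::log(m[s]);
        }
      }
    }
    contrib.slice(e) = P.slice(e) * inhat.slice(child);
    if (!touched[parent]) {
      inhat.slice(parent) = contrib.slice(e);
      ls_in.row(parent) = ls_in.row(child);
      touched[parent] = true;
    } else {
      inhat.slice(parent) %= contrib.slice(e);
      ls_in.row(parent) += ls_in.row(child);
    }
  }

  vec loglik(nsite);
  const mat& rp = inhat.slice(root - 1);
  for (uword s = 0; s < nsite; ++s) {
    double lik = dot(pi, rp.col(s));
    loglik[s] = (lik > 0) ? std::log(lik) + ls_in(root - 1, s)
                          : -datum::inf;
  }
  return Rcpp::List::create(Rcpp::Named("inhat") = inhat,
                            Rcpp::Named("ls_in") = ls_in,
                            Rcpp::Named("contrib") = contrib,
                            Rcpp::Named("loglik") = loglik);
}

// Per-site log-likelihood profile of one branch length: given the outside
// partial A (with log-scale ls_A) at the parent side of an edge and the
// inside partial B (ls_B) below it, returns sum_s w_s *
// [log(A[,s]' P B[,s]) + ls_A[s] + ls_B[s]].
// [[Rcpp::export]]
double cpp_edge_loglik(const arma::mat& A, const arma::mat& B,
                       const arma::mat& P, const arma::vec& ls,
                       const arma::vec& w) {
  mat M = P * B;
  double out = 0.0;
  for (uword s = 0; s < A.n_cols; ++s) {
    double lik = dot(A.col(s), M.col(s));
    if (lik <= 0) return -datum::inf;
    out += w[s] * (std::log(lik) + ls[s]);
  }
  return out;
}

// P(t) for one decomposition and one t, written into a preallocated slice.
static void fill_P(mat& out, const mat& V, const vec& lambda,
                   const vec& sqrtpi, const double t) {
  mat E = V * diagmat(exp(lambda * t)) * V.t();
  out = diagmat(1.0 / sqrtpi) * E * diagmat(sqrtpi);
  out.clamp(0.0, 1.0);
  out.each_col() /= sum(out, 1);
}

// All four site-class pattern log-likelihoods of branch-site Model A in
// one call.  Classes 0 and 1 are full prunings with the background cubes
// P0 (omega0) and P1 (omega = 1); classes 2a and 2b reuse those up-passes
// and only recompute the path from the foreground edges to the root with
// the foreground slices P2fg.  When null_equal is true (omega2 = 1 with
// equal scaling), class 2b equals class 1 and is copied.
// [[Rcpp::export]]
arma::mat cpp_modelA_logliks(const arma::imat& edge,
                             const arma::cube& tips,
                             const arma::mat& V0, const arma::vec& lam0,
                             const arma::mat& V1, const arma::vec& lam1,
                             const arma::mat& V2, const arma::vec& lam2,
                             const arma::vec& sqrtpi,
                             const arma::vec& len,
                             const arma::vec& rho,
                             const arma::ivec& fg_idx,
                             const arma::vec& pi,
                             const int nnode,
                             const int root,
                             const bool null_equal) {
  const uword nstate = tips.n_rows;
  const uword nsite = tips.n_cols;
  const uword ntip = tips.n_slices;
  const uword nedge = edge.n_rows;

  cube P0(nstate, nstate, nedge), P1(nstate, nstate, nedge);
  cube P2fg(nstate, nstate, fg_idx.n_elem);
  for (uword e = 0; e < nedge; ++e) {
    fill_P(P0.slice(e), V0, lam0, sqrtpi, len[e] * rho[0]);
    fill_P(P1.slice(e), V1, lam1, sqrtpi, len[e] * rho[1]);
  }
  for (uword k = 0; k < fg_idx.n_elem; ++k) {
    if (null_equal) {
      P2fg.slice(k) = P1.slice(fg_idx[k] - 1);
    } else {
      fill_P(P2fg.slice(k), V2, lam2, sqrtpi,
             len[fg_idx[k] - 1] * rho[2]);
    }
  }

  std::vector<int> fg_of(nedge, -1);
  for (uword k = 0; k < fg_idx.n_elem; ++k) fg_of[fg_idx[k] - 1] = k;

  mat out(nsite, 4);

  cube inhat(nstate, nsite, nnode);
  mat ls_in(nnode, nsite);
  cube contrib(nstate, nsite, nedge);

  // full up-pass with bookkeeping; returns per-site loglik
  auto uppass = [&](const cube& P, vec& loglik) {
    std::vector<bool> touched(nnode, false);
    ls_in.zeros();
    for (uword i = 0; i < ntip; ++i) {
      inhat.slice(i) = tips.slice(i);
      touched[i] = true;
    }
    for (uword e = 0; e < nedge; ++e) {
      const int parent = edge(e, 0) - 1;
      const int child = edge(e, 1) - 1;
      if ((uword)child >= ntip) {
        mat& cp = inhat.slice(child);
        rowvec m = max(cp, 0);
        for (uword s = 0; s < nsite; ++s) {
          if (m[s] > 0 && m[s] != 1.0) {
            cp.col(s) /= m[s];
            ls_in(child, s) += std::log(m[s]);
          }
        }
      }
      contrib.slice(e) = P.slice(e) * inhat.slice(child);
      if (!touched[parent]) {
        inhat.slice(parent) = contrib.slice(e);
        ls_in.row(parent) = ls_in.row(child);
        touched[parent] = true;
      } else {
        inhat.slice(parent) %= contrib.slice(e);
        ls_in.row(parent) += ls_in.row(child);
      }
    }
    const mat& rp = inhat.slice(root - 1);
    for (uword s = 0; s < nsite; ++s) {
      double lik = dot(pi, rp.col(s));
      loglik[s] = (lik > 0) ? std::log(lik) + ls_in(root - 1, s)
                            : -datum::inf;
    }
  };

  // recompute only the foreground-to-root paths against the stored
  // up-pass, with the foreground edges using P2fg
  auto patch = [&](const cube& P, vec& loglik) {
    std::vector<bool> dirty_edge(nedge, false), dirty_node(nnode, false);
    cube cnew(nstate, nsite, nedge);   // only dirty slices used
    mat lsnew(nedge, nsite, fill::zeros);
    mat rootB;
    rowvec rootls;
    for (uword e = 0; e <= nedge; ++e) {
      if (e == nedge) {
        // rebuild the root partial
        rootB = mat(nstate, nsite, fill::ones);
        rootls = rowvec(nsite, fill::zeros);
        for (uword e2 = 0; e2 < nedge; ++e2) {
          if ((int)(edge(e2, 0) - 1) != root - 1) continue;
          if (dirty_edge[e2]) {
            rootB %= cnew.slice(e2);
            rootls += lsnew.row(e2);
          } else {
            rootB %= contrib.slice(e2);
            rootls += ls_in.row(edge(e2, 1) - 1);
          }
        }
        break;
      }
      const int child = edge(e, 1) - 1;
      const bool patched = fg_of[e] >= 0;
      if (!patched && !dirty_node[child]) continue;
      mat B;
      rowvec lsB;
      if (dirty_node[child]) {
        B = mat(nstate, nsite, fill::ones);
        lsB = rowvec(nsite, fill::zeros);
        for (uword e2 = 0; e2 < e; ++e2) {
          if ((int)(edge(e2, 0) - 1) != child) continue;
          if (dirty_edge[e2]) {
            B %= cnew.slice(e2);
            lsB += lsnew.row(e2);
          } else {
            B %= contrib.slice(e2);
            lsB += ls_in.row(edge(e2, 1) - 1);
          }
        }
        rowvec m = max(B, 0);
        for (uword s = 0; s < nsite; ++s) {
          if (m[s] > 0) {
            B.col(s) /= m[s];
            lsB[s] += std::log(m[s]);
          }
        }
      } else {
        B = inhat.slice(child);
        lsB = ls_in.row(child);
      }
      const mat& Pe = patched ? P2fg.slice(fg_of[e]) : P.slice(e);
      cnew.slice(e) = Pe * B;
      lsnew.row(e) = lsB;
      dirty_edge[e] = true;
      dirty_node[edge(e, 0) - 1] = true;
    }
    for (uword s = 0; s < nsite; ++s) {
      double lik = dot(pi, rootB.col(s));
      loglik[s] = (lik > 0) ? std::log(lik) + rootls[s] : -datum::inf;
    }
  };

  vec l0(nsite), l1(nsite), l2a(nsite), l2b(nsite);
  uppass(P0, l0);
  patch(P0, l2a);
  uppass(P1, l1);
  if (null_equal) l2b = l1; else patch(P1, l2b);
  out.col(0) = l0;
  out.col(1) = l1;
  out.col(2) = l2a;
  out.col(3) = l2b;
  return out;
}

// Per-site log-likelihood by postorder pruning.
//   edge:     nedge x 2 matrix (parent, child), 1-based ape node ids,
//             ordered so every child appears before its own parent edge.
//   tips:     nstate x nsite x ntip cube of tip partial likelihoods.
//   P:        nstate x nstate x nedge cube, slice i transposed-ready for
//             edge row i (P[a,b] = prob a->b along the branch).
//   nnode:    total node count (tips + internals).
//   root:     1-based id of the root node.
//   logpi:    not used; pi passed directly.
// Returns numeric(nsite) of per-site log-likelihoods.
// [[Rcpp::export]]
arma::vec cpp_prune_loglik(const arma::imat& edge,
                           const arma::cube& tips,
                           const arma::cube& P,
                           const arma::vec& pi,
                           const int nnode,
                           const int root) {
  const uword nstate = tips.n_rows;
  const uword nsite = tips.n_cols;
  const uword ntip = tips.n_slices;

  std::vector<mat> partial(nnode);
  std::vector<rowvec> logscale(nnode);
  std::vector<bool> touched(nnode, false);

  for (uword e = 0; e < edge.n_rows; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    mat cp;
    rowvec csc;
    if ((uword)child < ntip) {
      cp = tips.slice(child);
      csc = rowvec(nsite, fill::zeros);
    } else {
      cp = partial[child];
      csc = logscale[child];
      // rescale to dodge underflow on deep trees
      rowvec m = max(cp, 0);
      for (uword s = 0; s < nsite; ++s) {
        if (m[s] > 0) {
          cp.col(s) /= m[s];
          csc[s] += std::log(m[s]);
        }
      }
    }
    mat contrib = P.slice(e) * cp;  // nstate x nsite
    if (!touched[parent]) {
      partial[parent] = contrib;
      logscale[parent] = csc;
      touched[parent] = true;
    } else {
      partial[parent] %= contrib;
      logscale[parent] += csc;
    }
  }

  vec out(nsite);
  const mat& rp = partial[root - 1];
  const rowvec& rs = logscale[root - 1];
  for (uword s = 0; s < nsite; ++s) {
    double lik = dot(pi, rp.col(s));
    out[s] = (lik > 0) ? std::log(lik) + rs[s] : -datum::inf;
  }
  return out;
}
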