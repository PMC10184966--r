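// Graphical lasso by block coordinate descent over the covariance estimate W
// (one lasso subproblem per column), with warm starts along a penalty path.
// Solves: maximize log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|
// The penalty applies to off-diagonal entries only, so the W diagonal is fixed at diag(S)
// as in the standard algorithm. The column subproblems are run on the full
// matrices with a zero-padded coefficient vector (beta_j = 0), which avoids
// submatrix copies in the hot loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// lasso coordinate descent for column j: beta minimizes
//   1/2 beta' W11 beta - s12' beta + lambda |beta|_1
// beta has length p with beta[j] fixed at 0 so full columns of W can be used.
static void lasso_cd_col(const mat& W, const double* sj, uword j,
                         double lambda, double* beta, double tol, int maxit) {
  const uword p = W.n_rows;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      const double* wk = W.colptr(k);
      double acc = 0.0;
      for (uword l = 0; l < p; ++l) acc += wk[l] * beta[l];
      double r = sj[k] - acc + wk[k] * beta[k];
      double bnew;
      if (r > lambda)       bnew = (r - lambda) / wk[k];
      else if (r < -lambda) bnew = (r + lambda) / wk[k];
      else                  bnew = 0.0;
      double d = std::abs(bnew - beta[k]);
      if (d > dmax) dmax = d;
      beta[k] = bnew;
    }
    if (dmax < tol) break;
  }
}

// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol = 1e-4, int maxit = 200,
                           int maxit_inner = 500) {
  const uword p = S.n_rows;
  const uword L = lambdas.n_elem;

  cube Theta(p, p, L, fill::zeros);
  cube Partial(p, p, L, fill::zeros);  // -Theta_ij / sqrt(Theta_ii Theta_jj)
  vec loglik_core(L, fill::zeros);     // log det(Theta) - tr(S Theta)
  ivec n_edges(L, fill::zeros);        // nonzero upper-triangle partials
  ivec iters(L, fill::zeros);
  ivec converged(L, fill::zeros);

  // scale for the convergence threshold: mean |off-diagonal of S|
  double soff = 0.0;
  if (p > 1) {
    soff = (accu(abs(S)) - accu(abs(S.diag()))) / (double)(p * (p - 1));
  }
  if (soff < 1e-12) soff = 1.0;

  mat W = S;                 // warm start carried across lambdas
  mat B(p, p, fill::zeros);  // zero-padded per-column lasso coefficients
  vec wj(p), beta(p);

  for (uword l = 0; l < L; ++l) {
    double lambda = lambdas(l);
    W.diag() = S.diag();   // diagonal unpenalized: w_ii = s_ii at the optimum
    double thr = tol * soff;
    double inner_tol = thr / 10.0;
    if (inner_tol < 1e-14) inner_tol = 1e-14;

    bool ok = false;
    int it = 0;
    for (; it < maxit; ++it) {
      double dmax = 0.0;
      for (uword j = 0; j < p; ++j) {
        beta = B.col(j);     // explicit copy of the warm start
        lasso_cd_col(W, S.colptr(j), j, lambda, beta.memptr(), inner_tol,
                     maxit_inner);
        wj = W * beta;       // new off-diagonal column j of W (beta(j) = 0)
        for (uword i = 0; i < p; ++i) {
          if (i == j) continue;
          double d = std::abs(W(i, j) - wj(i));
          if (d > dmax) dmax = d;
          W(i, j) = wj(i);
          W(j, i) = wj(i);
        }
        B.col(j) = beta;
      }
      if (dmax < thr) { ok = true; ++it; break; }
    }
    iters(l) = it;
    converged(l) = ok ? 1 : 0;

    // recover the precision matrix from W and the column coefficients
    mat Th(p, p, fill::zeros);
    for (uword j = 0; j < p; ++j) {
      double th22 = 1.0 / (W(j, j) - dot(W.col(j), B.col(j)));
      Th(j, j) = th22;
      for (uword i = 0; i < p; ++i) {
        if (i == j) continue;
        Th(i, j) = -B(i, j) * th22;
      }
    }
    Th = 0.5 * (Th + Th.t());
    Theta.slice(l) = Th;

    // partial correlations with tiny weights snapped to exact zero
    mat Pc(p, p, fill::zeros);
    int ne = 0;
    for (uword i = 0; i < p; ++i) {
      for (uword j = i + 1; j < p; ++j) {
        double w = -Th(i, j) / std::sqrt(Th(i, i) * Th(j, j));
        if (std::abs(w) < 1e-7) w = 0.0;
        Pc(i, j) = w;
        Pc(j, i) = w;
        if (w != 0.0) ++ne;
      }
    }
    Partial.slice(l) = Pc;
    n_edges(l) = ne;

    double ld, sign;
    bool okld = log_det(ld, sign, Th);
    if (!okld || sign <= 0) {
      loglik_core(l) = datum::nan;
    } else {
      loglik_core(l) = ld - accu(S % Th);
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("theta") = Theta,
    Rcpp::Named("partial") = Partial,
    Rcpp::Named("loglik_core") = loglik_core,
    Rcpp::Named("n_edges") = n_edges,
    Rcpp::Named("iters") = iters,
    Rcpp::Named("converged") = converged);
}

// Same path, but the EBIC selection happens in the loop and only the selected
// model is returned (hot loops: bootstrap replicates, permutation tests).
// EBIC = -2L + E log(n) + 4 gamma E log(p), L = n/2 (log det T - tr(S T)).
// Ties keep the earlier (sparser, larger-lambda) model.
// [[Rcpp::export]]
Rcpp::List glasso_select_cpp(const arma::mat& S, const arma::vec& lambdas,
                             double n, double gamma, double tol = 1e-4,
                             int maxit = 200, int maxit_inner = 500) {
  const uword p = S.n_rows;
  const uword L = lambdas.n_elem;
  const double logn = std::log(n);
  const double logp = std::log((double)p);

  vec loglik(L, fill::zeros);
  vec ebic(L);
  ebic.fill(datum::inf);
  ivec n_edges(L, fill::zeros);
  ivec converged(L, fill::zeros);

  double soff = 0.0;
  if (p > 1) {
    soff = (accu(abs(S)) - accu(abs(S.diag()))) / (double)(p * (p - 1));
  }
  if (soff < 1e-12) soff = 1.0;
  double thr = tol * soff;
  double inner_tol = thr / 10.0;
  if (inner_tol < 1e-14) inner_tol = 1e-14;

  mat W = S;
  mat B(p, p, fill::zeros);
  vec wj(p), beta(p);
  mat Th(p, p), Pc(p, p);
  mat best_partial(p, p, fill::zeros);
  double best_ebic = datum::inf;
  int best_idx = -1;

  for (uword l = 0; l < L; ++l) {
    double lambda = lambdas(l);
    W.diag() = S.diag();   // diagonal unpenalized: w_ii = s_ii at the optimum
    bool ok = false;
    for (int it = 0; it < maxit; ++it) {
      double dmax = 0.0;
      for (uword j = 0; j < p; ++j) {
        beta = B.col(j);
        lasso_cd_col(W, S.colptr(j), j, lambda, beta.memptr(), inner_tol,
                     maxit_inner);
        wj = W * beta;
        for (uword i = 0; i < p; ++i) {
          if (i == j) continue;
          double d = std::abs(W(i, j) - wj(i));
          if (d > dmax) dmax = d;
          W(i, j) = wj(i);
          W(j, i) = wj(i);
        }
        B.col(j) = beta;
      }
      if (dmax < thr) { ok = true; break; }
    }
    converged(l) = ok ? 1 : 0;
    if (!ok) continue;

    Th.zeros();
    for (uword j = 0; j < p; ++j) {
      double th22 = 1.0 / (W(j, j) - dot(W.col(j), B.col(j)));
      Th(j, j) = th22;
      for (uword i = 0; i < p; ++i) {
        if (i == j) continue;
        Th(i, j) = -B(i, j) * th22;
      }
    }
    Th = 0.5 * (Th + Th.t());

    int ne = 0;
    Pc.zeros();
    for (uword i = 0; i < p; ++i) {
      for (uword j2 = i + 1; j2 < p; ++j2) {
        double w = -Th(i, j2) / std::sqrt(Th(i, i) * Th(j2, j2));
        if (std::abs(w) < 1e-7) w = 0.0;
        Pc(i, j2) = w;
        Pc(j2, i) = w;
        if (w != 0.0) ++ne;
      }
    }
    n_edges(l) = ne;

    double ld, sign;
    bool okld = log_det(ld, sign, Th);
    if (!okld || sign <= 0) continue;
    double llc = ld - accu(S % Th);
    loglik(l) = 0.5 * n * llc;
    double eb = -n * llc + ne * logn + 4.0 * gamma * ne * logp;
    ebic(l) = eb;
    if (eb < best_ebic) {
      best_ebic = eb;
      best_idx = (int)l;
      best_partial = Pc;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("partial") = best_partial,
    Rcpp::Named("best") = best_idx + 1,
    Rcpp::Named("ebic") = ebic,
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("n_edges") = n_edges,
    Rcpp::Named("converged") = converged);
}

// single EBIC-glasso fit used inside the permutation loop; returns the
// selected partial-correlation matrix, or false if no penalty converged
static bool fit_ebic_net(const mat& S, double n, double gamma,
                         int n_lambda, double lambda_min_ratio,
                         double tol, int maxit, int maxit_inner,
                         mat& out_partial) {
  const uword p = S.n_rows;
  const double logn = std::log(n);
  const double logp = std::log((double)p);

  double lmax = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      if (std::abs(S(i, j)) > lmax) lmax = std::abs(S(i, j));
  if (lmax <= 0) lmax = 0.1;

  double soff = (accu(abs(S)) - accu(abs(S.diag()))) / (double)(p * (p - 1));
  if (soff < 1e-12) soff = 1.0;
  double thr = tol * soff;
  double inner_tol = std::max(thr / 10.0, 1e-14);

  const double lstep = (n_lambda > 1)
    ? std::log(lambda_min_ratio) / (double)(n_lambda - 1) : 0.0;

  mat W = S;
  mat B(p, p, fill::zeros);
  vec wj(p), beta(p);
  mat Th(p, p), Pc(p, p);
  double best_ebic = datum::inf;
  bool have = false;

  for (int l = 0; l < n_lambda; ++l) {
    double lambda = lmax * std::exp(lstep * l);
    W.diag() = S.diag();   // diagonal unpenalized: w_ii = s_ii at the optimum
    bool ok = false;
    for (int it = 0; it < maxit; ++it) {
      double dmax = 0.0;
      for (uword j = 0; j < p; ++j) {
        beta = B.col(j);
        lasso_cd_col(W, S.colptr(j), j, lambda, beta.memptr(), inner_tol,
                     maxit_inner);
        wj = W * beta;
        for (uword i = 0; i < p; ++i) {
          if (i == j) continue;
          double d = std::abs(W(i, j) - wj(i));
          if (d > dmax) dmax = d;
          W(i, j) = wj(i);
          W(j, i) = wj(i);
        }
        B.col(j) = beta;
      }
      if (dmax < thr) { ok = true; break; }
    }
    if (!ok) continue;

    Th.zeros();
    for (uword j = 0; j < p; ++j) {
      double th22 = 1.0 / (W(j, j) - dot(W.col(j), B.col(j)));
      Th(j, j) = th22;
      for (uword i = 0; i < p; ++i) {
        if (i == j) continue;
        Th(i, j) = -B(i, j) * th22;
      }
    }
    Th = 0.5 * (Th + Th.t());

    int ne = 0;
    Pc.zeros();
    for (uword i = 0; i < p; ++i) {
      for (uword j2 = i + 1; j2 < p; ++j2) {
        double w = -Th(i, j2) / std::sqrt(Th(i, i) * Th(j2, j2));
        if (std::abs(w) < 1e-7) w = 0.0;
        Pc(i, j2) = w;
        Pc(j2, i) = w;
        if (w != 0.0) ++ne;
      }
    }

    double ld, sign;
    if (!log_det(ld, sign, Th) || sign <= 0) continue;
    double llc = ld - accu(S % Th);
    double eb = -n * llc + ne * logn + 4.0 * gamma * ne * logp;
    if (eb < best_ebic) {
      best_ebic = eb;
      out_partial = Pc;
      have = true;
    }
  }
  return have;
}

static void pearson_cor(const mat& X, mat& S) {
  const uword n = X.n_rows;
  mat Z = X;
  for (uword j = 0; j < Z.n_cols; ++j) {
    double mu = mean(Z.col(j));
    double sd = stddev(Z.col(j));
    Z.col(j) = (Z.col(j) - mu) / sd;
  }
  S = (Z.t() * Z) / (double)(n - 1);
  S.diag().ones();
}

// Permutation loop of the network comparison test (Pearson input only).
// perm: n_perm x n_a matrix of 1-based row indices assigned to group A.
// Returns per-permutation M and S statistics, per-edge counts of
// |perm diff| >= |observed diff|, and a success flag per permutation.
// [[Rcpp::export]]
Rcpp::List nct_perm_cpp(const arma::mat& pooled, const arma::imat& perm,
                        const arma::vec& obs_diff, double gamma,
                        int n_lambda, double lambda_min_ratio,
                        double tol = 1e-4, int maxit = 200,
                        int maxit_inner = 500) {
  const uword n = pooled.n_rows;
  const uword p = pooled.n_cols;
  const uword n_perm = perm.n_rows;
  const uword n_a = perm.n_cols;
  const uword n_pairs = p * (p - 1) / 2;

  vec m_perm(n_perm, fill::zeros);
  vec s_perm(n_perm, fill::zeros);
  vec edge_ge(n_pairs, fill::zeros);
  ivec ok(n_perm, fill::zeros);

  mat Sa(p, p), Sb(p, p), Wa(p, p), Wb(p, p);
  std::vector<char> inA(n);

  for (uword r = 0; r < n_perm; ++r) {
    std::fill(inA.begin(), inA.end(), 0);
    for (uword c = 0; c < n_a; ++c) inA[perm(r, c) - 1] = 1;
    mat Xa(n_a, p), Xb(n - n_a, p);
    uword ia = 0, ib = 0;
    for (uword i = 0; i < n; ++i) {
      if (inA[i]) Xa.row(ia++) = pooled.row(i);
      else        Xb.row(ib++) = pooled.row(i);
    }
    pearson_cor(Xa, Sa);
    pearson_cor(Xb, Sb);
    if (!fit_ebic_net(Sa, (double)n_a, gamma, n_lambda, lambda_min_ratio,
                      tol, maxit, maxit_inner, Wa)) continue;
    if (!fit_ebic_net(Sb, (double)(n - n_a), gamma, n_lambda,
                      lambda_min_ratio, tol, maxit, maxit_inner, Wb)) continue;
    ok(r) = 1;
    double m = 0.0, sa = 0.0, sb = 0.0;
    uword e = 0;
    // upper triangle in column-major order to match R's upper.tri()
    for (uword j = 1; j < p; ++j) {
      for (uword i = 0; i < j; ++i) {
        double d = std::abs(Wa(i, j) - Wb(i, j));
        if (d > m) m = d;
        sa += std::abs(Wa(i, j));
        sb += std::abs(Wb(i, j));
        if (d >= obs_diff(e) - 1e-12) edge_ge(e) += 1.0;
        ++e;
      }
    }
    m_perm(r) = m;
    s_perm(r) = std::abs(sa - sb);
  }

  return Rcpp::List::create(
    Rcpp::Named("m_perm") = m_perm,
    Rcpp::Named("s_perm") = s_perm,
    Rcpp::Named("edge_ge") = edge_ge,
    Rcpp::Named("ok") = ok);
}
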