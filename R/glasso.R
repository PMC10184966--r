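#' Graphical lasso at a single penalty
#'
#' L1-penalized Gaussian maximum likelihood for a sparse precision matrix:
#' maximizes `log det(Theta) - tr(S Theta) - lambda * sum_(i!=j) |Theta_ij|`
#' (penalty on off-diagonal entries only) by block coordinate descent. Edge
#' weights are the regularized partial correlations
#' `w_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)`.
#'
#' @param S Correlation/covariance matrix (positive semi-definite).
#' @param lambda Penalty, `>= 0`. At `lambda = 0` (and `S` invertible) the
#'   solution is the unpenalized MLE `S^-1`.
#' @param tol Convergence tolerance: the sweep stops when the largest change in
#'   the working covariance is below `tol` times the mean absolute off-diagonal
#'   of `S`.
#' @param maxit Maximum outer sweeps.
#'
#' @return A list: `theta` (precision), `partial` (partial correlations, zero
#'   diagonal, values `|w| < 1e-7` set to exact zero), `loglik_core`
#'   (`log det Theta - tr(S Theta)`), `converged`, `iters`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-4, maxit = 200) {
  stopifnot(lambda >= 0, isSymmetric(unname(S)))
  fit <- glasso_path_cpp(unclass(S), lambda, tol = tol, maxit = maxit)
  if (!fit$converged[1]) {
    stop("graphical lasso did not converge in ", maxit, " sweeps (lambda = ",
         signif(lambda, 4), ")", call. = FALSE)
  }
  theta <- fit$theta[, , 1]
  dimnames(theta) <- dimnames(S)
  list(theta = theta, partial = precision_to_partial(theta),
       loglik_core = fit$loglik_core[1], converged = TRUE, iters = fit$iters[1])
}

precision_to_partial <- function(theta, zero_tol = 1e-7) {
  w <- -theta / sqrt(diag(theta) %o% diag(theta))
  diag(w) <- 0
  w[abs(w) < zero_tol] <- 0
  w
}

#' Extended Bayesian Information Criterion for a Gaussian graphical model
#'
#' `EBIC = -2 L + E log(n) + 4 gamma E log(p)` where `L` is the Gaussian
#' log-likelihood `n/2 (log det Theta - tr(S Theta))` (constants dropped), `E`
#' the number of nonzero upper-triangular edges, `n` the sample size, `p` the
#' node count, and `gamma >= 0` the sparsity hyperparameter (`gamma = 0`
#' reduces to the BIC).
#'
#' @param loglik Log-likelihood `L`.
#' @param n_edges Edge count `E`.
#' @param n Sample size.
#' @param p Number of nodes.
#' @param gamma EBIC hyperparameter.
#' @return The EBIC value.
#' @export
ebic <- function(loglik, n_edges, n, p, gamma = 0.5) {
  stopifnot(n_edges >= 0, n > 0, p > 1, gamma >= 0)
  -2 * loglik + n_edges * log(n) + 4 * gamma * n_edges * log(p)
}

#' Estimate a regularized partial-correlation network with EBIC selection
#'
#' Fits the graphical lasso along a log-spaced penalty path and keeps the
#' penalty minimizing the EBIC. This is the standard estimator for
#' cross-sectional symptom networks: the LASSO shrinks spurious edges to exact
#' zero and the EBIC (conventionally `gamma = 0.5`) selects a sparse,
#' interpretable graph.
#'
#' @param data Data frame of item responses, or a precomputed `"cor_matrix"`
#'   (in which case `n` is taken from its attribute or must be supplied).
#' @param n Sample size (only needed when `data` is a bare matrix).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda Number of penalties on the path (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of
#'   `lambda_max = max |S_ij|` (default 0.01).
#' @param cor_method Correlation method when `data` is raw (default
#'   `"polychoric"`; see [correlation_matrix()]).
#' @param missing Missing-data policy passed to [correlation_matrix()].
#' @param items Optional item columns.
#' @param communities Optional named community vector; defaults to the
#'   anxiety/sleep assignment when the canonical labels are present.
#' @param tol,maxit Solver controls, see [glasso_fit()].
#'
#' @return An object of class `"symptom_network"`: list with `weights` (p x p
#'   regularized partial correlations), `labels`, `communities`, `lambda`,
#'   `gamma`, `ebic`, `n_edges`, `n`, `cor_method` and `trace` (a tibble with
#'   the full path: `lambda`, `loglik`, `n_edges`, `ebic`).
#' @examples
#' net <- build_true_network(seed = 1)
#' dat <- sample_ordinal(net, n = 400, seed = 2)
#' fit <- ebic_glasso(dat, cor_method = "spearman")
#' glance(fit)
#' @export
ebic_glasso <- function(data, n = NULL, gamma = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01,
                        cor_method = c("polychoric", "pearson", "spearman"),
                        missing = "pairwise", items = NULL,
                        communities = NULL, tol = 1e-4, maxit = 200) {
  cor_method <- match.arg(cor_method)
  if (inherits(data, "cor_matrix") || (is.matrix(data) && isSymmetric(unname(data)) &&
                                       all(abs(diag(data) - 1) < 1e-10))) {
    S <- unclass(data)
    if (is.null(n)) n <- attr(data, "n")
    if (is.null(n)) stop("supply n when passing a correlation matrix", call. = FALSE)
    used_method <- attr(data, "method") %||% "supplied"
  } else {
    if (nrow(data) < 2L) stop("need at least 2 observations to estimate a network",
                              call. = FALSE)
    S <- correlation_matrix(data, method = cor_method, missing = missing,
                            items = items)
    n <- attr(S, "n")
    used_method <- cor_method
    S <- unclass(S)
  }
  p <- ncol(S)
  labels <- colnames(S) %||% paste0("V", seq_len(p))
  if (is.null(communities)) {
    communities <- communities_for(labels)
    names(communities) <- labels
  }

  lambdas <- lambda_path(S, n_lambda, lambda_min_ratio)
  fit <- glasso_select_cpp(S, lambdas, n, gamma, tol = tol, maxit = maxit)
  if (fit$best == 0) stop("no penalty on the path converged", call. = FALSE)
  best <- fit$best

  weights <- fit$partial
  dimnames(weights) <- list(labels, labels)
  structure(list(
    weights = weights, labels = labels, communities = communities,
    lambda = lambdas[best], gamma = gamma, ebic = fit$ebic[best],
    n_edges = fit$n_edges[best], n = n, p = p, cor_method = used_method,
    trace = tibble::tibble(lambda = lambdas, loglik = fit$loglik,
                           n_edges = as.integer(fit$n_edges), ebic = fit$ebic,
                           converged = fit$converged == 1L)
  ), class = "symptom_network")
}

lambda_path <- function(S, n_lambda, lambda_min_ratio) {
  lambda_max <- max(abs(S[upper.tri(S)]))
  if (lambda_max <= 0) lambda_max <- 0.1
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = n_lambda))
}

# lean fitter for resampling loops: complete-case numeric matrix in, minimal
# "symptom_network" out (no trace tibble); labels/communities precomputed by
# the caller
fast_network <- function(m, cor_method = "pearson", gamma = 0.5,
                         n_lambda = 100, lambda_min_ratio = 0.01,
                         tol = 1e-4, maxit = 200,
                         labels = NULL, communities = NULL) {
  S <- quick_cor(m, cor_method)
  if (is.null(labels)) labels <- colnames(S)
  lambdas <- lambda_path(S, n_lambda, lambda_min_ratio)
  fit <- glasso_select_cpp(unclass(S), lambdas, nrow(m), gamma,
                           tol = tol, maxit = maxit)
  if (fit$best == 0) stop("no penalty on the path converged", call. = FALSE)
  weights <- fit$partial
  dimnames(weights) <- list(labels, labels)
  structure(list(
    weights = weights, labels = labels, communities = communities,
    lambda = lambdas[fit$best], gamma = gamma, ebic = fit$ebic[fit$best],
    n_edges = fit$n_edges[fit$best], n = nrow(m), p = ncol(m),
    cor_method = cor_method
  ), class = "symptom_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.symptom_network <- function(x, ...) {
  cat("Regularized partial-correlation network (", x$p, " nodes)\n", sep = "")
  cat("  correlation: ", x$cor_method, ", n = ", x$n, "\n", sep = "")
  cat("  lambda = ", signif(x$lambda, 4), " (EBIC gamma = ", x$gamma,
      "), edges = ", x$n_edges, "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted network into an edge list
#'
#' @param x A `"symptom_network"`.
#' @param all Include zero-weight pairs (default `FALSE`).
#' @param ... Unused.
#' @return A tibble `from`, `to`, `weight`, `bridge` (cross-community edge).
#' @export
tidy.symptom_network <- function(x, all = FALSE, ...) {
  el <- tidy_weight_matrix(x$weights, x$labels)
  cm <- x$communities
  el$bridge <- !is.na(cm[el$from]) & !is.na(cm[el$to]) &
    cm[el$from] != cm[el$to]
  if (!all) el <- el[el$weight != 0, ]
  dplyr::arrange(el, dplyr::desc(abs(.data$weight)))
}

#' One-line model summary of a fitted network
#'
#' @param x A `"symptom_network"`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `p`, `lambda`, `gamma`, `ebic`, `n_edges`,
#'   `min_weight`, `max_weight`, `cor_method`.
#' @export
glance.symptom_network <- function(x, ...) {
  w <- upper_tri_vec(x$weights)
  nz <- w[w != 0]
  tibble::tibble(n = x$n, p = x$p, lambda = x$lambda, gamma = x$gamma,
                 ebic = x$ebic, n_edges = x$n_edges,
                 min_weight = if (length(nz)) min(nz) else 0,
                 max_weight = if (length(nz)) max(nz) else 0,
                 cor_method = x$cor_method)
}

#' Write a network as an edge-list TSV and optional GraphML
#'
#' @param net A `"symptom_network"`.
#' @param path Edge-list TSV path.
#' @param graphml Optional GraphML path (written with community and weight
#'   attributes via igraph).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml = NULL) {
  el <- tidy(net)
  utils::write.table(el[, c("from", "to", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    g <- network_igraph(net)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

# weighted igraph over |w| with sign kept as an attribute
network_igraph <- function(net, distance = FALSE) {
  el <- tidy(net)
  g <- igraph::graph_from_data_frame(
    el[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = net$labels,
                          community = unname(net$communities[net$labels]))
  )
  igraph::E(g)$sign_weight <- el$weight
  igraph::E(g)$weight <- if (distance) 1 / abs(el$weight) else abs(el$weight)
  g
}
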