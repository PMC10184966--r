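#' Specify a ground-truth symptom network
#'
#' Defines a sparse partial-correlation structure over two symptom communities
#' (seven anxiety items, seven sleep items by default) with a small set of
#' planted cross-community "bridge" edges. The default bridge set mirrors the
#' strongest cross-community connections reported for outpatient anxiety/sleep
#' networks: GAD.1-PSQI.7 (0.16), GAD.1-PSQI.1 (0.08), GAD.6-PSQI.7 (0.07) and
#' a weak negative GAD.6-PSQI.6 (-0.07).
#'
#' @param p Number of nodes (default 14; must equal `length(labels)`).
#' @param labels Node labels; default `GAD.1..GAD.7`, `PSQI.1..PSQI.7`.
#' @param communities Community per node; default 7 anxiety + 7 sleep.
#' @param within_density Probability that a within-community pair beyond the
#'   backbone chain gets an edge (default 0.3).
#' @param within_range Absolute-weight range for within-community edges
#'   (default `c(0.05, 0.35)`); the backbone chain edges are drawn from the
#'   upper half so every node stays connected.
#' @param anchor_edges Fixed within-community edges planted verbatim; the
#'   default mirrors the strongest within-community associations seen in
#'   outpatient anxiety/sleep networks (sleep duration-efficiency 0.60,
#'   nervousness-uncontrollable worry 0.45, sleep quality-latency 0.45, ...).
#' @param bridge_edges Data frame with columns `from`, `to`, `weight` giving
#'   planted cross-community partial correlations.
#' @param prob_negative Probability that a random within-community edge is
#'   negative (default 0.05; observed symptom networks are positive-dominant).
#' @param backbone Keep the within-community chain that guarantees
#'   connectedness (default `TRUE`; disable for fully empty or purely planted
#'   structures).
#'
#' @return A list of class `"network_spec"`.
#' @export
network_spec <- function(p = 14,
                         labels = symptom_nodes()$label,
                         communities = symptom_nodes()$community,
                         within_density = 0.3,
                         within_range = c(0.05, 0.35),
                         anchor_edges = default_anchor_edges(),
                         bridge_edges = default_bridge_edges(),
                         prob_negative = 0.05,
                         backbone = TRUE) {
  stopifnot(p == length(labels), p == length(communities),
            length(within_range) == 2L, within_range[1] >= 0,
            within_range[2] < 1, within_density >= 0, within_density <= 1)
  for (ed in list(bridge_edges, anchor_edges)) {
    if (!is.null(ed) && nrow(ed) > 0) {
      stopifnot(all(c("from", "to", "weight") %in% names(ed)))
      bad <- setdiff(c(ed$from, ed$to), labels)
      if (length(bad) > 0) stop("unknown edge node(s): ",
                                paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(p = p, labels = labels, communities = communities,
                 within_density = within_density, within_range = within_range,
                 anchor_edges = anchor_edges, bridge_edges = bridge_edges,
                 prob_negative = prob_negative, backbone = backbone),
            class = "network_spec")
}

#' @rdname network_spec
#' @export
default_anchor_edges <- function() {
  tibble::tibble(
    from = c("PSQI.3", "PSQI.1", "PSQI.2", "GAD.1", "GAD.4", "GAD.2"),
    to = c("PSQI.4", "PSQI.2", "PSQI.4", "GAD.2", "GAD.5", "GAD.3"),
    weight = c(0.60, 0.45, 0.35, 0.45, 0.40, 0.40)
  )
}

#' @rdname network_spec
#' @export
default_bridge_edges <- function() {
  tibble::tibble(
    from = c("GAD.1", "GAD.1", "GAD.6", "GAD.6"),
    to = c("PSQI.7", "PSQI.1", "PSQI.7", "PSQI.6"),
    weight = c(0.16, 0.08, 0.07, -0.07)
  )
}

#' Build a ground-truth network from a specification
#'
#' Draws the within-community edges at random under the spec, plants the bridge
#' edges, and converts the partial-correlation matrix to the implied latent
#' correlation matrix via the precision matrix. If the implied precision matrix
#' is not positive definite, all off-diagonal entries are shrunk by a factor of
#' 0.95 repeatedly (up to 50 times) until it is; the applied shrink factor is
#' recorded.
#'
#' @param spec A `network_spec`.
#' @param seed Integer seed for the random within-community structure.
#'
#' @return A list of class `"true_network"` with elements `partial` (p x p
#'   partial correlations, zero diagonal), `sigma` (implied latent correlation
#'   matrix), `precision`, `labels`, `communities`, `shrink` (total shrink
#'   factor applied, 1 if none) and `spec`.
#' @export
build_true_network <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(seed)
  p <- spec$p
  labels <- spec$labels
  P <- matrix(0, p, p, dimnames = list(labels, labels))

  comms <- unique(spec$communities)
  for (cm in comms) {
    idx <- which(spec$communities == cm)
    k <- length(idx)
    if (k < 2) next
    lo <- spec$within_range[1]; hi <- spec$within_range[2]
    mid <- (lo + hi) / 2
    # backbone chain keeps the community connected, weights in the upper half
    if (isTRUE(spec$backbone)) {
      for (t in seq_len(k - 1)) {
        w <- stats::runif(1, mid, hi)
        P[idx[t], idx[t + 1]] <- P[idx[t + 1], idx[t]] <- w
      }
    }
    # extra edges at the requested density
    pairs <- utils::combn(idx, 2)
    for (c in seq_len(ncol(pairs))) {
      i <- pairs[1, c]; j <- pairs[2, c]
      if (isTRUE(spec$backbone) && abs(match(i, idx) - match(j, idx)) == 1L) next
      if (stats::runif(1) < spec$within_density) {
        w <- stats::runif(1, lo, hi)
        if (stats::runif(1) < spec$prob_negative) w <- -w
        P[i, j] <- P[j, i] <- w
      }
    }
  }
  for (be in list(spec$anchor_edges, spec$bridge_edges)) {
    if (is.null(be) || nrow(be) == 0) next
    for (r in seq_len(nrow(be))) {
      i <- match(be$from[r], labels); j <- match(be$to[r], labels)
      P[i, j] <- P[j, i] <- be$weight[r]
    }
  }
  out <- partial_to_network(P, spec$communities)
  out$spec <- spec
  out
}

# convert a partial-correlation matrix (zero diagonal) to a true_network,
# shrinking off-diagonals until the implied precision is positive definite
partial_to_network <- function(P, communities, shrink_factor = 0.95,
                               max_iter = 50) {
  stopifnot(isSymmetric(unname(P)), all(diag(P) == 0), all(abs(P) < 1))
  labels <- rownames(P)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(P)))
  shrink <- 1
  for (it in seq_len(max_iter)) {
    Omega <- -P * shrink
    diag(Omega) <- 1
    ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-8) break
    shrink <- shrink * shrink_factor
    if (it == max_iter) stop("could not reach positive definiteness by shrinkage",
                             call. = FALSE)
  }
  Omega <- -P * shrink
  diag(Omega) <- 1
  Sigma <- solve(Omega)
  Sigma <- stats::cov2cor(Sigma)
  # recompute the precision of the standardized Sigma; its partials equal
  # P*shrink exactly (partial correlations are scale-invariant), so zero the
  # non-edges explicitly to remove numerical fill-in from the two inversions
  K <- solve(Sigma)
  Pshr <- -K / sqrt(diag(K) %o% diag(K))
  diag(Pshr) <- 0
  Pshr[P == 0] <- 0
  dimnames(Pshr) <- dimnames(Sigma) <- dimnames(K) <- list(labels, labels)
  structure(list(partial = Pshr, sigma = Sigma, precision = K,
                 labels = labels, communities = communities, shrink = shrink),
            class = "true_network")
}

#' Default discretization thresholds for the 14 items
#'
#' Thresholds on the latent standard-normal scale chosen so that the implied
#' four-category marginals have means matching typical outpatient item means
#' (anxiety items mostly right-skewed, several sleep components left-skewed).
#' Category probabilities for a target mean `m` on \{0..3\} are taken as
#' Binomial(3, m/3), and thresholds are the normal quantiles of their
#' cumulative sums.
#'
#' @param target_means Numeric vector of target item means on the 0-3 scale,
#'   named by node label. Defaults to outpatient-like values.
#' @return A 3-row matrix of increasing thresholds, one column per item.
#' @export
default_thresholds <- function(target_means = c(
  GAD.1 = 1.35, GAD.2 = 1.03, GAD.3 = 1.12, GAD.4 = 1.03, GAD.5 = 0.77,
  GAD.6 = 1.07, GAD.7 = 0.59, PSQI.1 = 1.98, PSQI.2 = 1.99, PSQI.3 = 1.97,
  PSQI.4 = 1.72, PSQI.5 = 1.31, PSQI.6 = 1.09, PSQI.7 = 2.12)) {
  stopifnot(all(target_means > 0), all(target_means < 3))
  th <- vapply(target_means, function(m) {
    pr <- stats::dbinom(0:3, size = 3, prob = m / 3)
    stats::qnorm(cumsum(pr)[1:3])
  }, numeric(3))
  rownames(th) <- paste0("t", 1:3)
  th
}

#' Sample ordinal item responses from a latent-Gaussian copula
#'
#' Draws `n` latent multivariate-normal vectors with the true network's implied
#' correlation matrix and discretizes each coordinate at its thresholds into
#' scores 0-3. With the default thresholds the marginals resemble outpatient
#' GAD-7/PSQI item distributions.
#'
#' @param truenet A `"true_network"` from [build_true_network()].
#' @param n Sample size.
#' @param thresholds 3 x p matrix of increasing latent thresholds (default
#'   [default_thresholds()]; recycled by label where possible).
#' @param seed Integer seed; identical seed and configuration give identical
#'   output.
#' @param covariates If `TRUE`, append synthetic demographic columns (`sex`,
#'   `age_group`, `education`, `employment`) drawn independently of the items
#'   with outpatient-like frequencies (a small fraction missing).
#'
#' @return A tibble with item columns named `gad1..gad7`/`psqi1..psqi7` when
#'   the canonical labels are used (otherwise the network labels), plus
#'   covariates if requested. Constant columns, if any arise, are recorded in
#'   the `"degenerate"` attribute.
#' @export
sample_ordinal <- function(truenet, n, thresholds = NULL, seed = 1,
                           covariates = FALSE) {
  stopifnot(inherits(truenet, "true_network"), n >= 1)
  p <- length(truenet$labels)
  if (is.null(thresholds)) {
    thresholds <- default_thresholds()
    if (!all(truenet$labels %in% colnames(thresholds))) {
      # non-canonical labels: symmetric default cuts
      thresholds <- matrix(stats::qnorm(c(0.4, 0.7, 0.9)), 3, p,
                           dimnames = list(paste0("t", 1:3), truenet$labels))
    } else {
      thresholds <- thresholds[, truenet$labels, drop = FALSE]
    }
  }
  stopifnot(ncol(thresholds) == p, nrow(thresholds) == 3,
            all(apply(thresholds, 2, function(t) all(diff(t) > 0))))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% chol(truenet$sigma)
  X <- matrix(0L, n, p)
  for (k in seq_len(p)) {
    X[, k] <- as.integer(cut(Z[, k], c(-Inf, thresholds[, k], Inf),
                             labels = FALSE)) - 1L
  }
  nodes <- symptom_nodes()
  cols <- nodes$column[match(truenet$labels, nodes$label)]
  cols <- ifelse(is.na(cols), truenet$labels, cols)
  colnames(X) <- cols
  out <- tibble::as_tibble(X)
  degenerate <- cols[apply(X, 2, function(x) length(unique(x)) == 1L)]
  if (covariates) out <- dplyr::bind_cols(out, sample_covariates(n))
  attr(out, "degenerate") <- degenerate
  attr(out, "labels") <- truenet$labels
  out
}

# outpatient-like demographic frequencies; independent of the items
sample_covariates <- function(n) {
  samp <- function(levels, prob) sample(levels, n, replace = TRUE, prob = prob)
  tibble::tibble(
    sex = samp(c("male", "female", NA), c(0.357, 0.641, 0.002)),
    age_group = samp(c("younger", "older"), c(0.66, 0.34)),
    education = samp(c("primary", "secondary", "high_school", "university",
                       "postgraduate", "other", NA),
                     c(0.118, 0.185, 0.158, 0.471, 0.037, 0.004, 0.027)),
    employment = samp(c("employed", "unemployed", "other"),
                      c(0.464, 0.236, 0.30))
  )
}

#' Sample two groups with possibly different true networks
#'
#' Draws independent samples for two groups (e.g. for permutation comparison
#' experiments), each from its own ground-truth network, using substreams of a
#' single seed so the pair is reproducible.
#'
#' @param truenet_a,truenet_b `"true_network"` objects sharing the same node
#'   set (pass the same object twice for the null regime).
#' @param n_a,n_b Group sample sizes.
#' @param seed Integer seed.
#' @param ... Passed to [sample_ordinal()] (e.g. `thresholds`).
#'
#' @return A tibble with the item columns and a `group` column (`"A"`/`"B"`).
#' @export
sample_two_groups <- function(truenet_a, truenet_b, n_a, n_b, seed = 1, ...) {
  if (!identical(truenet_a$labels, truenet_b$labels)) {
    stop("the two groups must share the same node set", call. = FALSE)
  }
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2)
  a <- sample_ordinal(truenet_a, n_a, seed = sub[1], ...)
  b <- sample_ordinal(truenet_b, n_b, seed = sub[2], ...)
  dplyr::bind_cols(dplyr::bind_rows(a, b),
                   tibble::tibble(group = rep(c("A", "B"), c(n_a, n_b))))
}

#' Modify one edge of a true network
#'
#' Convenience for planting a group difference: sets the partial correlation of
#' one node pair and rebuilds the implied correlation matrix.
#'
#' @param truenet A `"true_network"`.
#' @param from,to Node labels of the edge.
#' @param weight New partial-correlation weight.
#' @return A `"true_network"` with the edited edge.
#' @export
set_edge <- function(truenet, from, to, weight) {
  stopifnot(inherits(truenet, "true_network"))
  i <- match(from, truenet$labels); j <- match(to, truenet$labels)
  if (is.na(i) || is.na(j)) stop("unknown node label", call. = FALSE)
  P <- truenet$partial
  P[i, j] <- P[j, i] <- weight
  out <- partial_to_network(P, truenet$communities)
  out$spec <- truenet$spec
  out
}

#' Write a true network as an edge-list TSV
#'
#' @param truenet A `"true_network"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_true_edges <- function(truenet, path) {
  el <- tidy_weight_matrix(truenet$partial, truenet$labels)
  el <- el[el$weight != 0, ]
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# weight matrix -> tibble of upper-triangle pairs
tidy_weight_matrix <- function(W, labels) {
  pl <- pair_labels(labels)
  tibble::tibble(from = pl$from, to = pl$to, weight = upper_tri_vec(W))
}
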