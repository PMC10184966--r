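#' Expected influence of each node
#'
#' One-step expected influence: the signed sum of a node's edge weights,
#' `EI(v) = sum_u w_vu`. Unlike strength (which sums `|w|`), EI keeps negative
#' edges negative, so a node damped by negative connections scores lower. The
#' two-step variant adds each neighbour's own EI weighted by the connecting
#' edge.
#'
#' @param net A `"symptom_network"` or a symmetric weight matrix.
#' @param two_step Add the second-step term (default `FALSE`).
#' @return Named numeric vector of EI values.
#' @export
expected_influence <- function(net, two_step = FALSE) {
  W <- weight_matrix_of(net)
  ei1 <- rowSums(W)
  if (!two_step) return(ei1)
  ei1 + as.numeric(W %*% ei1)
}

weight_matrix_of <- function(net) {
  if (inherits(net, "symptom_network")) return(net$weights)
  if (inherits(net, "true_network")) return(net$partial)
  stopifnot(is.matrix(net), isSymmetric(unname(net)))
  W <- net
  if (is.null(rownames(W))) dimnames(W) <- list(paste0("V", seq_len(nrow(W))),
                                                paste0("V", seq_len(nrow(W))))
  W
}

communities_of <- function(net, communities = NULL) {
  cm <- communities
  if (is.null(cm) && inherits(net, c("symptom_network", "true_network"))) {
    cm <- net$communities
  }
  if (is.null(cm)) return(NULL)
  if (is.null(names(cm))) {
    labels <- rownames(weight_matrix_of(net))
    if (length(cm) != length(labels)) {
      stop("communities must be named or match the node count", call. = FALSE)
    }
    cm <- stats::setNames(cm, labels)
  }
  cm
}

#' Bridge expected influence
#'
#' For a node `v` in community `c(v)`, the bridge EI is the signed sum of its
#' edge weights to nodes *outside* its own community. Together with the
#' within-community EI it partitions the total EI:
#' `bridge_EI(v) + within_EI(v) = EI(v)`.
#'
#' @param net A `"symptom_network"` or weight matrix.
#' @param communities Named community assignment (required for bare matrices;
#'   taken from the network object otherwise). Every node must be assigned.
#' @return Named numeric vector of bridge EI values.
#' @export
bridge_expected_influence <- function(net, communities = NULL) {
  W <- weight_matrix_of(net)
  cm <- communities_of(net, communities)
  labels <- rownames(W)
  if (is.null(cm) || any(is.na(cm[labels]))) {
    stop("every node needs a community assignment for bridge EI", call. = FALSE)
  }
  cm <- cm[labels]
  cross <- outer(cm, cm, `!=`)
  rowSums(W * cross)
}

#' Strength centrality
#'
#' @param net A `"symptom_network"` or weight matrix.
#' @return Named vector of `sum |w|` per node.
#' @export
node_strength <- function(net) {
  rowSums(abs(weight_matrix_of(net)))
}

#' Betweenness and closeness on the weighted network
#'
#' Edge lengths are `1/|w|` (stronger association = shorter path), the standard
#' convention for psychometric networks whose weights may be negative.
#' Betweenness counts shortest paths through a node; closeness is the inverse
#' of the summed distances to all other nodes, or the mean inverse distance
#' (harmonic closeness, finite for disconnected graphs).
#'
#' @param net A `"symptom_network"` or weight matrix.
#' @param harmonic Use harmonic closeness (default `TRUE`; the classic
#'   definition returns `NA` for nodes in disconnected components).
#' @return A tibble `node`, `betweenness`, `closeness`.
#' @export
path_centralities <- function(net, harmonic = TRUE) {
  W <- weight_matrix_of(net)
  labels <- rownames(W)
  p <- nrow(W)
  D <- shortest_path_matrix(W)
  btw <- betweenness_from_weights(W)
  closeness <- vapply(seq_len(p), function(v) {
    d <- D[v, -v]
    if (harmonic) mean(1 / d) else {
      if (any(is.infinite(d))) NA_real_ else 1 / sum(d)
    }
  }, numeric(1))
  tibble::tibble(node = labels, betweenness = unname(btw),
                 closeness = unname(closeness))
}

# all-pairs shortest path distances over lengths 1/|w|, via igraph
shortest_path_matrix <- function(W) {
  p <- nrow(W)
  A <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  # igraph orders vertices as in A
  D
}

betweenness_from_weights <- function(W) {
  A <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  b <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  stats::setNames(as.numeric(b), rownames(W))
}

#' Node predictability
#'
#' Share of each node's variance explained by its network neighbours: the R^2
#' of an ordinary least-squares regression of the node on the nodes it shares a
#' nonzero edge with (a Gaussian nodewise approximation; items are treated as
#' numeric). A node with no neighbours has predictability 0.
#'
#' @param data Data frame of item responses (columns matching the network's
#'   labels or the canonical `gad*`/`psqi*` names).
#' @param net A `"symptom_network"`.
#' @return A tibble `node`, `n_neighbors`, `predictability`, plus the average
#'   in the `"average"` attribute.
#' @export
predictability <- function(data, net) {
  W <- weight_matrix_of(net)
  labels <- rownames(W)
  dat <- pick_items(data, NULL)
  colnames(dat) <- node_labels_for(colnames(dat))
  if (!all(labels %in% colnames(dat))) {
    stop("data is missing network node(s): ",
         paste(setdiff(labels, colnames(dat)), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(dat[, labels, drop = FALSE])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  r2 <- vapply(labels, function(v) {
    nb <- labels[W[v, ] != 0]
    if (length(nb) == 0L) return(0)
    y <- m[, v]
    X <- cbind(1, m[, nb, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(0)
    1 - ssr / sst
  }, numeric(1))
  out <- tibble::tibble(node = labels,
                        n_neighbors = rowSums(W != 0)[labels],
                        predictability = unname(r2))
  attr(out, "average") <- mean(r2)
  out
}

#' Full centrality table
#'
#' Per-node expected influence, bridge expected influence, strength,
#' betweenness, closeness and (when data are supplied) predictability.
#'
#' @param net A `"symptom_network"`.
#' @param data Optional item data for predictability.
#' @param communities Optional named community vector.
#' @param z_score Append z-scored columns (`*_z`) for plotting (default
#'   `FALSE`).
#' @return A tibble of class `"centrality_table"`, one row per node.
#' @export
centrality_table <- function(net, data = NULL, communities = NULL,
                             z_score = FALSE) {
  W <- weight_matrix_of(net)
  labels <- rownames(W)
  cm <- communities_of(net, communities)
  ei <- expected_influence(net)
  out <- tibble::tibble(
    node = labels,
    community = if (is.null(cm)) NA_character_ else unname(cm[labels]),
    ei = unname(ei),
    bridge_ei = if (is.null(cm) || any(is.na(cm[labels]))) NA_real_ else
      unname(bridge_expected_influence(net, cm)),
    strength = unname(node_strength(net))
  )
  pc <- path_centralities(net)
  out <- dplyr::left_join(out, pc, by = "node")
  if (!is.null(data)) {
    pr <- predictability(data, net)
    out <- dplyr::left_join(out, pr[, c("node", "predictability")], by = "node")
  }
  if (z_score) {
    for (col in intersect(c("ei", "bridge_ei", "strength", "betweenness",
                            "closeness"), names(out))) {
      v <- out[[col]]
      out[[paste0(col, "_z")]] <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v)
        else 0
    }
  }
  class(out) <- c("centrality_table", class(out))
  out
}
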