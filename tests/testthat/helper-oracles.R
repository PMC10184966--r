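# Independent oracles and small fixtures used across the suite.

# triangle network: edges (a,b) = 0.2, (a,c) = 0.3, (b,c) = -0.1
triangle_weights <- function() {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 0.2
  W["a", "c"] <- W["c", "a"] <- 0.3
  W["b", "c"] <- W["c", "b"] <- -0.1
  W
}

star_weights <- function(k = 4, w = 0.3) {
  labels <- c("hub", paste0("leaf", seq_len(k)))
  W <- matrix(0, k + 1, k + 1, dimnames = list(labels, labels))
  W[1, -1] <- W[-1, 1] <- w
  W
}

path_weights <- function(w = c(0.4, 0.2)) {
  labels <- c("a", "b", "c")
  W <- matrix(0, 3, 3, dimnames = list(labels, labels))
  W[1, 2] <- W[2, 1] <- w[1]
  W[2, 3] <- W[3, 2] <- w[2]
  W
}

random_weights <- function(p, seed, density = 0.5, wmax = 0.4) {
  set.seed(seed)
  W <- matrix(0, p, p, dimnames = list(paste0("n", 1:p), paste0("n", 1:p)))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (runif(1) < density) {
      W[i, j] <- W[j, i] <- runif(1, 0.05, wmax) * sample(c(-1, 1), 1, prob = c(0.2, 0.8))
    }
  }
  W
}

# exhaustive shortest-path metrics: enumerate every simple path between each
# ordered pair, find the minimum 1/|w| length, count the minimizers, and
# accumulate Brandes-style betweenness; harmonic closeness from the distances
brute_path_metrics <- function(W) {
  p <- nrow(W)
  len <- 1 / abs(W)
  len[W == 0] <- Inf
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1]] <<- path
        return(invisible())
      }
      for (u in seq_len(p)) {
        if (is.finite(len[v, u]) && !(u %in% path)) walk(c(path, u))
      }
    }
    walk(s)
    out
  }
  D <- matrix(Inf, p, p)
  diag(D) <- 0
  btw <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      ps <- paths_between(s, t)
      if (length(ps) == 0) next
      lens <- vapply(ps, function(pa) sum(len[cbind(pa[-length(pa)], pa[-1])]),
                     numeric(1))
      dmin <- min(lens)
      D[s, t] <- D[t, s] <- dmin
      short <- ps[abs(lens - dmin) < 1e-9]
      for (v in seq_len(p)) {
        if (v == s || v == t) next
        through <- sum(vapply(short, function(pa) v %in% pa, logical(1)))
        btw[v] <- btw[v] + through / length(short)
      }
    }
  }
  closeness <- vapply(seq_len(p), function(v) mean(1 / D[v, -v]), numeric(1))
  list(distance = D, betweenness = btw, closeness = closeness)
}

# step-down Holm adjustment written directly from the definition
brute_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# penalized glasso objective at a given precision matrix
glasso_objective <- function(theta, S, lambda) {
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(-Inf)
  determinant(theta, logarithm = TRUE)$modulus[1] - sum(S * theta) -
    lambda * sum(abs(theta[upper.tri(theta)])) * 2
}

# brute-force maximizer of the 3-node penalized objective over symmetric
# matrices (6 free parameters), multi-start Nelder-Mead
brute_glasso_max <- function(S, lambda) {
  obj <- function(par) {
    theta <- matrix(0, 3, 3)
    diag(theta) <- par[1:3]
    theta[1, 2] <- theta[2, 1] <- par[4]
    theta[1, 3] <- theta[3, 1] <- par[5]
    theta[2, 3] <- theta[3, 2] <- par[6]
    -glasso_objective(theta, S, lambda)
  }
  K <- solve(S)
  starts <- list(
    c(diag(K), K[1, 2], K[1, 3], K[2, 3]),
    c(1, 1, 1, 0, 0, 0),
    c(diag(K), 0, 0, 0)
  )
  best <- Inf
  for (s in starts) {
    for (pass in 1:3) {
      o <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 50000, reltol = 1e-15))
      s <- o$par
    }
    if (o$value < best) best <- o$value
  }
  -best
}

# small two-community ground truth for recovery/stability fixtures
toy_truth <- function(seed = 1, p = 6) {
  labels <- paste0(rep(c("A", "S"), each = p / 2), seq_len(p / 2))
  comm <- rep(c("anx", "slp"), each = p / 2)
  network_spec(
    p = p, labels = labels, communities = comm,
    within_density = 0.4, within_range = c(0.15, 0.35),
    anchor_edges = NULL,
    bridge_edges = tibble::tibble(from = "A1", to = paste0("S", p / 2),
                                  weight = 0.2),
    backbone = TRUE
  ) |> build_true_network(seed = seed)
}

# minimal fitted-network object wrapper around a weight matrix
as_net <- function(W, communities = NULL) {
  structure(list(weights = W, labels = rownames(W), communities = communities,
                 lambda = 0, gamma = 0.5, ebic = NA_real_,
                 n_edges = sum(W[upper.tri(W)] != 0), n = NA_integer_,
                 p = nrow(W), cor_method = "supplied"),
            class = "symptom_network")
}
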