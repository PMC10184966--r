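#' Permutation network comparison test (NCT)
#'
#' Tests whether two groups share the same network. Both networks are estimated
#' with identical EBIC-glasso settings; the test statistics are
#' `M = max_(i<j) |w^A_ij - w^B_ij|` (network-structure invariance) and
#' `S = |sum_(i<j)|w^A_ij| - sum_(i<j)|w^B_ij||` (global-strength invariance).
#' Group labels are shuffled over the pooled rows (preserving the original
#' group sizes), both networks re-estimated, and the statistics recomputed for
#' each permutation; the global p-values use the add-one convention
#' `p = (1 + #(perm >= obs)) / (1 + n_perm)`, so they are never exactly zero.
#' Per-edge differences are tested against their own permutation distributions
#' (plain proportion, as in the reference permutation test, so a large
#' difference can reach p = 0) and Holm-adjusted across all node pairs.
#'
#' @param data_a,data_b Data frames with the same item columns (one group
#'   each), each with at least 50 rows.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param edge_family `"all"` (default): Holm correction over all p(p-1)/2
#'   pairs; `"observed"`: only pairs with a nonzero edge in either observed
#'   network.
#' @param cor_method Correlation method used for every estimation (default
#'   `"pearson"`, whose permutation loop runs in compiled code; the repeated
#'   re-estimation makes this the practical choice, and `"spearman"` or
#'   `"polychoric"` can be requested explicitly).
#' @param items Optional item columns.
#' @param gamma,n_lambda,lambda_min_ratio,tol,maxit Estimation settings shared
#'   by every (re-)estimation, as in [ebic_glasso()].
#'
#' @return An object of class `"nct_result"`: `m_stat`, `s_stat`, `p_m`, `p_s`,
#'   `edge_tests` (tibble: `from`, `to`, `diff`, `p_raw`, `p_holm`),
#'   `network_a`, `network_b`, `n_perm`, `seed`.
#' @export
nct <- function(data_a, data_b, n_perm = 1000, seed = 1,
                edge_family = c("all", "observed"),
                cor_method = "pearson", items = NULL, gamma = 0.5,
                n_lambda = 100, lambda_min_ratio = 0.01, tol = 1e-4,
                maxit = 200) {
  edge_family <- match.arg(edge_family)
  a <- as.matrix(pick_items(data_a, items))
  b <- as.matrix(pick_items(data_b, items))
  if (!identical(colnames(a), colnames(b))) {
    stop("the two groups must have identical item columns", call. = FALSE)
  }
  a <- a[stats::complete.cases(a), , drop = FALSE]
  b <- b[stats::complete.cases(b), , drop = FALSE]
  n_a <- nrow(a); n_b <- nrow(b)
  if (n_a < 50 || n_b < 50) {
    stop("each group needs at least 50 complete rows for a meaningful comparison",
         call. = FALSE)
  }
  labels <- node_labels_for(colnames(a))
  comm <- communities_for(colnames(a))
  est <- list(gamma = gamma, n_lambda = n_lambda,
              lambda_min_ratio = lambda_min_ratio, tol = tol, maxit = maxit)
  fit_net <- function(m) do.call(fast_network, c(
    list(m, cor_method = cor_method, labels = labels, communities = comm), est))
  fit_a <- do.call(ebic_glasso, c(list(quick_cor(a, cor_method), n = n_a), est))
  fit_b <- do.call(ebic_glasso, c(list(quick_cor(b, cor_method), n = n_b), est))
  wa <- upper_tri_vec(fit_a$weights)
  wb <- upper_tri_vec(fit_b$weights)
  obs_diff <- abs(wa - wb)
  m_obs <- max(obs_diff)
  s_obs <- abs(sum(abs(wa)) - sum(abs(wb)))

  pooled <- rbind(a, b)
  n <- n_a + n_b
  set.seed(seed)
  failures <- 0L
  max_failures <- 0.05 * n_perm + 5
  if (cor_method == "pearson") {
    # compiled permutation loop; failed permutations (no penalty converged,
    # essentially never with Pearson input) are redrawn
    m_perm <- numeric(0)
    s_perm <- numeric(0)
    edge_ge <- numeric(length(obs_diff))
    remaining <- n_perm
    while (remaining > 0) {
      perm <- matrix(0L, remaining, n_a)
      for (r in seq_len(remaining)) perm[r, ] <- sample.int(n, n_a)
      res <- nct_perm_cpp(pooled, perm, obs_diff, gamma, n_lambda,
                          lambda_min_ratio, tol = tol, maxit = maxit)
      keep <- res$ok == 1
      m_perm <- c(m_perm, res$m_perm[keep])
      s_perm <- c(s_perm, res$s_perm[keep])
      edge_ge <- edge_ge + res$edge_ge
      failures <- failures + sum(!keep)
      if (failures > max_failures) {
        stop("NCT aborted: too many permutation estimation failures (",
             failures, ")", call. = FALSE)
      }
      remaining <- remaining - sum(keep)
    }
  } else {
    m_perm <- numeric(n_perm)
    s_perm <- numeric(n_perm)
    edge_ge <- numeric(length(obs_diff))
    done <- 0L
    while (done < n_perm) {
      idx <- sample.int(n, n_a)
      fits <- tryCatch(list(
        fit_net(pooled[idx, , drop = FALSE]),
        fit_net(pooled[-idx, , drop = FALSE])
      ), error = function(e) NULL)
      if (is.null(fits)) {
        failures <- failures + 1L
        if (failures > max_failures) {
          stop("NCT aborted: too many permutation estimation failures (",
               failures, ")", call. = FALSE)
        }
        next
      }
      d <- abs(upper_tri_vec(fits[[1]]$weights) - upper_tri_vec(fits[[2]]$weights))
      done <- done + 1L
      m_perm[done] <- max(d)
      s_perm[done] <- abs(sum(abs(upper_tri_vec(fits[[1]]$weights))) -
                            sum(abs(upper_tri_vec(fits[[2]]$weights))))
      edge_ge <- edge_ge + (d >= obs_diff - 1e-12)
    }
  }
  p_m <- (1 + sum(m_perm >= m_obs - 1e-12)) / (1 + n_perm)
  p_s <- (1 + sum(s_perm >= s_obs - 1e-12)) / (1 + n_perm)

  pl <- pair_labels(fit_a$labels)
  # per-edge p-values are the plain permutation proportion (they can reach 0);
  # the add-one guarantee applies to the global M and S tests. With add-one
  # per-edge values, Holm over all p(p-1)/2 pairs could never fall below
  # m/(n_perm + 1) and the edge tests would have no power at practical
  # permutation counts.
  edge_tests <- tibble::tibble(
    from = pl$from, to = pl$to,
    weight_a = wa, weight_b = wb, diff = wa - wb,
    p_raw = edge_ge / n_perm
  )
  if (edge_family == "observed") {
    fam <- wa != 0 | wb != 0
  } else {
    fam <- rep(TRUE, nrow(edge_tests))
  }
  edge_tests$in_family <- fam
  edge_tests$p_holm <- NA_real_
  edge_tests$p_holm[fam] <- stats::p.adjust(edge_tests$p_raw[fam], method = "holm")

  structure(list(
    m_stat = m_obs, s_stat = s_obs, p_m = p_m, p_s = p_s,
    edge_tests = edge_tests, network_a = fit_a, network_b = fit_b,
    m_perm = m_perm, s_perm = s_perm,
    n_a = n_a, n_b = n_b, n_perm = n_perm, n_failures = failures,
    edge_family = edge_family, seed = seed
  ), class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat("Network comparison test (", x$n_perm, " permutations)\n", sep = "")
  cat(sprintf("  structure  M = %.4f, p = %.4f\n", x$m_stat, x$p_m))
  cat(sprintf("  strength   S = %.4f, p = %.4f\n", x$s_stat, x$p_s))
  sig <- sum(x$edge_tests$p_holm < 0.05, na.rm = TRUE)
  cat("  edges with Holm-adjusted p < 0.05:", sig, "\n")
  invisible(x)
}

#' @export
tidy.nct_result <- function(x, ...) x$edge_tests

#' @export
glance.nct_result <- function(x, ...) {
  tibble::tibble(m_stat = x$m_stat, p_m = x$p_m, s_stat = x$s_stat,
                 p_s = x$p_s, n_perm = x$n_perm, n_a = x$n_a, n_b = x$n_b,
                 n_sig_edges = sum(x$edge_tests$p_holm < 0.05, na.rm = TRUE))
}

#' Split respondents into two comparison arms
#'
#' Maps the levels of a grouping variable onto two named arms using an
#' explicit category-to-arm rule; rows whose value is missing or unmapped are
#' excluded (their count is reported in the `"n_dropped"` attribute).
#'
#' @param data Data frame of respondents.
#' @param variable Grouping column name.
#' @param rule Named character vector or list mapping each category to an arm
#'   name, e.g. `c(male = "A", female = "B")`. Exactly two distinct arm names
#'   are required.
#' @return A named list of two tibbles (one per arm), each with at least 50
#'   rows.
#' @export
group_split_arms <- function(data, variable, rule) {
  if (!variable %in% names(data)) {
    stop("grouping variable '", variable, "' not in data", call. = FALSE)
  }
  rule <- unlist(rule)
  arms <- unique(unname(rule))
  if (length(arms) != 2L) stop("rule must map categories onto exactly two arms",
                               call. = FALSE)
  g <- as.character(data[[variable]])
  arm <- unname(rule[g])
  keep <- !is.na(arm)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with missing/unmapped '", variable, "' excluded")
  }
  out <- lapply(arms, function(a) tibble::as_tibble(data[keep & arm == a & !is.na(arm), ,
                                                         drop = FALSE]))
  names(out) <- arms
  sizes <- vapply(out, nrow, integer(1))
  if (any(sizes < 50)) {
    stop("arm '", arms[which.min(sizes)], "' has ", min(sizes),
         " rows (< 50); comparison not recommended", call. = FALSE)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
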