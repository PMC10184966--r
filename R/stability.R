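#' Nonparametric bootstrap for edge-weight accuracy
#'
#' Resamples respondents with replacement, re-estimates the full EBIC-glasso
#' network per replicate, and summarizes each edge's bootstrap distribution
#' (mean and 95% quantile interval). Also returns the bootstrapped
#' difference tests: a pair of edges (or of nodes' expected influence) differs
#' significantly when the bootstrap interval of their difference excludes zero
#' (two-sided alpha 0.05, no multiplicity correction -- the field's
#' convention for these diagnostic plots).
#'
#' @param data Data frame of item responses (complete cases are used for the
#'   resampling; incomplete rows are dropped with a message).
#' @param B Number of bootstrap replicates (default 1000; >= 100 recommended
#'   for stable quantiles).
#' @param seed Integer seed.
#' @param ci_level Quantile interval level (default 0.95).
#' @param items Optional item columns.
#' @param cor_method Correlation method for every estimation (default
#'   `"polychoric"`).
#' @param ... Estimation settings forwarded to the estimator (e.g. `gamma`).
#'
#' @return An object of class `"edge_bootstrap"`: `edges` (tibble: `from`,
#'   `to`, `sample` weight, `boot_mean`, `ci_low`, `ci_high`), `edge_diff` and
#'   `ei_diff` (logical significance matrices), `B`, `n_failed`, `seed`.
#' @export
bootstrap_edges <- function(data, B = 1000, seed = 1, ci_level = 0.95,
                            items = NULL, cor_method = "polychoric", ...) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  m <- complete_item_matrix(data, items)
  full <- ebic_glasso(quick_cor(m, cor_method), n = nrow(m), ...)
  labels <- full$labels
  pl <- pair_labels(labels)
  n_pairs <- length(pl$from)
  n <- nrow(m)

  set.seed(seed)
  boot_w <- matrix(NA_real_, B, n_pairs)
  boot_ei <- matrix(NA_real_, B, length(labels))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(
      fast_network(m[idx, , drop = FALSE], cor_method = cor_method,
                   labels = labels, ...),
      error = function(e) NULL)
    if (is.null(fit)) {
      failed <- failed + 1L
      next
    }
    boot_w[b, ] <- upper_tri_vec(fit$weights)
    boot_ei[b, ] <- expected_influence(fit)
  }
  if (failed > 0.05 * B) {
    stop("bootstrap aborted: ", failed, " of ", B, " replicates failed",
         call. = FALSE)
  }
  keep <- stats::complete.cases(boot_w)
  boot_w <- boot_w[keep, , drop = FALSE]
  boot_ei <- boot_ei[keep, , drop = FALSE]
  alpha <- (1 - ci_level) / 2

  edges <- tibble::tibble(
    from = pl$from, to = pl$to,
    sample = upper_tri_vec(full$weights),
    boot_mean = colMeans(boot_w),
    ci_low = apply(boot_w, 2, stats::quantile, probs = alpha),
    ci_high = apply(boot_w, 2, stats::quantile, probs = 1 - alpha)
  )
  structure(list(
    edges = edges,
    edge_diff = diff_sig_matrix(boot_w, paste(pl$from, pl$to, sep = "--"), alpha),
    ei_diff = diff_sig_matrix(boot_ei, labels, alpha),
    network = full, B = B, n_failed = failed, ci_level = ci_level, seed = seed
  ), class = "edge_bootstrap")
}

# symmetric logical matrix: does the bootstrap CI of (col_i - col_j) exclude 0?
diff_sig_matrix <- function(boot, labels, alpha) {
  k <- ncol(boot)
  sig <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    d <- boot[, i] - boot[, (i + 1):k, drop = FALSE]
    lo <- apply(d, 2, stats::quantile, probs = alpha)
    hi <- apply(d, 2, stats::quantile, probs = 1 - alpha)
    s <- lo > 0 | hi < 0
    sig[i, (i + 1):k] <- s
    sig[(i + 1):k, i] <- s
  }
  sig
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat("Edge-weight bootstrap: B =", x$B, "(", x$n_failed, "failed )\n")
  nz <- x$edges[x$edges$sample != 0, ]
  cat("  ", nrow(nz), "nonzero edges;",
      sum(nz$ci_low > 0 | nz$ci_high < 0), "with CI excluding 0\n")
  invisible(x)
}

#' @export
tidy.edge_bootstrap <- function(x, ...) x$edges

#' Case-dropping bootstrap and correlation-stability coefficient
#'
#' Repeatedly re-estimates the network on subsamples with a growing fraction
#' of respondents dropped, correlating each subsample's centrality with the
#' full-sample centrality. The CS-coefficient of an index is the largest drop
#' proportion at which at least `target` (default 95%) of the correlations stay
#' at or above `threshold` (default 0.7). A CS above 0.5 is conventionally
#' "stable"; the coefficient can never exceed the largest proportion tested.
#'
#' @param data Data frame of item responses.
#' @param indices Centrality indices to track: any of `"ei"`, `"bridge_ei"`,
#'   `"strength"`, `"betweenness"`, `"closeness"`.
#' @param drop_grid Increasing drop proportions (default
#'   `c(0.1, 0.25, 0.5, 0.75)`).
#' @param B Subsamples per drop level (default 250).
#' @param threshold Correlation threshold (default 0.7).
#' @param target Required fraction of subsamples meeting the threshold
#'   (default 0.95).
#' @param cor_use `"pearson"` (default) or `"spearman"` correlation between
#'   subsample and full-sample centralities.
#' @param seed Integer seed.
#' @param items Optional item columns.
#' @param cor_method Correlation method for every estimation (default
#'   `"polychoric"`).
#' @param ... Estimation settings forwarded to the estimator (e.g. `gamma`).
#'
#' @return An object of class `"cs_result"`: `record` (tibble: `index`,
#'   `drop`, `replicate`, `correlation`), `cs` (tibble: `index`,
#'   `cs_coefficient`), plus the call settings.
#' @export
case_drop_cs <- function(data, indices = c("ei", "bridge_ei"),
                         drop_grid = c(0.10, 0.25, 0.50, 0.75),
                         B = 250, threshold = 0.7, target = 0.95,
                         cor_use = c("pearson", "spearman"), seed = 1,
                         items = NULL, cor_method = "polychoric", ...) {
  cor_use <- match.arg(cor_use)
  stopifnot(all(drop_grid > 0), all(drop_grid < 1), !is.unsorted(drop_grid))
  m_items <- complete_item_matrix(data, items)
  n <- nrow(m_items)
  if (floor(n * (1 - max(drop_grid))) < 50) {
    stop("largest drop proportion leaves fewer than 50 rows", call. = FALSE)
  }
  full <- ebic_glasso(quick_cor(m_items, cor_method), n = n, ...)
  full_cent <- centrality_values(full, indices)
  labels <- full$labels
  comm <- full$communities

  set.seed(seed)
  rows <- list()
  for (d in drop_grid) {
    m <- floor(n * (1 - d))
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = FALSE)
      fit <- tryCatch(
        fast_network(m_items[idx, , drop = FALSE], cor_method = cor_method,
                     labels = labels, communities = comm, ...),
        error = function(e) NULL)
      sub_cent <- if (is.null(fit)) NULL else centrality_values(fit, indices)
      for (ix in indices) {
        r <- if (is.null(sub_cent)) 0 else {
          a <- full_cent[[ix]]; s <- sub_cent[[ix]]
          if (stats::sd(a) == 0 || stats::sd(s) == 0) 0
          else stats::cor(a, s, method = cor_use)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          index = ix, drop = d, replicate = b, correlation = r)
      }
    }
  }
  record <- dplyr::bind_rows(rows)
  cs <- cs_from_record(record, threshold, target)
  structure(list(record = record, cs = cs, drop_grid = drop_grid, B = B,
                 threshold = threshold, target = target, seed = seed),
            class = "cs_result")
}

# complete-case item matrix for resampling loops
complete_item_matrix <- function(data, items = NULL) {
  m <- as.matrix(pick_items(data, items))
  keep <- stats::complete.cases(m)
  if (!all(keep)) message(sum(!keep), " incomplete row(s) dropped")
  m[keep, , drop = FALSE]
}

centrality_values <- function(net, indices) {
  out <- list()
  if ("ei" %in% indices) out$ei <- unname(expected_influence(net))
  if ("bridge_ei" %in% indices) {
    out$bridge_ei <- unname(bridge_expected_influence(net))
  }
  if ("strength" %in% indices) out$strength <- unname(node_strength(net))
  if (any(c("betweenness", "closeness") %in% indices)) {
    pc <- path_centralities(net)
    if ("betweenness" %in% indices) out$betweenness <- pc$betweenness
    if ("closeness" %in% indices) out$closeness <- pc$closeness
  }
  out
}

#' Recompute CS coefficients from a resampling record
#'
#' @param record The `record` tibble of a [case_drop_cs()] result.
#' @param threshold Correlation threshold.
#' @param target Required fraction of subsamples at or above the threshold.
#' @return A tibble `index`, `cs_coefficient` (0 when even the smallest drop
#'   fails).
#' @export
cs_from_record <- function(record, threshold = 0.7, target = 0.95) {
  record |>
    dplyr::group_by(.data$index, .data$drop) |>
    dplyr::summarise(ok = mean(.data$correlation >= threshold) >= target,
                     .groups = "drop_last") |>
    dplyr::summarise(
      cs_coefficient = {
        d <- .data$drop[.data$ok]
        # largest drop in the contiguous run of passing levels from the bottom
        run <- cumall_pass(.data$drop, .data$ok)
        if (any(run)) max(.data$drop[run]) else 0
      },
      .groups = "drop")
}

# passing levels from the smallest drop upward (a failed level breaks the run)
cumall_pass <- function(drop, ok) {
  ord <- order(drop)
  run <- cumprod(ok[ord]) == 1
  run[order(ord)]
}

#' @export
print.cs_result <- function(x, ...) {
  cat("Case-dropping bootstrap (B =", x$B, "per level; grid:",
      paste(x$drop_grid, collapse = ", "), ")\n")
  for (i in seq_len(nrow(x$cs))) {
    cat("  CS(", x$cs$index[i], ") = ", x$cs$cs_coefficient[i], "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.cs_result <- function(x, ...) x$cs

#' @export
glance.cs_result <- function(x, ...) {
  tibble::tibble(B = x$B, threshold = x$threshold, target = x$target,
                 max_drop = max(x$drop_grid),
                 cs_ei = x$cs$cs_coefficient[match("ei", x$cs$index)])
}
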