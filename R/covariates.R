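#' Re-estimate the network after controlling for covariates
#'
#' Each item is regressed on the full covariate set by ordinary least squares
#' (categorical covariates expanded to treatment contrasts with the most
#' frequent level as reference; complete cases only) and the network is
#' re-estimated from the residuals. Residuals are continuous, so the adjusted
#' network uses Pearson correlations unless overridden.
#'
#' @param data Data frame with item and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param items Optional item columns.
#' @param cor_method Correlation method for the residual network (default
#'   `"pearson"`).
#' @param ... Further arguments to [ebic_glasso()] (e.g. `gamma`).
#'
#' @return A `"symptom_network"` fitted to the residualized items, with the
#'   covariates used and rows retained recorded in attributes `"covariates"`
#'   and `"n_complete"`.
#' @export
adjust_for_covariates <- function(data, covariates, items = NULL,
                                  cor_method = "pearson", ...) {
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0) stop("covariate(s) not in data: ",
                             paste(miss, collapse = ", "), call. = FALSE)
  dat_items <- pick_items(data, items)
  covs <- data[covariates]

  keep <- stats::complete.cases(dat_items) & stats::complete.cases(covs)
  dat_items <- dat_items[keep, , drop = FALSE]
  covs <- covs[keep, , drop = FALSE]
  if (nrow(dat_items) < 10L) stop("too few complete cases after covariate filtering",
                                  call. = FALSE)

  # drop constant covariates, relevel categoricals to modal reference
  dropped <- character(0)
  for (v in names(covs)) {
    x <- covs[[v]]
    if (length(unique(x)) < 2L) {
      dropped <- c(dropped, v)
      next
    }
    if (!is.numeric(x)) {
      f <- factor(x)
      covs[[v]] <- stats::relevel(f, ref = names(which.max(table(f))))
    }
  }
  if (length(dropped) > 0) {
    warning("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
    covs <- covs[setdiff(names(covs), dropped)]
  }
  if (ncol(covs) == 0L) {
    X <- matrix(1, nrow(dat_items), 1)
  } else {
    X <- stats::model.matrix(~ ., data = covs)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("collinear covariate columns dropped (rank ", qrX$rank, " < ",
            ncol(X), ")")
  }
  resid <- as.data.frame(qr.resid(qrX, as.matrix(dat_items)))
  sds <- vapply(resid, stats::sd, numeric(1))
  if (any(sds < 1e-10)) {
    stop("item(s) fully explained by covariates: ",
         paste(names(resid)[sds < 1e-10], collapse = ", "), call. = FALSE)
  }
  net <- ebic_glasso(resid, cor_method = cor_method, ...)
  attr(net, "covariates") <- setdiff(names(covs), dropped)
  attr(net, "n_complete") <- nrow(resid)
  net
}

#' Compare an adjusted network with the original
#'
#' Quantifies how much covariate adjustment changed the network: the Pearson
#' correlation between the two vectorized upper-triangular edge-weight sets and
#' a two-sided paired t-test of their difference, plus the same pair of
#' statistics over the nodes' expected-influence values (reported because
#' either vector is a defensible basis for the comparison). High `r` and a
#' non-significant `t` indicate the covariates do not materially alter the
#' structure.
#'
#' @param original,adjusted `"symptom_network"` objects on the same node set.
#' @param paired Use a paired t-test (default `TRUE`); `FALSE` gives the
#'   two-sample (Welch) version.
#' @return A tibble of class `"network_agreement"` with one row per comparison
#'   basis (`edges`, `ei`): `r`, `t_stat`, `p_value`, `mean_diff`.
#' @export
compare_adjusted <- function(original, adjusted, paired = TRUE) {
  if (!identical(original$labels, adjusted$labels)) {
    stop("networks have different node sets", call. = FALSE)
  }
  w1 <- upper_tri_vec(original$weights)
  w2 <- upper_tri_vec(adjusted$weights)
  e1 <- expected_influence(original)
  e2 <- expected_influence(adjusted)
  row_for <- function(a, b, basis) {
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
    if (paired && stats::sd(a - b) == 0) {
      # identical vectors: no difference to test
      t_stat <- if (mean(a - b) == 0) 0 else NA_real_
      p_value <- if (mean(a - b) == 0) 1 else NA_real_
    } else {
      tt <- tryCatch(stats::t.test(a, b, paired = paired), error = function(e) NULL)
      t_stat <- if (is.null(tt)) NA_real_ else unname(tt$statistic)
      p_value <- if (is.null(tt)) NA_real_ else tt$p.value
    }
    tibble::tibble(basis = basis, r = r, t_stat = t_stat, p_value = p_value,
                   mean_diff = mean(a - b))
  }
  out <- dplyr::bind_rows(row_for(w1, w2, "edges"), row_for(e1, e2, "ei"))
  class(out) <- c("network_agreement", class(out))
  out
}
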