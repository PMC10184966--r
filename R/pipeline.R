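#' Read respondent item data from CSV/TSV
#'
#' One row per respondent; item columns `gad1..gad7`, `psqi1..psqi7`; optional
#' covariates (`sex`, `age_group`, `education`, `employment`). Blank fields are
#' read as missing.
#'
#' @param path File path; `.tsv`/`.txt` are read tab-separated, anything else
#'   comma-separated.
#' @return A tibble.
#' @export
read_item_data <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                      na.strings = c("", "NA"),
                                      stringsAsFactors = FALSE))
}

#' Rank symptoms by a centrality index
#'
#' @param centrality A [centrality_table()] tibble.
#' @param k Number of symptoms to return (`k = 0` gives an empty table; `k`
#'   larger than the node count returns all).
#' @param by Index column to rank on: `"ei"` (default) or `"bridge_ei"` (any
#'   numeric column works).
#' @return The top-`k` rows, sorted by the index descending with ties broken
#'   alphabetically by node label (a stable, documented tie-break).
#' @export
rank_symptoms <- function(centrality, k = 3, by = "ei") {
  if (nrow(centrality) == 0L) stop("empty centrality table", call. = FALSE)
  if (!by %in% names(centrality)) stop("no column '", by, "'", call. = FALSE)
  ord <- order(-centrality[[by]], centrality$node)
  utils::head(centrality[ord, , drop = FALSE], n = max(0, min(k, nrow(centrality))))
}

#' Run the full symptom-network pipeline
#'
#' Orchestrates scoring and descriptives, network estimation, centrality,
#' and (optionally) covariate adjustment, bootstrap stability and permutation
#' group comparisons, returning a single report object and optionally writing
#' every stage's output to plain-text files (TSV/JSON/GraphML).
#'
#' @param data Data frame or CSV/TSV path. If `NULL`, data are simulated from
#'   `truenet` with `generator_n` respondents (ground-truth mode).
#' @param truenet Optional `"true_network"` used when `data` is `NULL`
#'   (default [build_true_network()] with the pipeline seed).
#' @param generator_n Simulated sample size when `data` is `NULL`.
#' @param seed Integer seed propagated (as substreams) to every stochastic
#'   stage.
#' @param cor_method Correlation method for estimation (default
#'   `"polychoric"`).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param covariates Optional covariate columns; when given, the network is
#'   re-estimated on covariate residuals and compared with the original.
#' @param bootstrap_B Bootstrap replicates for edge accuracy (0 = skip).
#' @param cs_B Subsamples per drop level for the CS coefficient (0 = skip).
#' @param cs_grid Drop grid for the case-dropping bootstrap.
#' @param nct_groups Optional named list of comparisons, each
#'   `list(variable =, rule =)` as in [group_split_arms()]; set `n_perm` via
#'   `nct_perm`.
#' @param nct_perm Permutations per comparison (default 1000).
#' @param top_k Size of the headline symptom rankings (default 3).
#' @param out_dir Optional output directory (created if needed).
#'
#' @return An object of class `"analysis_report"` (a named list): `data_info`,
#'   `descriptives`, `prevalence`, `network`, `centrality`, `top_central`,
#'   `top_bridge`, and when requested `adjusted`, `agreement`, `bootstrap`,
#'   `cs`, `nct`.
#' @export
run_pipeline <- function(data = NULL, truenet = NULL, generator_n = 2000,
                         seed = 1, cor_method = "polychoric", gamma = 0.5,
                         covariates = NULL, bootstrap_B = 0, cs_B = 0,
                         cs_grid = c(0.10, 0.25, 0.50, 0.75),
                         nct_groups = NULL, nct_perm = 1000, top_k = 3,
                         out_dir = NULL) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 5)

  simulated <- is.null(data)
  if (simulated) {
    if (is.null(truenet)) truenet <- build_true_network(seed = sub[1])
    data <- sample_ordinal(truenet, n = generator_n, seed = sub[2],
                           covariates = TRUE)
  } else if (is.character(data)) {
    data <- read_item_data(data)
  }
  data <- tibble::as_tibble(data)

  # validate the configuration before any heavy compute
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(data))
    if (length(miss)) stop("covariate column(s) missing: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.null(nct_groups)) {
    for (gname in names(nct_groups)) {
      v <- nct_groups[[gname]]$variable
      if (is.null(v) || !v %in% names(data)) {
        stop("NCT grouping variable missing from data: ",
             gname, call. = FALSE)
      }
      if (is.null(nct_groups[[gname]]$rule)) {
        stop("NCT comparison '", gname, "' needs a category->arm rule",
             call. = FALSE)
      }
    }
  }

  scored <- data
  has_gad <- all(paste0("gad", 1:7) %in% names(data))
  has_psqi <- all(paste0("psqi", 1:7) %in% names(data))
  prevalence <- NULL
  if (has_gad) scored <- score_gad7(scored)
  if (has_psqi) scored <- score_psqi(scored)
  if (has_gad || has_psqi) {
    rowsets <- list()
    if (has_gad) rowsets$anxiety <- prevalence_ci(sum(scored$anxiety), nrow(scored))
    if (has_psqi) rowsets$clinical_sleep <-
        prevalence_ci(sum(scored$clinical_sleep), nrow(scored))
    if (has_psqi) rowsets$poor_sleep <-
        prevalence_ci(sum(scored$poor_sleep), nrow(scored))
    prevalence <- dplyr::bind_rows(rowsets, .id = "outcome")
  }

  descriptives <- describe_items(data)
  network <- ebic_glasso(data, gamma = gamma, cor_method = cor_method)
  centrality <- centrality_table(network, data = data)
  top_central <- rank_symptoms(centrality, top_k, by = "ei")
  top_bridge <- rank_symptoms(centrality, top_k, by = "bridge_ei")

  report <- list(
    data_info = list(n = nrow(data), simulated = simulated, seed = seed),
    descriptives = descriptives, prevalence = prevalence,
    network = network, centrality = centrality,
    top_central = top_central, top_bridge = top_bridge
  )
  if (simulated) report$truth <- truenet

  if (!is.null(covariates)) {
    adjusted <- adjust_for_covariates(data, covariates, gamma = gamma)
    report$adjusted <- adjusted
    report$agreement <- compare_adjusted(network, adjusted)
  }
  if (bootstrap_B > 0) {
    report$bootstrap <- bootstrap_edges(data, B = bootstrap_B, seed = sub[3],
                                        gamma = gamma, cor_method = cor_method)
  }
  if (cs_B > 0) {
    report$cs <- case_drop_cs(data, drop_grid = cs_grid, B = cs_B,
                              seed = sub[4], gamma = gamma,
                              cor_method = cor_method)
  }
  if (!is.null(nct_groups)) {
    report$nct <- list()
    for (gname in names(nct_groups)) {
      gs <- nct_groups[[gname]]
      arms <- group_split_arms(data, gs$variable, gs$rule)
      report$nct[[gname]] <- nct(arms[[1]], arms[[2]], n_perm = nct_perm,
                                 seed = sub[5], gamma = gamma)
    }
  }
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Symptom network analysis report (n =", x$data_info$n, ")\n")
  if (!is.null(x$prevalence)) {
    for (i in seq_len(nrow(x$prevalence))) {
      r <- x$prevalence[i, ]
      cat(sprintf("  %-14s %d/%d = %.2f%% (95%% CI %.2f-%.2f%%)\n", r$outcome,
                  r$count, r$n, 100 * r$proportion, 100 * r$ci_low,
                  100 * r$ci_high))
    }
  }
  print(x$network)
  cat("  top central (EI):", paste(x$top_central$node, collapse = ", "), "\n")
  cat("  top bridge (bEI):", paste(x$top_bridge$node, collapse = ", "), "\n")
  if (!is.null(x$cs)) print(x$cs)
  if (!is.null(x$nct)) for (g in names(x$nct)) {
    cat("NCT [", g, "]: p(structure) = ", signif(x$nct[[g]]$p_m, 3),
        ", p(strength) = ", signif(x$nct[[g]]$p_s, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Write an analysis report to plain-text files
#'
#' @param report An `"analysis_report"`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(report$descriptives, "descriptives.tsv")
  if (!is.null(report$prevalence)) {
    jsonlite::write_json(report$prevalence, file.path(out_dir, "prevalence.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_network(report$network, file.path(out_dir, "network_edges.tsv"),
                graphml = file.path(out_dir, "network.graphml"))
  tsv(report$network$trace, "ebic_trace.tsv")
  tsv(report$centrality, "centrality.tsv")
  if (!is.null(report$truth)) {
    write_true_edges(report$truth, file.path(out_dir, "true_edges.tsv"))
  }
  if (!is.null(report$agreement)) tsv(report$agreement, "adjusted_agreement.tsv")
  if (!is.null(report$bootstrap)) tsv(report$bootstrap$edges, "edge_bootstrap.tsv")
  if (!is.null(report$cs)) {
    jsonlite::write_json(list(cs = report$cs$cs, threshold = report$cs$threshold,
                              B = report$cs$B, grid = report$cs$drop_grid),
                         file.path(out_dir, "cs_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$nct)) {
    for (g in names(report$nct)) {
      r <- report$nct[[g]]
      jsonlite::write_json(
        list(m_stat = r$m_stat, p_m = r$p_m, s_stat = r$s_stat, p_s = r$p_s,
             n_perm = r$n_perm,
             significant_edges = r$edge_tests[!is.na(r$edge_tests$p_holm) &
                                                r$edge_tests$p_holm < 0.05, ]),
        file.path(out_dir, paste0("nct_", g, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  summary_json <- list(
    n = report$data_info$n, simulated = report$data_info$simulated,
    lambda = report$network$lambda, ebic = report$network$ebic,
    n_edges = report$network$n_edges,
    top_central = report$top_central$node,
    top_bridge = report$top_bridge$node,
    average_predictability = if ("predictability" %in% names(report$centrality))
      mean(report$centrality$predictability) else NULL
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
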