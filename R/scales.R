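#' Score GAD-7 anxiety responses
#'
#' Sums the seven GAD-7 items (each scored 0-3) to a 0-21 total and flags at
#' least mild anxiety at the conventional screening cutoff, total >= 5.
#'
#' @param data A data frame with one row per respondent and the seven item
#'   columns (default `gad1..gad7`), or a bare numeric vector of 7 item scores
#'   for a single respondent.
#' @param items Character vector of the seven item column names.
#' @param cutoff Anxiety screening cutoff on the total score (default 5).
#'
#' @return The input as a tibble with `gad_total` (integer) and `anxiety`
#'   (logical, `gad_total >= cutoff`) appended. A bare vector input returns a
#'   one-row tibble.
#' @examples
#' score_gad7(c(1, 1, 1, 1, 1, 0, 0)) # total 5 -> flagged
#' @export
score_gad7 <- function(data, items = paste0("gad", 1:7), cutoff = 5) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- as.data.frame(as.list(stats::setNames(data[seq_along(items)], items)))
    if (length(items) != 7L) stop("expected 7 items", call. = FALSE)
  }
  mat <- validate_items(data, items, n_items = 7L, scale = "GAD-7")
  total <- as.integer(rowSums(mat))
  dplyr::mutate(tibble::as_tibble(data),
                gad_total = total,
                anxiety = total >= cutoff)
}

#' Score PSQI component data
#'
#' Sums the seven PSQI component scores (each 0-3) to the 0-21 global score and
#' flags poor sleep quality (global > 7) and clinical-level sleep problems
#' (global >= 10), the operationalizations validated for Chinese populations.
#'
#' @param data A data frame with the seven component columns (default
#'   `psqi1..psqi7`), or a numeric vector of 7 component scores.
#' @param items Character vector of the seven component column names.
#' @param clinical_cutoff Global-score cutoff for clinical sleep problems;
#'   the flag is `global >= clinical_cutoff` (default 10).
#' @param poor_cutoff Poor-sleep flag is `global > poor_cutoff` (default 7).
#'
#' @return The input as a tibble with `psqi_global`, `poor_sleep` and
#'   `clinical_sleep` appended.
#' @examples
#' score_psqi(c(2, 2, 2, 2, 1, 0, 1)) # global 10 -> clinical
#' @export
score_psqi <- function(data, items = paste0("psqi", 1:7),
                       clinical_cutoff = 10, poor_cutoff = 7) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- as.data.frame(as.list(stats::setNames(data[seq_along(items)], items)))
  }
  mat <- validate_items(data, items, n_items = 7L, scale = "PSQI")
  global <- as.integer(rowSums(mat))
  dplyr::mutate(tibble::as_tibble(data),
                psqi_global = global,
                poor_sleep = global > poor_cutoff,
                clinical_sleep = global >= clinical_cutoff)
}

# shared 0-3 range validation; errors name the offending item
validate_items <- function(data, items, n_items, scale) {
  if (length(items) != n_items) {
    stop(scale, ": expected ", n_items, " item columns, got ", length(items),
         call. = FALSE)
  }
  mat <- as.matrix(pick_items(data, items))
  storage.mode(mat) <- "double"
  for (k in seq_along(items)) {
    x <- mat[, k]
    bad <- is.na(x) | x < 0 | x > 3 | x != round(x)
    if (any(bad)) {
      stop(scale, " item '", items[k], "': value out of range {0,1,2,3} in row ",
           which(bad)[1], call. = FALSE)
    }
  }
  mat
}

#' Item-level descriptive statistics
#'
#' Computes per-item mean, sample SD, adjusted Fisher-Pearson sample skewness
#' and excess kurtosis (a normal distribution scores 0). Constant items get
#' `NA` skewness/kurtosis rather than an error.
#'
#' @param data Data frame of respondents; item columns selected by `items`
#'   (defaults to the canonical 14 columns present in the data).
#' @param items Optional character vector of item columns.
#'
#' @return A tibble with one row per item: `item`, `label`, `n`, `mean`, `sd`,
#'   `skewness`, `kurtosis`.
#' @export
describe_items <- function(data, items = NULL) {
  dat <- pick_items(data, items)
  purrr::map_dfr(names(dat), function(col) {
    x <- dat[[col]][!is.na(dat[[col]])]
    n <- length(x)
    if (n < 2L) stop("need >= 2 complete observations for item '", col, "'",
                     call. = FALSE)
    m <- mean(x)
    s <- stats::sd(x)
    if (s == 0) {
      sk <- NA_real_; ku <- NA_real_
    } else {
      z <- (x - m)
      m2 <- sum(z^2) / n
      m3 <- sum(z^3) / n
      m4 <- sum(z^4) / n
      g1 <- m3 / m2^1.5
      g2 <- m4 / m2^2 - 3
      # adjusted (sample) versions
      sk <- sqrt(n * (n - 1)) / (n - 2) * g1
      ku <- (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * g2 + 6)
    }
    tibble::tibble(item = col, label = node_labels_for(col), n = n,
                   mean = m, sd = s, skewness = sk, kurtosis = ku)
  })
}

#' Prevalence with a binomial confidence interval
#'
#' @param count Number of positive cases.
#' @param n Sample size.
#' @param level Confidence level (default 0.95).
#' @param method `"wald"` (default; normal approximation
#'   `p +/- z * sqrt(p(1-p)/n)`, clipped to `[0, 1]`) or `"wilson"`.
#'
#' @return A one-row tibble: `count`, `n`, `proportion`, `ci_low`, `ci_high`,
#'   `level`, `method`.
#' @examples
#' prevalence_ci(6534, 11194)
#' @export
prevalence_ci <- function(count, n, level = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (length(n) != 1L || n <= 0) stop("n must be a single positive count", call. = FALSE)
  if (count < 0 || count > n) stop("count must satisfy 0 <= count <= n", call. = FALSE)
  p <- count / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half; hi <- p + half
  } else {
    denom <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- center - half; hi <- center + half
  }
  tibble::tibble(count = as.integer(count), n = as.integer(n), proportion = p,
                 ci_low = max(0, lo), ci_high = min(1, hi),
                 level = level, method = method)
}

#' Cross-tabulate flagged cases by group
#'
#' Splits the flagged (e.g. anxious) respondents across the levels of a
#' grouping variable and reports each level's share of all flagged cases --
#' the column-wise convention of a demographic table whose percentages sum
#' to 100 down each column. Missing group values form an explicit
#' `"Missing"` category.
#'
#' @param data Data frame of respondents.
#' @param flag Column name (string) of a logical flag, e.g. `"anxiety"`.
#' @param group Column name (string) of a categorical grouping variable.
#'
#' @return A tibble with `group` level, `count` (flagged cases in the level),
#'   `total_flagged` (denominator) and `percent` (rounded half-up to 2 dp).
#' @export
group_rates <- function(data, flag, group) {
  f <- data[[flag]]
  g <- as.character(data[[group]])
  if (is.null(f) || is.null(g)) stop("flag/group column not found", call. = FALSE)
  g[is.na(g) | g == ""] <- "Missing"
  total <- sum(f, na.rm = TRUE)
  tab <- tibble::tibble(group = g, flagged = !is.na(f) & f) |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(count = sum(.data$flagged), .groups = "drop")
  tab$total_flagged <- total
  tab$percent <- if (total > 0) round_half_up(100 * tab$count / total, 2) else 0
  tab
}

# round half away from zero (printed-table convention), not banker's rounding
round_half_up <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}
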