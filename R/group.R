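#' One-sample group test of recruitment betas
#'
#' Tests whether the per-subject betas for one (network, condition) cell
#' differ from zero (one-sample t, `df = n - 1`), and summarises the
#' percent-of-sample sign consistency: the share of subjects recruiting the
#' network in the positive direction.
#'
#' @param betas Numeric vector of per-subject betas for one cell.
#' @return One-row tibble: `n`, `mean_beta`, `t`, `df`, `p`,
#'   `percent_positive`, `percent_negative`, `percent_zero`.
#' @export
#' @examples
#' group_ttest(c(1, 2, 3, 4, 5))
group_ttest <- function(betas) {
  betas <- as.numeric(betas)
  n <- length(betas)
  if (n < 2) stop("group_ttest: need at least 2 betas")
  if (stats::sd(betas) == 0)
    stop("group_ttest: degenerate sample (zero variance)")
  tt <- stats::t.test(betas, mu = 0)
  tibble::tibble(
    n = n,
    mean_beta = mean(betas),
    t = unname(tt$statistic),
    df = n - 1L,
    p = tt$p.value,
    percent_positive = 100 * sum(betas > 0) / n,
    percent_negative = 100 * sum(betas < 0) / n,
    percent_zero = 100 * sum(betas == 0) / n
  )
}

#' Network-by-contrast consistency grid
#'
#' Builds the group-level activation grid: one cell per network x
#' condition/contrast holding the group t, its (BH-adjusted) p-value, the
#' mean beta and the percent-of-sample sign consistency — the tabular form
#' of the classic recruitment heatmap, where colour saturates at `|t| >= 5`.
#'
#' @param table Recruitment tibble from [run_cohort()] (columns `network`,
#'   `condition`, `beta`; a `term_type` column is respected by
#'   `term_type_filter`).
#' @param term_type_filter Optional `"condition"` or `"contrast"` to restrict
#'   the grid.
#' @return A `consistency_table` tibble with one row per cell, including
#'   `p_fdr` (Benjamini-Hochberg across cells).
#' @export
consistency_table <- function(table, term_type_filter = NULL) {
  stopifnot(nrow(table) > 0,
            all(c("network", "condition", "beta") %in% names(table)))
  if (!is.null(term_type_filter) && "term_type" %in% names(table))
    table <- dplyr::filter(table, .data$term_type == term_type_filter)
  out <- table |>
    dplyr::group_by(.data$network, .data$condition) |>
    dplyr::reframe(group_ttest(.data$beta)) |>
    dplyr::mutate(p_fdr = stats::p.adjust(.data$p, method = "BH"))
  class(out) <- c("consistency_table", class(out))
  out
}

#' Compare recruitment variability between low and high performers
#'
#' Splits the cohort at the median performance score — ties go to the upper
#' group, i.e. the high group is "greater than or equal to" the split value —
#' reports each group's sample standard deviation of beta, and tests
#' homogeneity of variance. The default test is Brown-Forsythe: a one-way F
#' test on absolute deviations from the group medians, `df = (1, n - 2)`,
#' which is robust to non-normal betas. A plain two-sample variance-ratio F
#' test (`df = (n_low - 1, n_high - 1)`) is available as an option.
#'
#' @param y Numeric vector of betas.
#' @param performance Numeric performance scores, same length.
#' @param split `"median"` (the only built-in rule) or a numeric threshold.
#' @param method `"brown-forsythe"` (default) or `"variance-ratio"`.
#' @return One-row tibble: `split_value`, `n_low`, `n_high`, `sigma_low`,
#'   `sigma_high`, `F`, `df1`, `df2`, `p`, `method`, `degenerate`.
#' @export
variance_split_test <- function(y, performance, split = "median",
                                method = c("brown-forsythe",
                                           "variance-ratio")) {
  method <- match.arg(method)
  stopifnot(length(y) == length(performance), all(is.finite(y)),
            all(is.finite(performance)))
  split_value <- if (identical(split, "median")) {
    stats::median(performance)
  } else if (is.numeric(split)) split else
    stop("variance_split_test: unknown split rule")
  high <- performance >= split_value
  if (sum(high) < 2 || sum(!high) < 2)
    stop("variance_split_test: a group has fewer than 2 members after split")
  y_low <- y[!high]; y_high <- y[high]
  sigma_low <- stats::sd(y_low); sigma_high <- stats::sd(y_high)
  degenerate <- sigma_low == 0 || sigma_high == 0

  if (degenerate) {
    Fv <- NA_real_; df2 <- length(y) - 2L; df1 <- 1L; p <- NA_real_
    if (method == "variance-ratio") { df1 <- length(y_low) - 1L
      df2 <- length(y_high) - 1L }
    warning("variance_split_test: zero variance in a group; test degenerate")
  } else if (method == "brown-forsythe") {
    # one-way F on absolute deviations from group medians
    z_low <- abs(y_low - stats::median(y_low))
    z_high <- abs(y_high - stats::median(y_high))
    z <- c(z_low, z_high)
    g <- rep(c(1, 2), c(length(z_low), length(z_high)))
    zbar <- mean(z)
    ssb <- length(z_low) * (mean(z_low) - zbar)^2 +
      length(z_high) * (mean(z_high) - zbar)^2
    ssw <- sum((z_low - mean(z_low))^2) + sum((z_high - mean(z_high))^2)
    df1 <- 1L; df2 <- length(z) - 2L
    Fv <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  } else {
    df1 <- length(y_low) - 1L; df2 <- length(y_high) - 1L
    Fv <- stats::var(y_low) / stats::var(y_high)
    p <- 2 * min(stats::pf(Fv, df1, df2),
                 stats::pf(Fv, df1, df2, lower.tail = FALSE))
  }

  tibble::tibble(split_value = split_value,
                 n_low = length(y_low), n_high = length(y_high),
                 sigma_low = sigma_low, sigma_high = sigma_high,
                 F = Fv, df1 = df1, df2 = df2, p = p,
                 method = method, degenerate = degenerate)
}
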