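#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GLM result
#'
#' @param x A `glm_result` from [fit_glm()].
#' @param ... Unused.
#' @return Tibble with one row per task condition and contrast: `term`,
#'   `term_type`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy glm_result
#' @export
tidy.glm_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$task, term_type = "condition"),
    dplyr::mutate(x$contrasts, term_type = "contrast")
  ) |>
    dplyr::transmute(term = .data$term, term_type = .data$term_type,
                     estimate = .data$beta, std.error = .data$se,
                     statistic = .data$t, p.value = .data$p)
}

#' @rdname tidy.glm_result
#' @method glance glm_result
#' @export
glance.glm_result <- function(x, ...) {
  tibble::tibble(df.residual = x$df, sigma2 = x$sigma2,
                 n_task = nrow(x$task), n_contrasts = nrow(x$contrasts))
}

#' Tidy a Huber robust fit
#'
#' @param x A `huber_fit` from [robust_fit()].
#' @param ... Unused.
#' @return Coefficient tibble in broom column convention.
#' @method tidy huber_fit
#' @export
tidy.huber_fit <- function(x, ...) {
  dplyr::transmute(x$coefficients, term = .data$term,
                   estimate = .data$estimate, std.error = .data$se,
                   statistic = .data$t, p.value = .data$p)
}

#' @rdname tidy.huber_fit
#' @method glance huber_fit
#' @export
glance.huber_fit <- function(x, ...) {
  tibble::tibble(df.residual = x$df, scale = x$scale, tuning = x$tuning,
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy a stepwise selection fit
#'
#' @param x A `stepwise_fit` from [stepwise_select()].
#' @param ... Unused.
#' @return Final-model coefficient tibble in broom column convention.
#' @method tidy stepwise_fit
#' @export
tidy.stepwise_fit <- function(x, ...) {
  dplyr::transmute(x$fit, term = .data$term, estimate = .data$estimate,
                   std.error = .data$se, statistic = .data$t,
                   p.value = .data$p)
}

#' @rdname tidy.stepwise_fit
#' @method glance stepwise_fit
#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 selected = paste(x$selected, collapse = ","),
                 p_enter = x$p_enter, p_remove = x$p_remove,
                 n_steps = nrow(x$trace))
}

#' Tidy a two-stage performance regression
#'
#' @param x A `performance_fit` from [performance_regression()].
#' @param ... Unused.
#' @return Robust-stage coefficient tibble with the network and term
#'   attached.
#' @method tidy performance_fit
#' @export
tidy.performance_fit <- function(x, ...) {
  dplyr::mutate(tidy(x$robust), network = x$network,
                condition = x$condition, .before = 1)
}

#' @rdname tidy.performance_fit
#' @method glance performance_fit
#' @export
glance.performance_fit <- function(x, ...) {
  tibble::tibble(network = x$network, condition = x$condition, n = x$n,
                 n_selected = length(x$selected),
                 selected = paste(x$selected, collapse = ","),
                 no_predictors = x$no_predictors,
                 scale = x$robust$scale, iterations = x$robust$iterations)
}
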