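# OLS coefficient table via QR: term, estimate, se, t, p. X includes the
# intercept column already.
ols_coef_table <- function(y, X) {
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) return(NULL)   # collinear candidate set
  beta <- qr.coef(qr_X, y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  XtXinv <- chol2inv(qr.R(qr_X))
  se <- sqrt(sigma2 * diag(XtXinv))
  t <- beta / se
  tibble::tibble(term = colnames(X), estimate = unname(beta),
                 se = unname(se), t = unname(t),
                 p = 2 * stats::pt(abs(unname(t)), df, lower.tail = FALSE),
                 df = df)
}

#' Stepwise covariate selection by coefficient p-values
#'
#' Forward selection with backward elimination: at each step the candidate
#' whose coefficient p-value (two-sided t-test in the model holding the
#' current selection plus intercept) is smallest and below `p_enter` is
#' added; after every addition, any selected covariate whose p-value has
#' risen above `p_remove` is removed (largest first). The procedure stops at
#' a fixpoint. Ties break by candidate declaration order. Constant candidate
#' columns are dropped with a warning.
#'
#' @param y Numeric response (per-subject betas).
#' @param candidates Data frame of candidate covariates; numeric columns, or
#'   2-level categoricals which are recoded to 0/1 indicators.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must exceed `p_enter`.
#' @return A `stepwise_fit`: `selected` (character), `fit` (coefficient
#'   tibble of the final model incl. intercept), `trace` (tibble of steps),
#'   `p_enter`, `p_remove`.
#' @export
stepwise_select <- function(y, candidates, p_enter = 0.05, p_remove = 0.10) {
  stopifnot(p_enter < p_remove, p_enter > 0, p_remove < 1)
  y <- as.numeric(y)
  C <- encode_covariates(candidates)
  keep <- vapply(C, function(v) stats::sd(v) > 0, logical(1))
  if (any(!keep)) {
    warning("stepwise_select: dropping constant candidate(s): ",
            paste(names(C)[!keep], collapse = ", "))
    C <- C[keep]
  }
  if (length(y) <= ncol(C) + 1)
    warning("stepwise_select: fewer observations than candidates + 2; ",
            "selection will be unstable")
  Cm <- as.matrix(C)
  n <- length(y)
  stopifnot(nrow(Cm) == n)
  intercept <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

  selected <- character(0)
  trace <- list()
  repeat {
    pool <- setdiff(colnames(Cm), selected)
    if (!length(pool)) break
    entry_p <- vapply(pool, function(cand) {
      X <- cbind(intercept, Cm[, c(selected, cand), drop = FALSE])
      tab <- ols_coef_table(y, X)
      if (is.null(tab)) return(Inf)
      tab$p[tab$term == cand]
    }, numeric(1))
    entry_p[is.na(entry_p)] <- Inf      # degenerate fits never enter
    best <- which.min(entry_p)          # first minimum = declaration order
    if (!is.finite(entry_p[best]) || entry_p[best] >= p_enter) break
    selected <- c(selected, pool[best])
    trace[[length(trace) + 1]] <- tibble::tibble(
      action = "enter", term = pool[best], p = entry_p[best])
    # backward elimination at the new fixpoint
    repeat {
      X <- cbind(intercept, Cm[, selected, drop = FALSE])
      tab <- ols_coef_table(y, X)
      ps <- tab$p[match(selected, tab$term)]
      ps[is.na(ps)] <- 0                # a perfectly explaining term stays
      worst <- which.max(ps)
      if (!length(ps) || ps[worst] <= p_remove) break
      trace[[length(trace) + 1]] <- tibble::tibble(
        action = "remove", term = selected[worst], p = ps[worst])
      selected <- selected[-worst]
      if (!length(selected)) break
    }
  }

  X <- cbind(intercept, Cm[, selected, drop = FALSE])
  structure(list(selected = selected,
                 fit = ols_coef_table(y, X),
                 trace = if (length(trace)) dplyr::bind_rows(trace)
                         else tibble::tibble(action = character(),
                                             term = character(),
                                             p = numeric()),
                 p_enter = p_enter, p_remove = p_remove,
                 y = y, X = X),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> selected: %s (entry p < %g, removal p > %g)\n",
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)", x$p_enter, x$p_remove))
  print(x$fit)
  invisible(x)
}

#' Huber robust linear regression
#'
#' M-estimation with the Huber weight function by iteratively reweighted
#' least squares. Residuals within `tuning` robust-scale units keep weight
#' 1; larger residuals are down-weighted by `tuning / |r/s|`. The scale `s`
#' is re-estimated each iteration as `median(|r|) / 0.6745` (the MAD rule
#' for residuals centred at zero). The default tuning constant 1.345 gives
#' 95% efficiency under Gaussian errors. Standard errors come from the
#' asymptotic covariance of the final weighted solve,
#' `sigma2_w * (X'WX)^-1` with `sigma2_w = sum(w r^2) / (n - p)`.
#'
#' @param y Numeric response.
#' @param X Covariate matrix or data frame (without intercept; one is added).
#' @param tuning Huber tuning constant (default 1.345).
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Iteration cap; exceeding it is an error carrying the
#'   iteration trace.
#' @return A `huber_fit`: `coefficients` tibble (term, estimate, se, t, p),
#'   `df`, `scale`, `iterations`, `weights`, `converged`.
#' @export
robust_fit <- function(y, X, tuning = 1.345, tol = 1e-8, max_iter = 200) {
  y <- as.numeric(y)
  if (is.null(X) || (!is.null(ncol(X)) && ncol(X) == 0) || length(X) == 0) {
    X1 <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(encode_covariates(as.data.frame(X)))
    stopifnot(nrow(X) == length(y))
    X1 <- cbind("(Intercept)" = 1, X)
  }
  n <- length(y); p <- ncol(X1)
  if (n <= p) stop("robust_fit: need more observations than coefficients")
  if (qr(X1)$rank < p) stop("robust_fit: covariate matrix is rank deficient")

  beta <- qr.coef(qr(X1), y)            # OLS start
  w <- rep(1, n)
  s <- NA_real_
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- as.vector(y - X1 %*% beta)
    s <- stats::median(abs(r)) / 0.6745
    if (s < 1e-12) { w <- rep(1, n); converged <- TRUE; break }
    u <- abs(r / s)
    w <- ifelse(u <= tuning, 1, tuning / u)
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(X1 * sw), y * sw)
    delta <- max(abs(beta_new - beta))
    trace <- c(trace, delta)
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("robust_fit: no convergence in ", max_iter,
         " iterations; last coefficient changes: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = ", "))

  r <- as.vector(y - X1 %*% beta)
  df <- n - p
  sigma2_w <- sum(w * r^2) / df
  XtWXinv <- chol2inv(chol(crossprod(X1 * sqrt(w))))
  se <- sqrt(sigma2_w * diag(XtWXinv))
  t <- beta / se
  structure(list(
    coefficients = tibble::tibble(
      term = colnames(X1), estimate = unname(beta), se = unname(se),
      t = unname(t),
      p = 2 * stats::pt(abs(unname(t)), df, lower.tail = FALSE)),
    df = df, scale = s, tuning = tuning, iterations = length(trace),
    weights = w, residuals = r, converged = converged,
    method = "huber"),
    class = "huber_fit")
}

#' @export
print.huber_fit <- function(x, ...) {
  cat(sprintf("<huber_fit> tuning %.4g, scale %.4g, %d iteration(s), df = %d\n",
              x$tuning, x$scale, x$iterations, x$df))
  print(x$coefficients)
  invisible(x)
}

# recode a covariate frame to numeric columns: 2-level categoricals become
# 0/1 indicators named <col>_<level>; numerics pass through
encode_covariates <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  out <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      out[[nm]] <- as.numeric(v)
    } else {
      v <- as.factor(v)
      lv <- levels(v)
      if (length(lv) == 1) {
        out[[nm]] <- rep(0, length(v))   # constant; dropped by callers
      } else if (length(lv) == 2) {
        out[[paste0(nm, "_", lv[2])]] <- as.numeric(v == lv[2])
      } else {
        for (l in lv[-1]) out[[paste0(nm, "_", l)]] <- as.numeric(v == l)
      }
    }
  }
  tibble::as_tibble(out)
}

#' Two-stage performance regression for one network
#'
#' The brain-behaviour analysis: per-subject recruitment betas for one
#' network (and one condition/contrast) are first screened by
#' [stepwise_select()] over the full covariate pool — performance, age, sex,
#' education, handedness, head coil, session order and mean trial duration —
#' then the selected covariates are refit with [robust_fit()] (Huber,
#' tuning 1.345) so outlying subjects cannot dominate the slope. If nothing
#' is selected, an intercept-only robust fit flagged `no_predictors` is
#' returned.
#'
#' @param table Recruitment tibble (needs `subject_id`, `network`,
#'   `condition`, `beta`).
#' @param subjects Covariate tibble with `subject_id`, `performance` and the
#'   nuisance columns above; subjects with missing covariates are dropped
#'   with a warning.
#' @param network Network label to analyse.
#' @param condition Condition/contrast label; may be omitted when the table
#'   holds a single term for the network.
#' @param force_in Covariate names always carried into the robust stage
#'   (e.g. `"mean_trial_duration"`), regardless of selection.
#' @param p_enter,p_remove Stepwise thresholds (defaults 0.05 / 0.10).
#' @param tuning Huber tuning constant (default 1.345).
#' @return A `performance_fit`: the `huber_fit` plus `stepwise`
#'   (the [stepwise_select()] object), `network`, `condition`, `n`,
#'   `no_predictors`.
#' @export
performance_regression <- function(table, subjects, network,
                                   condition = NULL, force_in = NULL,
                                   p_enter = 0.05, p_remove = 0.10,
                                   tuning = 1.345) {
  stopifnot(network %in% table$network)
  rows <- dplyr::filter(table, .data$network == !!network)
  if (is.null(condition)) {
    terms <- unique(rows$condition)
    if (length(terms) > 1)
      stop("performance_regression: multiple terms for ", network,
           " (", paste(terms, collapse = ", "), "); pass `condition`")
    condition <- terms
  }
  rows <- dplyr::filter(rows, .data$condition == !!condition)
  if (!nrow(rows))
    stop("performance_regression: no rows for ", network, " / ", condition)

  pool_cols <- c("performance", "age", "sex", "education", "handedness",
                 "coil", "session_order", "mean_trial_duration")
  missing_cols <- setdiff(c("subject_id", "performance"), names(subjects))
  if (length(missing_cols))
    stop("performance_regression: covariate table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  pool_cols <- intersect(pool_cols, names(subjects))

  dat <- dplyr::inner_join(rows["subject_id"] |> dplyr::mutate(beta = rows$beta),
                           subjects[c("subject_id", pool_cols)],
                           by = "subject_id")
  complete <- stats::complete.cases(dat)
  if (any(!complete)) {
    warning("performance_regression: excluding ", sum(!complete),
            " subject(s) with missing covariates: ",
            paste(dat$subject_id[!complete], collapse = ", "))
    dat <- dat[complete, ]
  }
  if (nrow(dat) < 10)
    warning("performance_regression: fewer than 10 complete subjects (",
            nrow(dat), ")")

  sw <- stepwise_select(dat$beta, dat[pool_cols],
                        p_enter = p_enter, p_remove = p_remove)
  C <- encode_covariates(dat[pool_cols])
  force_enc <- if (length(force_in))
    names(C)[vapply(names(C), function(nm)
      any(startsWith(nm, force_in)), logical(1))] else character(0)
  final_terms <- union(sw$selected, force_enc)
  no_predictors <- length(final_terms) == 0

  rf <- robust_fit(dat$beta,
                   if (no_predictors) NULL
                   else C[final_terms],
                   tuning = tuning)
  structure(list(robust = rf, stepwise = sw, network = network,
                 condition = condition, n = nrow(dat),
                 selected = final_terms, no_predictors = no_predictors),
            class = "performance_fit")
}

#' @export
print.performance_fit <- function(x, ...) {
  cat(sprintf("<performance_fit> %s / %s, n = %d%s\n", x$network,
              x$condition, x$n,
              if (x$no_predictors) " [no predictors]" else ""))
  cat("stepwise selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  print(x$robust$coefficients)
  invisible(x)
}

#' Performance regression across all networks
#'
#' Runs [performance_regression()] for every network in the table and
#' summarises the performance coefficient per network, with
#' Benjamini-Hochberg adjustment across networks.
#'
#' @inheritParams performance_regression
#' @param ... Passed to [performance_regression()].
#' @return Tibble: one row per network with `selected`, `performance_beta`,
#'   `performance_t`, `performance_p`, `p_fdr` (NA where performance was not
#'   selected).
#' @export
performance_screen <- function(table, subjects, condition = NULL, ...) {
  nets <- unique(table$network)
  rows <- purrr::map_dfr(nets, function(nw) {
    fit <- performance_regression(table, subjects, nw,
                                  condition = condition, ...)
    cf <- fit$robust$coefficients
    perf <- cf[cf$term == "performance", ]
    tibble::tibble(
      network = nw, n = fit$n,
      selected = paste(fit$selected, collapse = ","),
      performance_selected = "performance" %in% fit$selected,
      performance_beta = if (nrow(perf)) perf$estimate else NA_real_,
      performance_t = if (nrow(perf)) perf$t else NA_real_,
      performance_p = if (nrow(perf)) perf$p else NA_real_)
  })
  dplyr::mutate(rows, p_fdr = stats::p.adjust(.data$performance_p,
                                              method = "BH"))
}
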