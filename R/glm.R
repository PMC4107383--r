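#' Fit a task GLM to a component timecourse
#'
#' Ordinary least squares of the timecourse on the full design matrix;
#' t-scores use the residual variance with `df = n_frames - rank(design)`.
#' Contrast estimates are the corresponding weighted sums of task betas with
#' their own standard errors. No autocorrelation correction is applied.
#'
#' @param tc A `component_timecourse` (from [project_map()]) or a bare
#'   numeric vector of the same length as the design.
#' @param dm A `design_matrix` from [build_design()].
#' @return A `glm_result`: tibbles `task` (term, beta, se, t, p) and
#'   `contrasts`, plus `df`, `sigma2` and the full coefficient vector.
#' @export
fit_glm <- function(tc, dm) {
  stopifnot(inherits(dm, "design_matrix"))
  y <- if (inherits(tc, "component_timecourse")) tc$values else as.numeric(tc)
  X <- dm$X
  if (length(y) != nrow(X))
    stop("fit_glm: timecourse has ", length(y), " frames, design has ",
         nrow(X))
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) stop("fit_glm: design matrix is rank deficient")
  beta <- qr.coef(qr_X, y)
  resid <- y - X %*% beta
  df <- length(y) - qr_X$rank
  sigma2 <- sum(resid^2) / df
  XtXinv <- chol2inv(qr.R(qr_X))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  se_all <- sqrt(sigma2 * diag(XtXinv))

  tcols <- dm$task_columns
  task <- tibble::tibble(
    term = tcols,
    beta = unname(beta[tcols]),
    se = unname(se_all[tcols]),
    t = unname(beta[tcols] / se_all[tcols]),
    p = 2 * stats::pt(abs(unname(beta[tcols] / se_all[tcols])), df,
                      lower.tail = FALSE)
  )

  contrasts <- purrr::imap_dfr(dm$contrasts, function(w, nm) {
    full_w <- stats::setNames(numeric(ncol(X)), colnames(X))
    full_w[names(w)] <- w
    est <- sum(full_w * beta)
    se <- sqrt(sigma2 * drop(t(full_w) %*% XtXinv %*% full_w))
    tibble::tibble(term = nm, beta = est, se = se, t = est / se,
                   p = 2 * stats::pt(abs(est / se), df, lower.tail = FALSE))
  })

  structure(list(task = task, contrasts = contrasts, df = df,
                 sigma2 = sigma2, coefficients = beta,
                 residuals = as.vector(resid),
                 label = if (inherits(tc, "component_timecourse")) tc$label
                         else NA_character_),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result>%s df = %d, sigma2 = %.4g\n",
              if (is.na(x$label)) "" else paste0(" ", x$label),
              x$df, x$sigma2))
  print(x$task)
  invisible(x)
}

#' Run the single-subject analysis chain
#'
#' Composes the per-subject pipeline: motion QC, percent-signal-change
#' scaling, projection onto every network map, design construction (with the
#' subject's six motion parameters in the baseline), and GLM fitting. One
#' row is emitted per (network, condition or contrast).
#'
#' @param volumes A [volume_series()] (raw or already scaled).
#' @param maps List of [component_map()] on the data grid (resample first if
#'   needed).
#' @param design A [task_design()].
#' @param drift_order Legendre drift order for the baseline (default 2).
#' @param qc Apply [qc_motion()] and refuse failing data (default `TRUE`).
#' @return A tibble with columns `subject_id`, `network`, `condition`,
#'   `term_type` (`"condition"` or `"contrast"`), `beta`, `se`, `t`, `p`,
#'   `df`.
#' @export
run_subject <- function(volumes, maps, design, drift_order = 2, qc = TRUE) {
  stopifnot(inherits(volumes, "volume_series"))
  if (qc) {
    qcr <- qc_motion(volumes)
    if (!qcr$pass)
      stop("run_subject: motion QC failed (",
           length(qcr$offending_frames), " frame(s) over limit: ",
           paste(utils::head(qcr$offending_frames, 5), collapse = ", "),
           if (length(qcr$offending_frames) > 5) ", ..." else "", ")")
  }
  for (m in maps)
    if (!grid_equal(m$grid, volumes$grid))
      stop("run_subject: map ", m$label, " not on the data grid; ",
           "resample_map() first")
  if (!volumes$scaled) volumes <- scale_psc(volumes)
  dm <- tryCatch(
    build_design(design, volumes$n_frames, volumes$tr,
                 motion = volumes$motion, drift_order = drift_order),
    error = function(e) stop("run_subject: design stage failed: ",
                             conditionMessage(e)))
  purrr::map_dfr(maps, function(map) {
    fit <- fit_glm(project_map(map, volumes), dm)
    dplyr::bind_rows(
      dplyr::mutate(fit$task, term_type = "condition"),
      dplyr::mutate(fit$contrasts, term_type = "contrast")
    ) |>
      dplyr::transmute(
        subject_id = volumes$subject_id %||% NA_character_,
        network = map$label,
        condition = .data$term,
        term_type = .data$term_type,
        beta = .data$beta, se = .data$se, t = .data$t, p = .data$p,
        df = fit$df)
  })
}

#' Run the analysis chain for a whole cohort
#'
#' Applies [run_subject()] to every subject and binds the recruitment rows;
#' subject-level covariates (head coil, session order) can be joined in for
#' downstream group analyses.
#'
#' @param volumes_list List of [volume_series()].
#' @param maps,design,drift_order,qc Passed to [run_subject()].
#' @param subjects Optional covariate tibble with `subject_id`; `coil` and
#'   `session_order` columns are carried into the output when present.
#' @return A recruitment tibble (one row per subject x network x term).
#' @export
run_cohort <- function(volumes_list, maps, design, subjects = NULL,
                       drift_order = 2, qc = TRUE) {
  tbl <- purrr::map_dfr(volumes_list, run_subject, maps = maps,
                        design = design, drift_order = drift_order, qc = qc)
  if (!is.null(subjects)) {
    keep <- intersect(c("subject_id", "coil", "session_order"),
                      names(subjects))
    tbl <- dplyr::left_join(tbl, subjects[keep], by = "subject_id")
  }
  tbl
}
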