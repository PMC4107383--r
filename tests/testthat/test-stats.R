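test_that("group t-test follows the textbook one-sample formula", {
  r <- group_ttest(c(-1, 1, -2, 2))
  expect_equal(r$t, 0)
  expect_equal(r$percent_positive, 50)

  b <- c(1, 2, 3, 4, 5)
  r2 <- group_ttest(b)
  expect_equal(r2$t, mean(b) / (sd(b) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r2$df, 4L)
  expect_equal(r2$percent_positive, 100)

  r3 <- group_ttest(c(-1, -2, 0, 3))
  expect_equal(r3$percent_positive + r3$percent_negative + r3$percent_zero,
               100)

  expect_error(group_ttest(c(2, 2, 2)), "zero variance")
  expect_error(group_ttest(1), "at least 2")
})

test_that("consistency grid equals cell-by-cell group tests", {
  set.seed(41)
  tbl <- tidyr::expand_grid(network = c("C_1", "C_2"),
                            condition = c("A", "B"),
                            subject_id = sprintf("s%02d", 1:15))
  tbl$beta <- rnorm(nrow(tbl), mean = rep(c(2, 0, -2, 1), each = 15))
  grid <- consistency_table(tbl)
  expect_equal(nrow(grid), 4L)
  for (i in seq_len(nrow(grid))) {
    cell <- tbl[tbl$network == grid$network[i] &
                  tbl$condition == grid$condition[i], ]
    expect_equal(grid$t[i], group_ttest(cell$beta)$t)
    expect_equal(grid$percent_positive[i],
                 group_ttest(cell$beta)$percent_positive)
  }
  expect_equal(grid$p_fdr, p.adjust(grid$p, "BH"))
})

test_that("stepwise selection finds exact predictors and honours thresholds", {
  set.seed(42)
  n <- 40
  cands <- as.data.frame(matrix(rnorm(n * 4), n,
                                dimnames = list(NULL, paste0("x", 1:4))))
  y <- 3 * cands$x1
  fit <- stepwise_select(y, cands)
  expect_equal(fit$selected, "x1")
  expect_equal(fit$p_enter, 0.05)
  expect_equal(fit$p_remove, 0.10)
  expect_error(stepwise_select(y, cands, p_enter = 0.2, p_remove = 0.1))

  cands$flat <- 1
  expect_warning(stepwise_select(y, cands), "constant")
})

test_that("stepwise selection agrees with an lm-based re-implementation", {
  set.seed(43)
  for (rep in 1:25) {
    n <- 40
    cands <- as.data.frame(matrix(rnorm(n * 6), n,
                                  dimnames = list(NULL, paste0("x", 1:6))))
    y <- 0.5 * cands$x2 + rnorm(n)
    fit <- stepwise_select(y, cands)
    expect_identical(fit$selected, oracle_stepwise(y, cands))
  }
})

test_that("stepwise selection is invariant to affine candidate rescaling", {
  set.seed(44)
  n <- 40
  cands <- as.data.frame(matrix(rnorm(n * 5), n,
                                dimnames = list(NULL, paste0("x", 1:5))))
  y <- 0.8 * cands$x3 + rnorm(n)
  base <- stepwise_select(y, cands)
  scaled <- cands
  scaled$x1 <- 100 * scaled$x1 - 7
  scaled$x3 <- -0.001 * scaled$x3 + 2
  res <- stepwise_select(y, scaled)
  expect_identical(res$selected, base$selected)
  expect_equal(res$fit$p[match(res$selected, res$fit$term)],
               base$fit$p[match(base$selected, base$fit$term)],
               tolerance = 1e-8)
})

test_that("Huber regression matches oracle, rlm, and collapses to OLS", {
  set.seed(45)
  n <- 50
  X <- data.frame(x = rnorm(n))
  y <- 1 + 2 * X$x + rnorm(n)
  y[1:5] <- y[1:5] + 10 * sd(y)     # gross outliers

  fit <- robust_fit(y, X)
  expect_equal(fit$coefficients$estimate, oracle_huber(y, X),
               tolerance = 1e-6)
  expect_equal(fit$tuning, 1.345)
  expect_true(fit$converged)

  rlm_fit <- MASS::rlm(y ~ x, data = X, psi = MASS::psi.huber, k = 1.345,
                       scale.est = "MAD", maxit = 200)
  expect_equal(fit$coefficients$estimate, unname(coef(rlm_fit)),
               tolerance = 1e-3)

  # enormous tuning constant keeps every weight at 1 -> plain OLS
  ols <- oracle_ols(y, cbind(1, X$x))
  loose <- robust_fit(y, X, tuning = 1e6)
  expect_equal(loose$coefficients$estimate, ols, tolerance = 1e-6)

  # clean noiseless data: all weights 1 from the start
  y0 <- 1 + 2 * X$x
  clean <- robust_fit(y0, X)
  expect_equal(clean$coefficients$estimate, c(1, 2), tolerance = 1e-8)

  expect_error(robust_fit(y, data.frame(a = X$x, b = X$x)), "rank")
})

test_that("Huber beats OLS against outliers and recovers slopes unbiasedly", {
  n <- 50; n_rep <- 100
  wins <- 0
  for (r in seq_len(n_rep)) {
    set.seed(4500 + r)
    x <- rnorm(n)
    y <- 1 - x + rnorm(n)
    out <- order(x, decreasing = TRUE)[1:5]   # high-leverage points
    y[out] <- y[out] + 10      # one-sided gross contamination at 10 sigma
    hub <- robust_fit(y, data.frame(x = x))$coefficients$estimate[2]
    ols <- oracle_ols(y, cbind(1, x))[2]
    if (abs(hub + 1) < abs(ols + 1)) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("robust slope interval has near-nominal coverage at moderate SNR", {
  n <- 40; n_rep <- 100
  sd_dev <- 11.5 * sqrt(n) / 4       # calibrated so the slope |t| is near 4
  est <- se <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(4600 + r)
    perf <- runif(n, 60, 100)
    y <- 5 - 1 * perf + rnorm(n, sd = sd_dev)
    fit <- robust_fit(y, data.frame(performance = perf))
    est[r] <- fit$coefficients$estimate[2]
    se[r] <- fit$coefficients$se[2]
  }
  expect_lt(abs(mean(est) + 1), 0.1)
  tcrit <- qt(0.975, n - 2)
  cover <- mean(abs(est + 1) <= tcrit * se)
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
})

test_that("variance split assigns ties upward and matches car's Levene test", {
  set.seed(46)
  y <- rnorm(41)
  perf <- c(runif(20, 60, 82), rep(83, 5), runif(16, 84, 100))
  r <- variance_split_test(y, perf)
  expect_equal(r$split_value, 83)
  expect_equal(r$n_high, 21L)        # the five 83s sit at/above the median
  expect_equal(r$df1, 1L)
  expect_equal(r$df2, 39L)

  g <- factor(perf >= 83)
  lev <- car::leveneTest(y, g, center = median)
  expect_equal(r$F, lev$`F value`[1], tolerance = 1e-10)
  expect_equal(r$p, lev$`Pr(>F)`[1], tolerance = 1e-10)

  bf <- oracle_brown_forsythe(y, perf >= 83)
  expect_equal(r$F, bf$F, tolerance = 1e-10)

  vr <- variance_split_test(y, perf, method = "variance-ratio")
  expect_equal(vr$df1, 19L)
  expect_equal(vr$df2, 20L)

  expect_warning(
    dz <- variance_split_test(c(rep(1, 3), rep(5, 3)),
                              c(60, 60, 60, 90, 90, 90)), "degenerate")
  expect_true(dz$degenerate)
  expect_equal(dz$sigma_low, 0)
})

test_that("two-stage performance regression recovers signal and confounds", {
  # strong link: performance selected, robust slope close to truth
  co <- gen_cohort(tiny_config(cohort_size = 40, n_networks = 1, seed = 8),
                   slope = -1, intercept = 5, subject_sd = 3,
                   generate_volumes = FALSE)
  tbl <- dplyr::transmute(co$truth, subject_id, network, condition,
                          beta = true_beta)
  fit <- performance_regression(tbl, co$subjects, "C_1")
  expect_true("performance" %in% fit$selected)
  slope <- fit$robust$coefficients$estimate[
    fit$robust$coefficients$term == "performance"]
  expect_lt(abs(slope + 1), 0.2)

  # coil-driven cohorts: coil always recovered; the null performance
  # covariate enters only at its type-I rate
  sel <- vapply(1:20, function(s) {
    co2 <- gen_cohort(tiny_config(cohort_size = 40, n_networks = 1,
                                  seed = 100 + s),
                      slope = 0, intercept = 0, subject_sd = 0.5,
                      nuisance_effects = list(coil = 10),
                      generate_volumes = FALSE)
    tbl2 <- dplyr::transmute(co2$truth, subject_id, network, condition,
                             beta = true_beta)
    fit2 <- performance_regression(tbl2, co2$subjects, "C_1")
    c(coil = any(startsWith(fit2$selected, "coil")),
      perf = "performance" %in% fit2$selected)
  }, logical(2))
  expect_true(all(sel["coil", ]))
  expect_lte(mean(sel["perf", ]), 0.3)

  # pure-noise cohort may select nothing -> intercept-only result flagged
  co3 <- gen_cohort(tiny_config(cohort_size = 20, n_networks = 1, seed = 2),
                    slope = 0, intercept = 0, subject_sd = 1,
                    generate_volumes = FALSE)
  tbl3 <- dplyr::transmute(co3$truth, subject_id, network, condition,
                           beta = true_beta)
  fit3 <- performance_regression(tbl3, co3$subjects, "C_1")
  if (fit3$no_predictors)
    expect_equal(fit3$robust$coefficients$term, "(Intercept)")

  # forced-in trial duration survives even when not selected
  fit4 <- performance_regression(tbl3, co3$subjects, "C_1",
                                 force_in = "mean_trial_duration")
  expect_true("mean_trial_duration" %in% fit4$selected)
})

test_that("tidy and glance expose broom-style summaries", {
  set.seed(47)
  X <- data.frame(x = rnorm(30))
  fit <- robust_fit(1 + X$x + rnorm(30, sd = 0.5), X)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$tuning, 1.345)
})
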