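test_that("the HRF kernel has the canonical double-gamma shape", {
  for (tr in c(0.5, 1, 2)) {
    h <- hrf_kernel(tr)
    expect_equal(max(h), 1)
    expect_equal(h[1], 0)
    expect_lt(abs(attr(h, "times")[which.max(h)] - 6), tr / 2 + 1e-9)
  }
  # fine-grid argmax of the underlying double-gamma sits at 6 s
  fine <- hrf_kernel(0.001)
  expect_equal(attr(fine, "times")[which.max(fine)], 6, tolerance = 0.01)
  # late undershoot is negative, bounded by the 6:1 ratio
  expect_lt(min(fine), 0)
  expect_gt(min(fine), -1 / 6)
})

test_that("design construction convolves boxcars and validates rank", {
  tr <- 2; n <- 40
  motion <- matrix(rnorm(n * 6, sd = 0.05), n, 6)

  # impulse-like single block of one TR reproduces the kernel samples
  d <- task_design(data.frame(condition = "task", onset = 0, duration = tr),
                   total_duration = n * tr)
  dm <- build_design(d, n, tr, motion, drift_order = 2)
  k <- hrf_kernel(tr)
  expect_equal(unname(dm$X[seq_along(k), "task"]), as.vector(k),
               tolerance = 1e-12)
  expect_true(all(dm$X[(length(k) + 1):n, "task"] == 0))

  expect_equal(sum(startsWith(colnames(dm$X), "motion_")), 6L)
  expect_equal(dm$baseline_columns,
               c(paste0("drift_", 0:2),
                 paste0("motion_", c("x", "y", "z", "roll", "pitch", "yaw"))))

  # condition covering every frame with flat drift and no motion variation
  # leaves nothing to separate task from baseline
  full <- task_design(data.frame(condition = "task", onset = 0,
                                 duration = n * tr),
                      total_duration = n * tr)
  expect_error(build_design(full, n, tr, matrix(0, n, 6), drift_order = 0),
               "collinear")

  short <- task_design(data.frame(condition = "task", onset = 0,
                                  duration = 100), total_duration = 100)
  expect_error(build_design(short, 10, 2, motion[1:10, ]), "shorter")
})

test_that("GLM estimates match the normal-equations oracle", {
  set.seed(21)
  tr <- 2; n <- 20
  motion <- matrix(rnorm(n * 6, sd = 0.05), n, 6)
  d <- block_design(n_frames = n, tr = tr, block_s = 8, rest_s = 8)
  dm <- build_design(d, n, tr, motion, drift_order = 0)
  stopifnot(ncol(dm$X) >= 4)
  for (rep in 1:5) {
    y <- rnorm(n)
    fit <- fit_glm(y, dm)
    expect_equal(unname(fit$coefficients), oracle_ols(y, dm$X),
                 tolerance = 1e-10)
  }
})

test_that("exact, orthogonal, and contrast cases behave as OLS dictates", {
  tr <- 2; n <- 60
  set.seed(22)
  motion <- matrix(rnorm(n * 6, sd = 0.05), n, 6)
  d <- task_design(data.frame(condition = c("A", "B"),
                              onset = c(10, 70), duration = 20),
                   contrasts = list(A_minus_B = c(A = 1, B = -1)),
                   total_duration = n * tr)
  dm <- build_design(d, n, tr, motion)

  y <- 2 * dm$X[, "A"]
  fit <- fit_glm(y, dm)
  expect_equal(fit$task$beta[fit$task$term == "A"], 2, tolerance = 1e-10)
  expect_equal(fit$sigma2, 0, tolerance = 1e-20)

  # contrast estimate is exactly the weighted sum of betas
  expect_equal(fit$contrasts$beta,
               sum(c(1, -1) * fit$task$beta), tolerance = 1e-12)

  # a response orthogonal to the design gets beta 0 for every task column
  y_orth <- qr.resid(qr(dm$X), rnorm(n))
  fit2 <- fit_glm(y_orth, dm)
  expect_lt(max(abs(fit2$task$beta)), 1e-10)

  # residuals orthogonal to every design column
  fit3 <- fit_glm(rnorm(n), dm)
  expect_lt(max(abs(t(dm$X) %*% fit3$residuals)), 1e-8)

  expect_error(fit_glm(rnorm(10), dm), "frames")
})

test_that("the subject runner composes scaling, projection and GLM", {
  cfg <- tiny_config(n_networks = 1, grid_shape = c(10, 10, 8))
  maps <- gen_component_maps(cfg)
  beta <- matrix(-3, 1, 1, dimnames = list("C_1", "task"))
  truth <- ground_truth("s1", beta, 80, noise_sd = 0, seed = 9)
  v <- gen_subject_volumes(maps, truth, cfg)
  rows <- run_subject(v, maps, cfg$design)
  expect_equal(nrow(rows), 2L)   # one condition + one contrast
  got <- rows$beta[rows$term_type == "condition"]
  expect_equal(got, -3, tolerance = 1e-6 * 3)

  # counting contract: maps x (conditions + contrasts)
  g <- scan_grid(c(6, 6, 4))
  maps10 <- lapply(1:10, function(i)
    single_voxel_map(g, c(1 + (i - 1) %% 6, 1 + (i - 1) %/% 6, 2),
                     label = paste0("C_", i)))
  d2 <- task_design(data.frame(condition = c("A", "B"),
                               onset = c(10, 50), duration = 16),
                    contrasts = list(A_vs_B = c(1, -1)),
                    total_duration = 100)
  v2 <- random_volumes(shape = c(6, 6, 4), n_frames = 50, seed = 5,
                       baseline = 100)
  expect_equal(nrow(run_subject(v2, maps10, d2)), 30L)

  # motion QC gate
  v$motion[10, 1] <- 10
  expect_error(run_subject(v, maps, cfg$design), "QC")
})

test_that("projecting then fitting equals voxelwise fitting then weighting", {
  set.seed(31)
  n <- 40
  v <- random_volumes(shape = c(4, 4, 2), n_frames = n, seed = 31,
                      baseline = 200)
  v <- scale_psc(v)
  d <- block_design(n_frames = n, tr = 2, block_s = 16, rest_s = 16)
  dm <- build_design(d, n, 2, v$motion)
  w <- array(rnorm(32), c(4, 4, 2))
  m <- component_map(w, v$grid)

  beta_proj <- fit_glm(project_map(m, v), dm)$task$beta
  beta_vox <- apply(v$data, 2, function(y) fit_glm(y, dm)$task$beta)
  expect_equal(beta_proj, sum(as.vector(w) * beta_vox), tolerance = 1e-8)
})

test_that("beta estimates are unbiased under noise", {
  # one synthetic subject design, many noise draws at matched signal/noise
  cfg <- tiny_config(n_networks = 1, grid_shape = c(6, 6, 4), n_frames = 60)
  maps <- gen_component_maps(cfg)
  true_b <- 2
  beta <- matrix(true_b, 1, 1, dimnames = list("C_1", "task"))
  n_rep <- 200
  est <- vapply(seq_len(n_rep), function(i) {
    truth <- ground_truth("s", beta, 50, noise_sd = abs(true_b), seed = i)
    v <- gen_subject_volumes(maps, truth, cfg)
    rows <- run_subject(v, maps, cfg$design, qc = FALSE)
    rows$beta[rows$term_type == "condition"]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - true_b), 2 * mc_se + 1e-12)
})
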