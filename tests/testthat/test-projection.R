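test_that("resampling is the identity on matching grids and preserves constants", {
  g <- scan_grid(c(4, 4, 3))
  m <- component_map(array(rnorm(48), c(4, 4, 3)), g)
  expect_identical(resample_map(m, g)$weights, m$weights)

  const <- component_map(array(7, c(4, 4, 3)), g)
  tg <- scan_grid(c(2, 2, 2), voxel_size = c(5, 5, 5), origin = c(1, 1, 1))
  expect_true(all(resample_map(const, tg)$weights == 7))
  expect_equal(max(abs(resample_map(const, tg, "trilinear")$weights - 7)),
               0, tolerance = 1e-12)

  far <- scan_grid(c(2, 2, 2), origin = c(1000, 0, 0))
  expect_error(resample_map(m, far), "disjoint")
})

test_that("nearest-neighbour downsampling picks the hand-computed voxel", {
  # source: 2x2x2 unit grid at origin 0 holding 1..8 in column-major order;
  # target: one voxel whose centre sits at world (0.6, 0.6, 0.6), i.e.
  # continuous source index 0.6 on each axis, rounding to source voxel
  # (1,1,1) 0-based = value 8
  src <- scan_grid(c(2, 2, 2), voxel_size = c(1, 1, 1))
  m <- component_map(array(1:8, c(2, 2, 2)), src)
  tg <- scan_grid(c(1, 1, 1), voxel_size = c(2, 2, 2),
                  origin = c(0.6, 0.6, 0.6))
  expect_equal(as.vector(resample_map(m, tg)$weights), 8)
})

test_that("percent signal change matches its definition", {
  g <- scan_grid(c(1, 1, 1))
  v <- volume_series(matrix(c(90, 110), 2, 1), g, tr = 1)
  expect_equal(as.vector(scale_psc(v)$data), c(-10, 10))

  vc <- volume_series(matrix(5, 4, 1), g, tr = 1)
  expect_true(all(scale_psc(vc)$data == 0))

  vr <- random_volumes(shape = c(4, 4, 2), n_frames = 20, baseline = 100)
  s <- scale_psc(vr)
  expect_lt(max(abs(colMeans(s$data))), 1e-10)
  expect_true(s$scaled)
  expect_error(scale_psc(s), "already")

  # near-zero-mean voxels are floored to zero and counted
  vz <- volume_series(cbind(c(1e-12, -1e-12), c(90, 110)),
                      scan_grid(c(2, 1, 1)), tr = 1)
  sz <- scale_psc(vz)
  expect_true(all(sz$data[, 1] == 0))
  expect_equal(attr(sz, "n_floored"), 1L)
})

test_that("projection matches the brute-force voxel-loop oracle", {
  set.seed(11)
  v <- random_volumes(shape = c(2, 2, 2), n_frames = 3, seed = 11)
  w <- array(rnorm(8), c(2, 2, 2))
  m <- component_map(w, v$grid)
  got <- project_map(m, v)$values
  want <- oracle_project(w, as_array(v))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("projection is linear, sifting, and grid-checked", {
  v <- random_volumes(shape = c(3, 3, 2), n_frames = 10, seed = 2)
  g <- v$grid
  zero <- component_map(array(0, g$shape), g)
  expect_true(all(project_map(zero, v)$values == 0))

  sift <- single_voxel_map(g, c(2, 3, 1))
  vox <- 2 + (3 - 1) * 3 + (1 - 1) * 9
  expect_equal(project_map(sift, v)$values, v$data[, vox])

  w1 <- array(rnorm(18), g$shape); w2 <- array(rnorm(18), g$shape)
  lhs <- project_map(component_map(2 * w1 - 3 * w2, g), v)$values
  rhs <- 2 * project_map(component_map(w1, g), v)$values -
    3 * project_map(component_map(w2, g), v)$values
  expect_equal(lhs, rhs, tolerance = 1e-10)

  other <- volume_series(matrix(0, 10, 8), scan_grid(c(2, 2, 2)), tr = 1)
  expect_error(project_map(component_map(w1, g), other), "resample")
})

test_that("stripe components are flagged by spatial parity correlation", {
  g <- scan_grid(c(8, 8, 6))
  parity <- netrecruit:::slice_parity_pattern(g, "even")
  stripe <- component_map(array(parity, g$shape), g, label = "stripe")
  blob <- gen_component_maps(tiny_config(n_networks = 1,
                                         grid_shape = c(8, 8, 6)))[[1]]
  dec <- decomposition(list(stripe, blob), matrix(rnorm(40), 20, 2))
  det <- detect_stripe_components(dec, mask = rep(TRUE, 384))
  expect_true(det$flagged[1])
  expect_equal(det$max_abs_r[1], 1, tolerance = 1e-12)
  expect_equal(det$best_pattern[1], "even")
  expect_error(detect_stripe_components(dec, slice_axis = 4), "axis")
})

test_that("component removal subtracts exactly the flagged reconstructions", {
  g <- scan_grid(c(4, 4, 2))
  set.seed(3)
  m1 <- component_map(array(rnorm(32), g$shape), g, "A")
  m2 <- component_map(array(rnorm(32), g$shape), g, "B")
  mix <- matrix(rnorm(30), 15, 2)
  data <- mix[, 1] %*% t(as.vector(m1$weights)) +
    mix[, 2] %*% t(as.vector(m2$weights))
  v <- volume_series(data, g, tr = 1)
  dec <- decomposition(list(m1, m2), mix)

  expect_identical(remove_components(v, dec, integer(0))$data, v$data)
  kept <- remove_components(v, dec, 1)
  expect_equal(kept$data, mix[, 2] %*% t(as.vector(m2$weights)),
               tolerance = 1e-10)
  none <- remove_components(v, dec, 1:2)
  expect_lt(max(abs(none$data)), 1e-10)
  expect_error(remove_components(v, dec, 3), "unknown")
})

test_that("removal of an orthogonal component leaves other timecourses unchanged", {
  g <- scan_grid(c(4, 4, 2))
  w1 <- array(0, g$shape); w1[1:2, , ] <- rnorm(16)
  w2 <- array(0, g$shape); w2[3:4, , ] <- rnorm(16)   # disjoint support
  m1 <- component_map(w1, g, "A"); m2 <- component_map(w2, g, "B")
  set.seed(4)
  mix <- matrix(rnorm(40), 20, 2)
  noise <- matrix(rnorm(20 * 32, sd = 0.1), 20, 32)
  v <- volume_series(mix[, 1] %*% t(as.vector(w1)) +
                       mix[, 2] %*% t(as.vector(w2)) + noise, g, tr = 1)
  before <- project_map(m2, v)$values
  after <- project_map(m2, remove_components(v, decomposition(list(m1, m2),
                                                              mix), 1))$values
  expect_equal(after, before, tolerance = 1e-8)
})

test_that("motion QC applies the 3 mm / 3 degree frame-to-first rule", {
  v <- random_volumes(n_frames = 10)
  v$motion[] <- 0
  expect_true(qc_motion(v)$pass)

  v$motion[7, 2] <- 3.5           # y translation beyond the limit
  r <- qc_motion(v)
  expect_false(r$pass)
  expect_equal(r$offending_frames, 7L)

  # rotations are checked on their own scale
  v$motion[7, 2] <- 0
  v$motion[4, 6] <- -3.2
  expect_equal(qc_motion(v)$offending_frames, 4L)

  # limits are relative to the first frame, not to zero
  v$motion[] <- 2.9
  expect_true(qc_motion(v)$pass)
})
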