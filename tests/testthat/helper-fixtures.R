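# small deterministic fixtures shared across tests

tiny_config <- function(seed = 1, ...) {
  args <- list(grid_shape = c(12, 12, 8), n_frames = 80, tr = 2,
               n_networks = 2, cohort_size = 4, snr = Inf,
               master_seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# random volume series with small nonzero motion so designs stay full rank
random_volumes <- function(shape = c(4, 4, 2), n_frames = 20, tr = 2,
                           seed = 1, baseline = 0) {
  set.seed(seed)
  g <- scan_grid(shape)
  motion <- matrix(rnorm(n_frames * 6, sd = 0.05), n_frames, 6)
  volume_series(baseline + matrix(rnorm(n_frames * prod(shape)),
                                  n_frames, prod(shape)),
                g, tr = tr, motion = motion)
}

# indicator map putting weight 1 on a single voxel (1-based index triple)
single_voxel_map <- function(grid, ijk, label = "C_1") {
  w <- array(0, grid$shape)
  w[ijk[1], ijk[2], ijk[3]] <- 1
  component_map(w, grid, label = label, kind = "indicator-mask")
}
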