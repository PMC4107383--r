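#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults are a
#' desk-scale stand-in for a block-design task fMRI study: a 20 x 20 x 10
#' voxel grid at 3 mm, TR 2 s, 150 frames, a 20 s on / 20 s off block task,
#' and 38 subjects. Identical `master_seed` and parameters reproduce a cohort
#' bit-for-bit.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param n_frames Frames per run.
#' @param tr Repetition time, seconds.
#' @param n_networks Number of network blobs to place.
#' @param design A [task_design()]; default [block_design()] matched to
#'   `n_frames` and `tr`.
#' @param snr Signal-to-noise ratio: per-subject noise sd is
#'   `mean(abs(true_beta)) / snr` in percent-signal-change units; `Inf` for
#'   noiseless data.
#' @param ar_coefficient AR(1) coefficient of the temporal noise in `[0, 1)`;
#'   0 (default) gives white noise.
#' @param cohort_size Number of subjects.
#' @param artifact_spec Optional list `list(parity =, amplitude =)` describing
#'   a slice-stripe artifact injected into every subject (see
#'   [inject_stripe_artifact()]).
#' @param master_seed Integer master seed; all randomness derives from it.
#' @param baseline Raw-signal baseline level (arbitrary scanner units).
#' @param blob_sigma Gaussian width of network blobs, voxels.
#' @param voxel_size Voxel size in mm.
#' @param performance_range Range of the uniform performance score
#'   (accuracy %), within `[0, 100]`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_shape = c(20, 20, 10), n_frames = 150, tr = 2,
                       n_networks = 3, design = NULL, snr = 5,
                       ar_coefficient = 0, cohort_size = 38,
                       artifact_spec = NULL, master_seed = 1L,
                       baseline = 1000, blob_sigma = 1.5,
                       voxel_size = c(3, 3, 3),
                       performance_range = c(60, 100)) {
  stopifnot(all(grid_shape >= 1), n_frames >= 1, tr > 0, n_networks >= 1,
            snr > 0, ar_coefficient >= 0, ar_coefficient < 1,
            cohort_size >= 1, baseline > 0, blob_sigma > 0,
            performance_range[1] >= 0, performance_range[2] <= 100,
            performance_range[1] < performance_range[2])
  master_seed <- as.integer(master_seed)
  if (is.null(design)) design <- block_design(n_frames = n_frames, tr = tr)
  if (!is.null(artifact_spec))
    stopifnot(is.list(artifact_spec),
              all(c("parity", "amplitude") %in% names(artifact_spec)))
  structure(list(grid = scan_grid(grid_shape, voxel_size),
                 n_frames = as.integer(n_frames), tr = tr,
                 n_networks = as.integer(n_networks), design = design,
                 snr = snr, ar_coefficient = ar_coefficient,
                 cohort_size = as.integer(cohort_size),
                 artifact_spec = artifact_spec, master_seed = master_seed,
                 baseline = baseline, blob_sigma = blob_sigma,
                 performance_range = as.numeric(performance_range)),
            class = "sim_config")
}

# deterministic seed splitting: all generator randomness flows from the
# master seed through this rule, so cohorts reproduce under any call order
derive_seed <- function(seed, salt) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (k in c(salt, 2654435761)) s <- (s * 48271 + k) %% 2147483647
  as.integer(s)
}

#' Per-subject ground truth
#'
#' Records the generative state of one synthetic subject: the true recruitment
#' amplitude for every (network, condition) cell, the performance score, the
#' linear link (`true_beta = intercept + slope * performance + deviation`),
#' the noise level, and the seed. Regenerating with the same seed reproduces
#' the subject bit-identically.
#'
#' @param subject_id Identifier.
#' @param true_beta Numeric matrix, networks x conditions, dimnames required.
#' @param performance Performance score in `[0, 100]`.
#' @param slope,intercept Generative coefficients of the performance link.
#' @param noise_sd Noise standard deviation (percent-signal-change units),
#'   `>= 0`.
#' @param seed Integer seed that generated (and regenerates) this subject.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(subject_id, true_beta, performance, slope = 0,
                         intercept = 0, noise_sd = 0, seed = 1L) {
  true_beta <- as.matrix(true_beta)
  stopifnot(!is.null(rownames(true_beta)), !is.null(colnames(true_beta)),
            noise_sd >= 0, performance >= 0, performance <= 100)
  structure(list(subject_id = subject_id, true_beta = true_beta,
                 performance = performance, slope = slope,
                 intercept = intercept, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate network component maps
#'
#' Places `n_networks` Gaussian blobs at seeded random integer-voxel centres,
#' truncated at 3 sigma so supports are pairwise disjoint, and normalised to
#' unit energy (sum of squared weights = 1). Unit-energy disjoint maps make
#' the dot-product projection an orthogonal-projection coefficient, so the
#' generative amplitudes are recovered exactly in the noiseless closed loop.
#'
#' @param config A [sim_config()].
#' @return List of `n_networks` [component_map()] objects labelled
#'   `C_1 ... C_n`, each with attribute `center` (0-based voxel indices).
#' @export
gen_component_maps <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$grid
  sigma <- config$blob_sigma
  r_t <- 3 * sigma                    # truncation radius, voxels
  min_sep <- 2 * r_t + 0.5
  margin <- 1
  lo <- rep(margin, 3)
  hi <- g$shape - 1 - margin
  if (any(hi < lo))
    stop("gen_component_maps: grid too small to place network 1")

  set.seed(derive_seed(config$master_seed, 101))
  centers <- matrix(NA_real_, config$n_networks, 3)
  for (i in seq_len(config$n_networks)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      cand <- vapply(1:3, function(a) sample(lo[a]:hi[a], 1), numeric(1))
      ok <- i == 1 ||
        all(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                            matrix(cand, i - 1, 3, byrow = TRUE))^2)) >= min_sep)
      if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("gen_component_maps: grid too small to place network ", i,
           " with separation ", min_sep, " voxels")
  }

  ax <- lapply(1:3, function(a) seq_len(g$shape[a]) - 1)
  maps <- lapply(seq_len(config$n_networks), function(i) {
    d2 <- outer(outer((ax[[1]] - centers[i, 1])^2,
                      (ax[[2]] - centers[i, 2])^2, `+`),
                (ax[[3]] - centers[i, 3])^2, `+`)
    w <- exp(-d2 / (2 * sigma^2))
    w[d2 > r_t^2] <- 0
    w <- w / sqrt(sum(w^2))
    m <- component_map(w, g, label = paste0("C_", i))
    attr(m, "center") <- centers[i, ]
    m
  })

  # disjoint supports guarantee zero overlap; assert the contract anyway
  W <- vapply(maps, function(m) as.vector(m$weights), numeric(n_voxels(g)))
  ov <- crossprod(W)
  diag(ov) <- 0
  if (max(abs(ov)) >= 0.1)
    stop("gen_component_maps: map overlap contract violated")
  maps
}

# mean-centred HRF-convolved condition regressors, frames x conditions
task_signal_regressors <- function(design, n_frames, tr) {
  kernel <- hrf_kernel(tr)
  S <- vapply(design$condition_labels, function(lab) {
    s <- convolve_hrf(condition_boxcar(design, lab, n_frames, tr), kernel)
    s - mean(s)
  }, numeric(n_frames))
  matrix(S, nrow = n_frames, dimnames = list(NULL, design$condition_labels))
}

#' Generate one subject's 4-D volume series
#'
#' Builds the raw BOLD series as a multiplicative percent modulation of a
#' constant baseline: `Y(t, v) = B * (1 + (signal + noise)(t, v) / 100)`,
#' where the signal at voxel v is `sum_M X_M(v) * sum_N beta(M, N) * s_N(t)`
#' with `s_N` the mean-centred HRF-convolved condition boxcar (shared with
#' [build_design()]), and the noise is white (or AR(1)) Gaussian with
#' per-voxel sd `truth$noise_sd` in percent-signal-change units. A small
#' random-walk motion-parameter table is attached; if the config carries an
#' `artifact_spec`, the stripe artifact is injected.
#'
#' @param maps List of [component_map()] on one grid, labels matching the
#'   rownames of `truth$true_beta`.
#' @param truth A [ground_truth()] with a `true_beta` entry for every
#'   (map label, design condition) pair.
#' @param config A [sim_config()].
#' @return A [volume_series()] (raw units, `scaled = FALSE`).
#' @export
gen_subject_volumes <- function(maps, truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  g <- maps[[1]]$grid
  for (m in maps[-1])
    if (!grid_equal(g, m$grid))
      stop("gen_subject_volumes: maps on different grids")
  labels <- vapply(maps, function(m) m$label, character(1))
  conds <- config$design$condition_labels
  missing_nets <- setdiff(labels, rownames(truth$true_beta))
  missing_conds <- setdiff(conds, colnames(truth$true_beta))
  if (length(missing_nets) || length(missing_conds))
    stop("gen_subject_volumes: true_beta missing entries for ",
         paste(c(missing_nets, missing_conds), collapse = ", "))

  nt <- config$n_frames
  nv <- n_voxels(g)
  S <- task_signal_regressors(config$design, nt, config$tr)   # nt x conds
  B <- truth$true_beta[labels, conds, drop = FALSE]           # nets x conds
  amp <- S %*% t(B)                                           # nt x nets
  W <- vapply(maps, function(m) as.vector(m$weights), numeric(nv))
  psc <- amp %*% t(W)                                         # nt x nv

  if (truth$noise_sd > 0) {
    set.seed(derive_seed(truth$seed, 7))
    eps <- matrix(stats::rnorm(nt * nv), nt, nv)
    phi <- config$ar_coefficient
    if (phi > 0) {
      # stationary AR(1) with marginal sd 1
      for (t in 2:nt) eps[t, ] <- phi * eps[t - 1, ] + sqrt(1 - phi^2) * eps[t, ]
    }
    psc <- psc + truth$noise_sd * eps
  }

  data <- config$baseline * (1 + psc / 100)

  set.seed(derive_seed(truth$seed, 11))
  motion <- apply(matrix(stats::rnorm(nt * 6, sd = 0.01), nt, 6), 2, cumsum)
  motion <- matrix(motion, nt, 6)

  vs <- volume_series(data, g, tr = config$tr, motion = motion,
                      subject_id = truth$subject_id)
  if (!is.null(config$artifact_spec))
    vs <- inject_stripe_artifact(vs,
                                 parity = config$artifact_spec$parity,
                                 amplitude = config$artifact_spec$amplitude,
                                 seed = derive_seed(truth$seed, 13))
  vs
}

#' Inject a slice-stripe motion artifact
#'
#' Head motion under interleaved slice acquisition leaves alternating bands
#' of correlated signal locked to slice parity. The injected artifact is
#' `amplitude * m(v) * a(t)` with `m` the +/-1 slice-parity spatial pattern
#' along the slice axis and `a(t)` a seeded standard-normal timecourse.
#'
#' @param volumes A [volume_series()].
#' @param parity `"even"`, `"odd"`, or `"interleave-k"` for sign flips every
#'   k slices (e.g. `"interleave-2"`); slice indices are 0-based.
#' @param amplitude Artifact amplitude, `>= 0`; 0 returns the input unchanged.
#' @param seed Integer seed for the artifact timecourse.
#' @param slice_axis Axis of slice acquisition (default 3).
#' @return A [volume_series()] with the artifact added.
#' @export
inject_stripe_artifact <- function(volumes, parity = "even", amplitude,
                                   seed = 1L, slice_axis = 3) {
  stopifnot(inherits(volumes, "volume_series"), amplitude >= 0)
  if (amplitude == 0) return(volumes)
  m <- slice_parity_pattern(volumes$grid, parity, slice_axis)
  set.seed(as.integer(seed))
  a <- stats::rnorm(volumes$n_frames)
  volumes$data <- volumes$data + amplitude * (a %*% t(m))
  volumes
}

# +/-1 spatial pattern over the grid from slice parity along slice_axis;
# "even" = +1 on 0-based even slices, "odd" its negation, "interleave-k"
# flips sign every k slices
slice_parity_pattern <- function(grid, parity, slice_axis = 3) {
  if (slice_axis < 1 || slice_axis > 3)
    stop("slice_parity_pattern: slice axis ", slice_axis,
         " outside grid dimensionality")
  idx <- seq_len(grid$shape[slice_axis]) - 1
  sign_of <- if (parity %in% c("even", "odd")) {
    s <- ifelse(idx %% 2 == 0, 1, -1)
    if (parity == "odd") -s else s
  } else if (grepl("^interleave-[0-9]+$", parity)) {
    k <- as.integer(sub("interleave-", "", parity))
    if (k < 1) stop("slice_parity_pattern: interleave step must be >= 1")
    ifelse((idx %/% k) %% 2 == 0, 1, -1)
  } else {
    stop("slice_parity_pattern: unknown parity keyword '", parity, "'")
  }
  per_voxel <- array(1, grid$shape)
  perm <- broadcast_slices(per_voxel, slice_axis, sign_of)
  as.vector(perm)
}

# broadcast a per-slice vector along slice_axis into a full 3-D array
broadcast_slices <- function(arr, axis, values) {
  d <- dim(arr)
  out <- array(0, d)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (s in seq_len(d[axis])) {
    idx_s <- idx
    idx_s[[axis]] <- s
    out[idx_s[[1]], idx_s[[2]], idx_s[[3]]] <- values[s]
  }
  out
}

#' Generate a synthetic cohort with a performance-activity link
#'
#' Draws performance scores uniformly over the configured range, builds each
#' subject's true recruitment amplitudes as
#' `true_beta = intercept + slope * performance + N(0, subject_sd)` per
#' (network, condition) cell, generates nuisance covariates (age, sex,
#' education, handedness, head coil, session order, mean trial duration)
#' independently of amplitude unless a nonzero `nuisance_effects` entry is
#' configured, and (optionally) synthesises every subject's 4-D volumes.
#'
#' @param config A [sim_config()].
#' @param slope,intercept Generative link coefficients; scalars, or vectors
#'   recycled over networks (so e.g. one network can deactivate).
#' @param subject_sd Between-subject sd of amplitude deviations (beta units).
#' @param nuisance_effects Optional named list of additive amplitude effects
#'   for binary covariates, e.g. `list(coil = 10)` adds 10 to every cell of
#'   subjects scanned with the 32-channel coil. Supported names: `coil`,
#'   `sex`, `handedness`, `session_order`.
#' @param generate_volumes If `FALSE`, skip the (relatively expensive) volume
#'   synthesis and return `volumes = NULL`; truth and covariates are
#'   unaffected.
#' @return A list with elements `maps` (the shared [gen_component_maps()]
#'   output), `volumes` (list of [volume_series()] or `NULL`), `subjects`
#'   (tibble of covariates, one row per subject) and `truth` (long tibble of
#'   true amplitudes per subject x network x condition); all index-aligned
#'   by `subject_id`.
#' @export
gen_cohort <- function(config, slope = 0, intercept = 1, subject_sd = 5,
                       nuisance_effects = NULL, generate_volumes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$cohort_size < 2)
    stop("gen_cohort: cohort_size must be >= 2")
  n <- config$cohort_size
  nets <- paste0("C_", seq_len(config$n_networks))
  conds <- config$design$condition_labels
  slope <- rep_len(slope, config$n_networks)
  intercept <- rep_len(intercept, config$n_networks)

  set.seed(derive_seed(config$master_seed, 211))
  subjects <- tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    performance = stats::runif(n, config$performance_range[1],
                               config$performance_range[2]),
    age = round(pmin(pmax(stats::rnorm(n, 45, 12), 20), 75)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    education = sample(12:20, n, replace = TRUE),
    handedness = sample(c("R", "L"), n, replace = TRUE, prob = c(0.9, 0.1)),
    coil = sample(c("8ch", "32ch"), n, replace = TRUE),
    session_order = sample(c("AB", "BA"), n, replace = TRUE),
    mean_trial_duration = pmax(stats::rnorm(n, 6, 1), 1)
  )

  nuis_shift <- numeric(n)
  if (!is.null(nuisance_effects)) {
    ref <- list(coil = "32ch", sex = "M", handedness = "L",
                session_order = "BA")
    for (nm in names(nuisance_effects)) {
      if (!nm %in% names(ref))
        stop("gen_cohort: unsupported nuisance effect '", nm, "'")
      nuis_shift <- nuis_shift +
        nuisance_effects[[nm]] * (subjects[[nm]] == ref[[nm]])
    }
  }

  truths <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- derive_seed(config$master_seed, 1000 + i)
    set.seed(sseed)
    dev <- matrix(stats::rnorm(length(nets) * length(conds), sd = subject_sd),
                  length(nets), length(conds))
    beta <- matrix(intercept + slope * subjects$performance[i],
                   length(nets), length(conds)) + dev + nuis_shift[i]
    dimnames(beta) <- list(nets, conds)
    noise_sd <- if (is.finite(config$snr)) mean(abs(beta)) / config$snr else 0
    truths[[i]] <- ground_truth(subjects$subject_id[i], beta,
                                performance = subjects$performance[i],
                                slope = slope[1], intercept = intercept[1],
                                noise_sd = noise_sd, seed = sseed)
  }

  maps <- gen_component_maps(config)
  volumes <- NULL
  if (generate_volumes)
    volumes <- lapply(truths, gen_subject_volumes, maps = maps,
                      config = config)

  truth_tbl <- purrr::map_dfr(truths, function(tr)
    tidyr::expand_grid(network = nets, condition = conds) |>
      dplyr::mutate(subject_id = tr$subject_id,
                    true_beta = as.vector(t(tr$true_beta)),
                    performance = tr$performance,
                    noise_sd = tr$noise_sd, seed = tr$seed,
                    .before = 1))
  truth_tbl <- dplyr::relocate(truth_tbl, "subject_id")

  list(maps = maps, volumes = volumes, subjects = subjects,
       truth = truth_tbl, truth_objects = truths)
}
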