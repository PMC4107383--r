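#' Resample a component map onto a target grid
#'
#' Network maps are typically distributed at a different resolution than the
#' functional data and must be resampled onto the data grid before
#' projection. Nearest-neighbour interpolation is the default (it preserves
#' the original weight values); trilinear interpolation is available. Grids
#' are related through their world-space (mm) coordinates; when the grids
#' already match the map is returned unchanged.
#'
#' @param map A [component_map()].
#' @param target_grid A [scan_grid()] overlapping the map in world space.
#' @param method `"nearest"` (default) or `"trilinear"`.
#' @return A [component_map()] on `target_grid`.
#' @export
resample_map <- function(map, target_grid, method = c("nearest", "trilinear")) {
  stopifnot(inherits(map, "component_map"), inherits(target_grid, "scan_grid"))
  method <- match.arg(method)
  src <- map$grid
  if (grid_equal(src, target_grid)) return(map)

  # world extents must overlap on every axis
  for (a in 1:3) {
    s_lo <- src$origin[a]; s_hi <- src$origin[a] + (src$shape[a] - 1) * src$voxel_size[a]
    t_lo <- target_grid$origin[a]
    t_hi <- target_grid$origin[a] + (target_grid$shape[a] - 1) * target_grid$voxel_size[a]
    if (t_hi < s_lo - src$voxel_size[a] / 2 || t_lo > s_hi + src$voxel_size[a] / 2)
      stop("resample_map: source and target grids are disjoint in world space",
           " on axis ", a)
  }

  # continuous source voxel index of each target voxel centre, per axis
  src_index <- lapply(1:3, function(a)
    (axis_world(target_grid, a) - src$origin[a]) / src$voxel_size[a])

  out <- array(0, target_grid$shape)
  if (method == "nearest") {
    near <- lapply(1:3, function(a)
      pmin(pmax(round(src_index[[a]]), 0), src$shape[a] - 1) + 1)
    out[] <- map$weights[as.matrix(expand.grid(near[[1]], near[[2]], near[[3]]))]
  } else {
    lo <- lapply(1:3, function(a)
      pmin(pmax(floor(src_index[[a]]), 0), src$shape[a] - 1))
    hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1, src$shape[a] - 1))
    fr <- lapply(1:3, function(a)
      pmin(pmax(src_index[[a]] - lo[[a]], 0), 1))
    idx <- expand.grid(i = seq_len(target_grid$shape[1]),
                       j = seq_len(target_grid$shape[2]),
                       k = seq_len(target_grid$shape[3]))
    acc <- numeric(nrow(idx))
    for (corner in 0:7) {
      cx <- bitwAnd(corner, 1L); cy <- bitwAnd(bitwShiftR(corner, 1L), 1L)
      cz <- bitwAnd(bitwShiftR(corner, 2L), 1L)
      xi <- (if (cx) hi[[1]] else lo[[1]])[idx$i] + 1
      yi <- (if (cy) hi[[2]] else lo[[2]])[idx$j] + 1
      zi <- (if (cz) hi[[3]] else lo[[3]])[idx$k] + 1
      wx <- (if (cx) fr[[1]] else 1 - fr[[1]])[idx$i]
      wy <- (if (cy) fr[[2]] else 1 - fr[[2]])[idx$j]
      wz <- (if (cz) fr[[3]] else 1 - fr[[3]])[idx$k]
      acc <- acc + wx * wy * wz * map$weights[cbind(xi, yi, zi)]
    }
    out[] <- acc
  }
  component_map(out, target_grid, label = map$label, kind = map$kind)
}

#' Scale a volume series to percent signal change
#'
#' Each voxel's series `v(t)` becomes `100 * (v(t) - mean(v)) / mean(v)`,
#' the standard BOLD normalisation that makes amplitudes comparable across
#' voxels and subjects. Voxels whose temporal mean magnitude falls below
#' `mean_floor` carry no interpretable signal and are zeroed out (their count
#' is recorded in attribute `n_floored`). Scaling is a one-shot state change:
#' applying it twice is an error.
#'
#' @param volumes A [volume_series()] with `scaled = FALSE`.
#' @param mean_floor Minimum `|temporal mean|` for a voxel to be scaled.
#' @return The scaled [volume_series()] (`scaled = TRUE`).
#' @export
scale_psc <- function(volumes, mean_floor = 1e-8) {
  stopifnot(inherits(volumes, "volume_series"))
  if (volumes$scaled)
    stop("scale_psc: series is already in percent-signal-change units")
  mu <- colMeans(volumes$data)
  bad <- abs(mu) < mean_floor
  mu_safe <- ifelse(bad, 1, mu)
  volumes$data <- 100 * sweep(sweep(volumes$data, 2, mu, "-"), 2, mu_safe, "/")
  volumes$data[, bad] <- 0
  volumes$scaled <- TRUE
  attr(volumes, "n_floored") <- sum(bad)
  volumes
}

#' Project a volume series onto a component map
#'
#' The component timecourse is the voxelwise dot product between the spatial
#' map and each frame: `values[t] = sum_v weights(v) * data(t, v)`. Each
#' frame's intensities are thereby weighted by the voxel's contribution to
#' the network. The operation is linear in both the map and the data.
#'
#' @param map A [component_map()] on the same grid as the data (use
#'   [resample_map()] first otherwise).
#' @param volumes A [volume_series()].
#' @return A `component_timecourse`: list with `label`, `values` (one per
#'   frame), `tr` and `source_id`.
#' @export
project_map <- function(map, volumes) {
  stopifnot(inherits(map, "component_map"), inherits(volumes, "volume_series"))
  if (!grid_equal(map$grid, volumes$grid))
    stop("project_map: map grid does not match data grid; ",
         "resample_map() the map onto the data grid first")
  values <- as.vector(volumes$data %*% as.vector(map$weights))
  structure(list(label = map$label, values = values, tr = volumes$tr,
                 source_id = volumes$subject_id),
            class = "component_timecourse")
}

#' @export
print.component_timecourse <- function(x, ...) {
  cat(sprintf("<component_timecourse> %s, %d frames, range [%.3g, %.3g]\n",
              x$label, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Detect slice-stripe artifact components
#'
#' Head-motion artifact appears in ICA decompositions as spatial maps with
#' alternating bands locked to slice-acquisition parity. For every component
#' the Pearson correlation is computed between its spatial map (over in-mask
#' voxels) and each mean-centred +/-1 slice-parity pattern; a component is
#' flagged when any `|r|` exceeds the threshold. The default threshold of
#' 0.05 is deliberately liberal: parity patterns do not represent plausible
#' brain activity, so false positives are cheap.
#'
#' @param decomp A [decomposition()].
#' @param slice_axis Slice-acquisition axis (default 3).
#' @param patterns Character vector of parity patterns to test (see
#'   [inject_stripe_artifact()]).
#' @param threshold Flagging threshold on `|r|`, in (0, 1); default 0.05.
#' @param mask Optional logical/0-1 vector over voxels restricting the
#'   correlation; default: voxels with nonzero weight in any component map.
#' @return A tibble with one row per component: `component`, `label`,
#'   `max_abs_r`, `best_pattern`, `flagged`.
#' @export
detect_stripe_components <- function(decomp, slice_axis = 3,
                                     patterns = c("even", "odd"),
                                     threshold = 0.05, mask = NULL) {
  stopifnot(inherits(decomp, "decomposition"), length(patterns) >= 1,
            threshold > 0, threshold < 1)
  if (slice_axis < 1 || slice_axis > 3)
    stop("detect_stripe_components: slice axis ", slice_axis,
         " outside grid dimensionality")
  W <- vapply(decomp$spatial_maps, function(m) as.vector(m$weights),
              numeric(n_voxels(decomp$grid)))
  if (is.null(mask)) mask <- rowSums(W != 0) > 0
  mask <- as.logical(mask)
  P <- vapply(patterns, function(p)
    slice_parity_pattern(decomp$grid, p, slice_axis),
    numeric(n_voxels(decomp$grid)))
  r <- abs(stats::cor(W[mask, , drop = FALSE], P[mask, , drop = FALSE]))
  r[is.na(r)] <- 0                      # zero-variance map or pattern in mask
  best <- apply(r, 1, which.max)
  tibble::tibble(
    component = seq_len(decomp$n_components),
    label = vapply(decomp$spatial_maps, function(m) m$label, character(1)),
    max_abs_r = apply(r, 1, max),
    best_pattern = patterns[best],
    flagged = apply(r, 1, max) > threshold
  )
}

#' Remove components from a volume series
#'
#' Subtracts the outer-product reconstruction of the flagged components
#' (`mixing[, f] %o% spatial_map_f`) from the data, the standard ICA
#' denoising step once stripe components have been identified. Removing the
#' empty set is the identity.
#'
#' @param volumes The [volume_series()] the decomposition was derived from.
#' @param decomp A [decomposition()] on the same grid and frame count.
#' @param flagged Integer ids of components to remove (e.g. the `component`
#'   column of [detect_stripe_components()] rows with `flagged == TRUE`).
#' @return The cleaned [volume_series()].
#' @export
remove_components <- function(volumes, decomp, flagged) {
  stopifnot(inherits(volumes, "volume_series"), inherits(decomp, "decomposition"))
  if (!grid_equal(volumes$grid, decomp$grid))
    stop("remove_components: decomposition grid does not match data grid")
  if (nrow(decomp$mixing) != volumes$n_frames)
    stop("remove_components: decomposition has ", nrow(decomp$mixing),
         " frames, data has ", volumes$n_frames)
  if (!length(flagged)) return(volumes)
  flagged <- as.integer(flagged)
  unknown <- setdiff(flagged, seq_len(decomp$n_components))
  if (length(unknown))
    stop("remove_components: unknown component id(s): ",
         paste(unknown, collapse = ", "))
  W <- vapply(decomp$spatial_maps[flagged], function(m) as.vector(m$weights),
              numeric(n_voxels(decomp$grid)))
  volumes$data <- volumes$data -
    decomp$mixing[, flagged, drop = FALSE] %*% t(W)
  volumes
}

#' Motion quality control
#'
#' A dataset passes QC when every frame stays within the translation and
#' rotation limits relative to the first frame: below 3 mm on every
#' translation axis and below 3 degrees on every rotation axis by default.
#'
#' @param volumes A [volume_series()] with a motion table.
#' @param max_translation_mm Translation limit per axis (default 3).
#' @param max_rotation_deg Rotation limit per axis (default 3).
#' @return A list: `pass` (logical), `offending_frames` (integer frame
#'   indices), `max_translation`, `max_rotation` observed.
#' @export
qc_motion <- function(volumes, max_translation_mm = 3.0,
                      max_rotation_deg = 3.0) {
  stopifnot(inherits(volumes, "volume_series"))
  m <- volumes$motion
  if (is.null(m)) stop("qc_motion: no motion table attached")
  rel <- sweep(m, 2, m[1, ], "-")
  trans_bad <- apply(abs(rel[, 1:3, drop = FALSE]) >= max_translation_mm, 1, any)
  rot_bad <- apply(abs(rel[, 4:6, drop = FALSE]) >= max_rotation_deg, 1, any)
  offending <- which(trans_bad | rot_bad)
  list(pass = length(offending) == 0,
       offending_frames = offending,
       max_translation = max(abs(rel[, 1:3])),
       max_rotation = max(abs(rel[, 4:6])))
}
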