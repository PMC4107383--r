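#' Define a scan grid
#'
#' A grid describes the 3-D sampling lattice shared by spatial maps and
#' functional volumes: the number of voxels per axis, the voxel size in mm,
#' and the world-space position of the first voxel. Voxel indices are 0-based
#' in world-coordinate arithmetic (`world = origin + index * voxel_size`);
#' the third axis is the slice axis unless stated otherwise.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param voxel_size Numeric vector of length 3, voxel edge length in mm.
#' @param origin Numeric vector of length 3, world coordinate (mm) of voxel
#'   `(0, 0, 0)`.
#' @return A `scan_grid` object.
#' @export
#' @examples
#' scan_grid(c(20, 20, 10), voxel_size = c(3, 3, 3))
scan_grid <- function(shape, voxel_size = c(3, 3, 3), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1),
            length(voxel_size) == 3, all(voxel_size > 0),
            length(origin) == 3, all(is.finite(origin)))
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("<scan_grid> %s voxels, %s mm, origin (%s)\n",
              paste(x$shape, collapse = "x"),
              paste(x$voxel_size, collapse = "x"),
              paste(x$origin, collapse = ", ")))
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

n_voxels <- function(grid) prod(grid$shape)

# world coordinates of every voxel centre along one axis (0-based indices)
axis_world <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_size[axis]
}

#' Create a network component map
#'
#' A component map is a 3-D spatial weight image for one intrinsic network
#' (an ICA z/t statistic map or a binary indicator mask) on a known grid.
#' Labels follow the `C_1 ... C_10` convention used for canonical
#' resting-state networks, but any identifier is accepted.
#'
#' @param weights 3-D numeric array of voxel weights; finite values only.
#' @param grid A [scan_grid()] whose shape matches `dim(weights)`.
#' @param label Network identifier (e.g. `"C_3"`).
#' @param kind `"statistic-map"` (default) or `"indicator-mask"`.
#' @return A `component_map` object.
#' @export
component_map <- function(weights, grid, label = "C_1", kind = "statistic-map") {
  weights <- as.array(weights)
  stopifnot(length(dim(weights)) == 3L, all(is.finite(weights)))
  if (!identical(as.integer(dim(weights)), grid$shape))
    stop("component_map: weights shape (", paste(dim(weights), collapse = "x"),
         ") does not match grid shape (", paste(grid$shape, collapse = "x"), ")")
  kind <- match.arg(kind, c("statistic-map", "indicator-mask"))
  structure(list(label = label, weights = weights, grid = grid, kind = kind),
            class = "component_map")
}

#' @export
print.component_map <- function(x, ...) {
  cat(sprintf("<component_map> %s (%s), grid %s, weight range [%.3g, %.3g]\n",
              x$label, x$kind, paste(x$grid$shape, collapse = "x"),
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Threshold a statistic map into a display mask
#'
#' Display figures conventionally show only voxels with strongly positive
#' contributions; the customary threshold for z/t-valued network maps is
#' `t >= 4`. The mask is for visualisation and export only — projection always
#' uses the unthresholded map.
#'
#' @param map A [component_map()] of kind `"statistic-map"`.
#' @param threshold Minimum weight retained; default 4.
#' @return A `component_map` of kind `"indicator-mask"` with 0/1 weights.
#' @export
display_mask <- function(map, threshold = 4) {
  stopifnot(inherits(map, "component_map"))
  component_map((map$weights >= threshold) * 1, map$grid,
                label = map$label, kind = "indicator-mask")
}

#' Create a 4-D functional volume series
#'
#' Holds a BOLD series as a frames-by-voxels matrix (voxels in column-major
#' order of the 3-D grid, x fastest) together with its repetition time and the
#' six rigid-body motion parameters per frame.
#'
#' @param data Numeric matrix, `n_frames` rows by `prod(grid$shape)` columns,
#'   or a 4-D array `(x, y, z, t)` which is reshaped.
#' @param grid A [scan_grid()].
#' @param tr Repetition time in seconds.
#' @param motion Numeric `n_frames` x 6 matrix with columns
#'   `x, y, z, roll, pitch, yaw` (mm and degrees), or `NULL` for all-zero.
#' @param scaled Logical; `TRUE` once the series is in percent-signal-change
#'   units.
#' @param subject_id Optional identifier carried through the pipeline.
#' @return A `volume_series` object.
#' @export
volume_series <- function(data, grid, tr, motion = NULL, scaled = FALSE,
                          subject_id = NULL) {
  if (length(dim(data)) == 4L) {
    stopifnot(identical(as.integer(dim(data)[1:3]), grid$shape))
    nt <- dim(data)[4]
    data <- t(matrix(data, nrow = prod(dim(data)[1:3]), ncol = nt))
  }
  data <- as.matrix(data)
  if (ncol(data) != n_voxels(grid))
    stop("volume_series: data has ", ncol(data), " voxels but grid has ",
         n_voxels(grid))
  n_frames <- nrow(data)
  if (is.null(motion)) motion <- matrix(0, n_frames, 6)
  motion <- as.matrix(motion)
  if (nrow(motion) != n_frames || ncol(motion) != 6)
    stop("volume_series: motion table must be ", n_frames, " frames x 6 columns")
  colnames(motion) <- c("x", "y", "z", "roll", "pitch", "yaw")
  stopifnot(tr > 0)
  structure(list(data = data, grid = grid, tr = tr, n_frames = n_frames,
                 motion = motion, scaled = isTRUE(scaled),
                 subject_id = subject_id),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series>%s %d frames x %s voxels, TR %.3gs, %s\n",
              if (is.null(x$subject_id)) "" else paste0(" ", x$subject_id),
              x$n_frames, paste(x$grid$shape, collapse = "x"), x$tr,
              if (x$scaled) "percent-signal-change" else "raw units"))
  invisible(x)
}

#' Convert a volume series back to a 4-D array
#'
#' @param volumes A [volume_series()].
#' @return A 4-D numeric array `(x, y, z, t)`.
#' @export
as_array <- function(volumes) UseMethod("as_array")

#' @export
as_array.volume_series <- function(volumes) {
  array(t(volumes$data), dim = c(volumes$grid$shape, volumes$n_frames))
}

#' Create an ICA-style decomposition
#'
#' Pairs spatial maps with their mixing (per-frame loading) timecourses so
#' that `mixing %*% maps` reconstructs the component contribution to a
#' 4-D series. The decomposition itself is produced elsewhere (e.g. by an
#' external ICA routine) and consumed here for artifact screening and removal.
#'
#' @param spatial_maps List of [component_map()] on one shared grid.
#' @param mixing Numeric `n_frames` x `n_components` matrix.
#' @return A `decomposition` object.
#' @export
decomposition <- function(spatial_maps, mixing) {
  stopifnot(length(spatial_maps) >= 1,
            all(vapply(spatial_maps, inherits, TRUE, "component_map")))
  mixing <- as.matrix(mixing)
  if (ncol(mixing) != length(spatial_maps))
    stop("decomposition: ", ncol(mixing), " mixing columns for ",
         length(spatial_maps), " spatial maps")
  g <- spatial_maps[[1]]$grid
  for (m in spatial_maps[-1])
    if (!grid_equal(g, m$grid)) stop("decomposition: maps on different grids")
  structure(list(spatial_maps = spatial_maps, mixing = mixing,
                 n_components = length(spatial_maps), grid = g),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d components, %d frames, grid %s\n",
              x$n_components, nrow(x$mixing),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Define a task design
#'
#' Conditions are lists of block (or event) onsets and durations in seconds;
#' contrasts are named weight vectors over conditions.
#'
#' @param conditions Data frame with columns `condition`, `onset`, `duration`
#'   (seconds); several rows per condition give several blocks.
#' @param contrasts Named list of numeric weight vectors, each with one entry
#'   per condition (named or in condition declaration order).
#' @param total_duration Total run length in seconds; every block must end by
#'   this time.
#' @return A `task_design` object.
#' @export
#' @examples
#' task_design(data.frame(condition = "task", onset = c(20, 60), duration = 20),
#'             total_duration = 100)
task_design <- function(conditions, contrasts = list(), total_duration) {
  conditions <- tibble::as_tibble(conditions)
  stopifnot(all(c("condition", "onset", "duration") %in% names(conditions)),
            total_duration > 0)
  if (any(conditions$onset < 0 | conditions$duration <= 0))
    stop("task_design: onsets must be >= 0 and durations > 0")
  if (any(conditions$onset + conditions$duration > total_duration + 1e-9))
    stop("task_design: a block ends after total_duration (",
         total_duration, " s)")
  labels <- unique(conditions$condition)
  contrasts <- lapply(contrasts, function(w) {
    if (!is.null(names(w))) {
      stopifnot(all(names(w) %in% labels))
      full <- stats::setNames(numeric(length(labels)), labels)
      full[names(w)] <- w
      full
    } else {
      stopifnot(length(w) == length(labels))
      stats::setNames(as.numeric(w), labels)
    }
  })
  structure(list(conditions = conditions, contrasts = contrasts,
                 condition_labels = labels, total_duration = total_duration),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("<task_design> %d condition(s): %s; %d contrast(s); %.4g s\n",
              length(x$condition_labels),
              paste(x$condition_labels, collapse = ", "),
              length(x$contrasts), x$total_duration))
  invisible(x)
}

#' A simple alternating block design
#'
#' Rest-task alternation starting with rest: blocks of `block_s` seconds of
#' the single condition separated by `rest_s` seconds, filling
#' `n_frames * tr` seconds. One `task_vs_rest` contrast is attached.
#'
#' @param n_frames,tr Run length in frames and repetition time (s).
#' @param block_s,rest_s Block and rest durations (s).
#' @param label Condition label.
#' @return A [task_design()].
#' @export
block_design <- function(n_frames = 150, tr = 2, block_s = 20, rest_s = 20,
                         label = "task") {
  total <- n_frames * tr
  onsets <- seq(rest_s, total - block_s, by = block_s + rest_s)
  if (!length(onsets)) stop("block_design: run too short for one block")
  task_design(
    tibble::tibble(condition = label, onset = onsets, duration = block_s),
    contrasts = stats::setNames(list(stats::setNames(1, label)),
                                paste0(label, "_vs_rest")),
    total_duration = total
  )
}
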