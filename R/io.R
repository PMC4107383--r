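#' Read and write NIFTI volumes
#'
#' Volume series are stored as 4-D NIFTI-1 (`.nii`/`.nii.gz`) with the voxel
#' size and TR in `pixdim`; the motion table travels separately as a
#' 6-column TSV. Component maps are 3-D NIFTI-1.
#'
#' @param volumes A [volume_series()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @param motion_path Optional TSV path for the motion parameters.
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(volumes, path, motion_path = NULL) {
  stopifnot(inherits(volumes, "volume_series"))
  img <- RNifti::asNifti(as_array(volumes))
  RNifti::pixdim(img) <- c(volumes$grid$voxel_size, volumes$tr)
  RNifti::writeNifti(img, path)
  if (!is.null(motion_path)) write_motion(volumes$motion, motion_path)
  invisible(path)
}

#' @rdname write_volume_series
#' @param tr Repetition time override (seconds); default from the header.
#' @param subject_id Optional identifier to attach.
#' @export
read_volume_series <- function(path, motion_path = NULL, tr = NULL,
                               subject_id = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop("read_volume_series: expected a 4-D image")
  pd <- RNifti::pixdim(img)
  grid <- scan_grid(dim(arr)[1:3], voxel_size = pd[1:3])
  if (is.null(tr)) tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  motion <- if (!is.null(motion_path)) read_motion(motion_path) else NULL
  volume_series(arr, grid, tr = tr, motion = motion, subject_id = subject_id)
}

#' @rdname write_volume_series
#' @param map A [component_map()].
#' @export
write_component_map <- function(map, path) {
  stopifnot(inherits(map, "component_map"))
  img <- RNifti::asNifti(map$weights)
  RNifti::pixdim(img) <- map$grid$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_series
#' @param label Network label for the map read back.
#' @export
read_component_map <- function(path, label = "C_1") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("read_component_map: expected a 3-D image")
  grid <- scan_grid(dim(arr), voxel_size = RNifti::pixdim(img)[1:3])
  component_map(arr, grid, label = label)
}

#' Write a table as TSV
#'
#' The universal table dialect of this package: tab-separated, header row,
#' UTF-8, `.` decimal separator, no quoting or row names.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Read and write motion-parameter tables
#'
#' Six columns per frame: `x, y, z` translations (mm) and
#' `roll, pitch, yaw` rotations (degrees).
#'
#' @param motion Numeric frames x 6 matrix.
#' @param path TSV path.
#' @export
write_motion <- function(motion, path) {
  write_table(as.data.frame(motion), path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.delim(path, sep = "\t"))
  if (ncol(m) != 6)
    stop("read_motion: expected 6 columns, found ", ncol(m))
  m
}

#' Read a task timing file
#'
#' Timing files are 3-column TSV with header `onset`, `duration`,
#' `condition` (onset and duration in seconds). Malformed rows are reported
#' with their line numbers.
#'
#' @param path TSV path.
#' @param total_duration Run length in seconds; defaults to the end of the
#'   last block.
#' @param contrasts Optional named contrast list passed to [task_design()].
#' @return A [task_design()].
#' @export
read_timing <- function(path, total_duration = NULL, contrasts = list()) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "condition")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("read_timing: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(raw$onset) | !is.finite(raw$duration) |
                 raw$onset < 0 | raw$duration <= 0)
  if (length(bad))
    stop("read_timing: malformed row(s) at line(s) ",
         paste(bad + 1, collapse = ", "),
         " (onset must be >= 0, duration > 0)")
  if (is.null(total_duration))
    total_duration <- max(raw$onset + raw$duration)
  over <- which(raw$onset + raw$duration > total_duration + 1e-9)
  if (length(over))
    stop("read_timing: block(s) at line(s) ", paste(over + 1, collapse = ", "),
         " end after total_duration (", total_duration, " s)")
  task_design(raw[need], contrasts = contrasts,
              total_duration = total_duration)
}

#' @rdname read_timing
#' @param design A [task_design()] to write.
#' @export
write_timing <- function(design, path) {
  stopifnot(inherits(design, "task_design"))
  write_table(design$conditions[c("onset", "duration", "condition")], path)
}

#' Read a subject covariate table
#'
#' Requires `subject_id` and `performance` columns; the nuisance covariates
#' (`age`, `sex`, `education`, `handedness`, `coil`, `session_order`,
#' `mean_trial_duration`) are used by [performance_regression()] when
#' present.
#'
#' @param path TSV path.
#' @return A tibble of subject records.
#' @export
read_covariates <- function(path) {
  tbl <- read_table_tsv(path)
  missing_cols <- setdiff(c("subject_id", "performance"), names(tbl))
  if (length(missing_cols))
    stop("read_covariates: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(tbl$performance)))
    stop("read_covariates: non-finite performance at line(s) ",
         paste(which(!is.finite(tbl$performance)) + 1, collapse = ", "))
  tbl
}
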