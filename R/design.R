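#' Canonical double-gamma hemodynamic response function
#'
#' The BOLD impulse response is modelled as a difference of two gamma
#' densities: a positive lobe peaking at 6 s and an undershoot peaking at
#' 16 s with a 6:1 peak-to-undershoot ratio. The kernel is sampled at the
#' repetition time and normalised to peak amplitude 1, so convolved
#' unit-height boxcars keep interpretable amplitude units.
#'
#' @param tr Sampling interval (repetition time), seconds; must be > 0.
#' @param duration Kernel support in seconds (default 32, after which the
#'   response has decayed to numerical silence).
#' @param peak,undershoot Modes (s) of the response and undershoot lobes.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric vector of kernel samples at times `0, tr, 2*tr, ...`
#'   up to `duration`, with attribute `times`.
#' @export
#' @examples
#' h <- hrf_kernel(tr = 2)
#' max(h)                       # 1 by normalisation
#' attr(h, "times")[which.max(h)]  # peak near 6 s
hrf_kernel <- function(tr, duration = 32, peak = 6, undershoot = 16,
                       ratio = 6) {
  stopifnot(tr > 0, duration > 0, peak > 0, undershoot > peak, ratio > 0)
  times <- seq(0, duration, by = tr)
  # gamma density with rate 1 has mode = shape - 1
  h <- stats::dgamma(times, shape = peak + 1, rate = 1) -
    stats::dgamma(times, shape = undershoot + 1, rate = 1) / ratio
  h <- h / max(h)
  attr(h, "times") <- times
  h
}

# Legendre polynomials P_0..P_order evaluated on n points mapped to [-1, 1];
# the standard slow-drift baseline basis. Returns an n x (order+1) matrix.
legendre_drift <- function(n, order) {
  x <- if (n == 1) 0 else seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2)
    for (k in 2:order)
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
  colnames(P) <- paste0("drift_", 0:order)
  P
}

# sample a condition's boxcar (1 inside blocks) at frame onset times
condition_boxcar <- function(design, label, n_frames, tr) {
  times <- (seq_len(n_frames) - 1) * tr
  rows <- design$conditions[design$conditions$condition == label, ]
  box <- numeric(n_frames)
  for (i in seq_len(nrow(rows)))
    box[times >= rows$onset[i] - 1e-9 &
          times < rows$onset[i] + rows$duration[i] - 1e-9] <- 1
  box
}

# discrete convolution of a frame-sampled regressor with an HRF kernel,
# truncated to n frames (no tr scaling: a single-sample boxcar reproduces
# the kernel samples exactly); direct sum rather than FFT so silent frames
# stay exactly zero
convolve_hrf <- function(box, kernel) {
  n <- length(box)
  out <- numeric(n)
  for (j in which(box != 0)) {
    rng <- j:min(n, j + length(kernel) - 1)
    out[rng] <- out[rng] + box[j] * kernel[seq_along(rng)]
  }
  out
}

#' Build a task GLM design matrix
#'
#' One regressor per condition is formed by convolving its unit-height
#' boxcar with the canonical HRF; the baseline holds Legendre drift
#' polynomials up to `drift_order` (order 0 is the intercept) plus the six
#' rigid-body motion parameters. Column rank is validated on construction.
#'
#' @param design A [task_design()].
#' @param n_frames Number of frames; `n_frames * tr` must cover the design.
#' @param tr Repetition time, seconds.
#' @param motion `n_frames` x 6 motion-parameter matrix (mm / degrees);
#'   columns enter the baseline model.
#' @param drift_order Highest Legendre drift order (default 2).
#' @param kernel Optional HRF kernel (from [hrf_kernel()]); defaults to the
#'   canonical double-gamma at `tr`.
#' @return A `design_matrix` object: the numeric matrix plus labels of task,
#'   baseline columns, contrast weights, and frame times.
#' @export
build_design <- function(design, n_frames, tr, motion,
                         drift_order = 2, kernel = NULL) {
  stopifnot(inherits(design, "task_design"), n_frames >= 1, tr > 0)
  if (n_frames * tr < design$total_duration - 1e-9)
    stop("build_design: run (", n_frames * tr,
         " s) shorter than the task design (", design$total_duration, " s)")
  if (is.null(kernel)) kernel <- hrf_kernel(tr)
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) == n_frames, ncol(motion) == 6)

  task_cols <- vapply(design$condition_labels, function(lab)
    convolve_hrf(condition_boxcar(design, lab, n_frames, tr), kernel),
    numeric(n_frames))
  task_cols <- matrix(task_cols, nrow = n_frames,
                      dimnames = list(NULL, design$condition_labels))

  drift <- legendre_drift(n_frames, drift_order)
  colnames(motion) <- paste0("motion_", c("x", "y", "z", "roll", "pitch", "yaw"))
  X <- cbind(task_cols, drift, motion)

  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop("build_design: design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  structure(list(X = X, task_columns = design$condition_labels,
                 baseline_columns = setdiff(colnames(X),
                                            design$condition_labels),
                 contrasts = design$contrasts,
                 frame_times = (seq_len(n_frames) - 1) * tr, tr = tr),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d frames x %d columns (%d task, %d baseline), %d contrast(s)\n",
              nrow(x$X), ncol(x$X), length(x$task_columns),
              length(x$baseline_columns), length(x$contrasts)))
  invisible(x)
}
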