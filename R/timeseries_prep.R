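#' ROI time-series container
#'
#' Holds one subject's region-of-interest signal matrix (rows = timepoints,
#' columns = regions) together with the region labels and the repetition time.
#'
#' @param data Numeric matrix, timepoints x regions, no missing values.
#' @param region_labels Character vector of unique region names, one per column.
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, region_labels = colnames(data), tr_seconds = 2) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(region_labels)) {
    region_labels <- sprintf("R%03d", seq_len(ncol(data)))
  }
  region_labels <- as.character(region_labels)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("roi_timeseries: data contains missing or non-finite values")
  }
  if (ncol(data) < 2L) stop("roi_timeseries: need at least 2 regions")
  if (nrow(data) < 2L) stop("roi_timeseries: need at least 2 timepoints")
  if (length(region_labels) != ncol(data)) {
    stop("roi_timeseries: region_labels length must equal number of columns")
  }
  if (anyDuplicated(region_labels)) stop("roi_timeseries: region labels must be unique")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("roi_timeseries: tr_seconds must be a positive scalar")
  }
  colnames(data) <- region_labels
  structure(
    list(data = data, region_labels = region_labels, tr_seconds = as.numeric(tr_seconds)),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf(
    "<roi_timeseries> %d timepoints x %d regions, TR = %g s\n",
    nrow(x$data), ncol(x$data), x$tr_seconds
  ))
  invisible(x)
}

#' Head-motion realignment parameters
#'
#' Six-column rigid-body motion trace in the SPM `rp_*.txt` convention:
#' columns 1-3 are translations in mm, columns 4-6 rotations in degrees.
#' Framewise displacement is filled in by [framewise_displacement()].
#'
#' @param data Numeric matrix with exactly 6 columns.
#' @return An object of class `motion_params` with `fd_series`/`mean_fd` unset
#'   (`NULL`) until [framewise_displacement()] is applied.
#' @export
motion_params <- function(data) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) != 6L) stop("motion_params: expected exactly 6 columns")
  if (anyNA(data)) stop("motion_params: missing values")
  colnames(data) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                      "rot_x_deg", "rot_y_deg", "rot_z_deg")
  structure(
    list(data = data, fd_series = NULL, mean_fd = NULL),
    class = "motion_params"
  )
}

#' Drop initial volumes of a time series
#'
#' Removes the first `n_discard` rows, the usual guard against initial
#' magnetisation-equilibration instability of the scanner signal.
#'
#' @param ts A [roi_timeseries()].
#' @param n_discard Number of leading timepoints to drop (default 10).
#' @return A [roi_timeseries()] with `n_discard` fewer rows.
#' @export
discard_initial_volumes <- function(ts, n_discard = 10L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop("n_discard must be >= 0")
  if (n_discard >= nrow(ts$data)) {
    stop("n_discard must be smaller than the number of timepoints")
  }
  if (n_discard == 0L) return(ts)
  out <- ts
  out$data <- ts$data[-seq_len(n_discard), , drop = FALSE]
  out
}

#' Linear detrend and zero-phase bandpass filter
#'
#' Removes each region's linear trend, then applies a 4th-order Butterworth
#' band-pass forward and backward (zero phase) with the given corner
#' frequencies. Defaults retain the 0.01-0.08 Hz band conventionally used for
#' resting-state fluctuations.
#'
#' @param ts A [roi_timeseries()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2*tr_seconds)` (the Nyquist frequency).
#' @return Filtered [roi_timeseries()].
#' @export
detrend_bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf(
      "band (%g, %g) Hz must lie strictly inside (0, Nyquist = %g) Hz",
      low_hz, high_hz, nyq
    ))
  }
  x <- ts$data
  tt <- seq_len(nrow(x))
  # per-column linear detrend
  fit <- stats::lm.fit(cbind(1, tt), x)
  x <- fit$residuals
  bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  for (j in seq_len(ncol(x))) {
    x[, j] <- signal::filtfilt(bf, x[, j])
  }
  out <- ts
  dimnames(x) <- dimnames(ts$data)
  out$data <- x
  out
}

#' Regress confound time courses out of every region
#'
#' Ordinary least-squares regression of each region on an intercept plus the
#' supplied confound columns (e.g. global signal, surrogate white-matter and
#' CSF signals, motion parameters); returns the residuals. Rank-deficient
#' confound matrices are handled by the minimum-norm (pseudoinverse) solution
#' with a warning.
#'
#' @param ts A [roi_timeseries()].
#' @param confounds Numeric matrix with one row per timepoint.
#' @return Residual [roi_timeseries()].
#' @seealso [global_signal()] for the ROI-level global-signal regressor.
#' @export
nuisance_regression <- function(ts, confounds) {
  stopifnot(inherits(ts, "roi_timeseries"))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(ts$data)) {
    stop("confounds must have one row per timepoint")
  }
  if (ncol(confounds) < 1L) stop("need at least one confound column")
  X <- cbind(intercept = 1, confounds)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient confound matrix; using minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% ts$data) / sv$d[pos])
    resid <- ts$data - X %*% coef
  } else {
    resid <- stats::lm.fit(X, ts$data)$residuals
  }
  out <- ts
  dimnames(resid) <- dimnames(ts$data)
  out$data <- resid
  out
}

#' ROI-level global signal
#'
#' The row mean of all region time courses, the ROI-level analogue of the
#' whole-brain mean signal.
#'
#' @param ts A [roi_timeseries()].
#' @return Numeric vector, one value per timepoint.
#' @export
global_signal <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  rowMeans(ts$data)
}

#' Framewise displacement (Power formulation)
#'
#' FD at frame t is the sum of absolute frame-to-frame changes of the three
#' translations plus the three rotations converted to arc length on a sphere
#' of radius `sphere_radius_mm`. The series is padded with a leading 0 so it
#' aligns with the frames; `mean_fd` averages the `T - 1` real displacements.
#'
#' @param mp A [motion_params()].
#' @param sphere_radius_mm Radius of the reference sphere in mm (default 50).
#' @return The [motion_params()] with `fd_series` (mm, length = frames) and
#'   `mean_fd` (mm) filled in.
#' @export
framewise_displacement <- function(mp, sphere_radius_mm = 50) {
  stopifnot(inherits(mp, "motion_params"))
  if (nrow(mp$data) < 2L) stop("need at least 2 frames")
  d <- diff(mp$data)
  trans <- rowSums(abs(d[, 1:3, drop = FALSE]))
  rot <- rowSums(abs(d[, 4:6, drop = FALSE]) * pi / 180 * sphere_radius_mm)
  fd <- trans + rot
  mp$fd_series <- c(0, fd)
  mp$mean_fd <- mean(fd)
  mp
}

#' Head-motion exclusion rule
#'
#' A subject is excluded when any frame's absolute realignment parameter
#' exceeds the translation threshold in any axis or the rotation threshold
#' about any axis (strict inequality: a value exactly at the threshold is
#' kept).
#'
#' @param mp A [motion_params()].
#' @param max_translation_mm Translation limit in mm (default 1.0).
#' @param max_rotation_deg Rotation limit in degrees (default 1.0).
#' @return `TRUE` if the subject should be excluded, else `FALSE`.
#' @export
motion_exclusion <- function(mp, max_translation_mm = 1.0, max_rotation_deg = 1.0) {
  stopifnot(inherits(mp, "motion_params"))
  any(abs(mp$data[, 1:3]) > max_translation_mm) ||
    any(abs(mp$data[, 4:6]) > max_rotation_deg)
}
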