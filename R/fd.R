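#' Framewise displacement from realignment estimates
#'
#' Computes per-frame framewise displacement (FD) from a six-parameter
#' rigid-body realignment trace. The realignment estimates are first
#' low-pass filtered (zero-phase, 2nd-order Butterworth) to remove
#' high-frequency noise such as respiration-linked pseudo-motion; FD is then
#' the sum of absolute frame-to-frame differences of the three translations
#' plus the three rotations converted to millimeters of arc on a sphere of
#' radius `rotation_radius_mm`. The first frame of a run has FD 0 by
#' convention.
#'
#' @param trace Data frame or matrix with six columns: translations
#'   `trans_x`, `trans_y`, `trans_z` (mm) then rotations `rot_x`, `rot_y`,
#'   `rot_z` (radians). Column order is used if names are absent.
#' @param rotation_radius_mm Sphere radius for the rotation-to-mm
#'   conversion; 50 mm is the standard convention.
#' @param lowpass_hz Low-pass cutoff applied to the realignment estimates
#'   before differencing; `NULL` disables filtering (raw FD).
#' @param tr Sampling interval, seconds.
#' @return Numeric FD vector (mm), one value per frame; attribute
#'   `filtered` records whether filtering was applied.
#' @examples
#' tr <- as.data.frame(matrix(0, 10, 6))
#' tr[5:10, 1] <- 0.2  # a 0.2 mm x-translation step
#' compute_fd(tr, lowpass_hz = NULL)
#' @export
compute_fd <- function(trace, rotation_radius_mm = 50, lowpass_hz = 0.1,
                       tr = 1.0) {
  m <- as.matrix(trace)
  if (nrow(m) < 2)
    stop("degenerate motion trace: need at least 2 frames", call. = FALSE)
  stopifnot(ncol(m) == 6, all(is.finite(m)), rotation_radius_mm > 0)
  if (!is.null(lowpass_hz)) {
    nyq <- 0.5 / tr
    stopifnot(lowpass_hz > 0, lowpass_hz < nyq)
    bf <- signal::butter(2, lowpass_hz / nyq, type = "low")
    m <- apply(m, 2, function(x) signal::filtfilt(bf, x))
  }
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  attr(fd, "filtered") <- !is.null(lowpass_hz)
  fd
}

#' Root-mean-square framewise displacement
#'
#' Per-subject motion summary: `sqrt(mean(FD^2))` over all frames of the
#' included runs (set `frames` to restrict to retained frames).
#'
#' @param fd FD vector, or list of per-run FD vectors.
#' @param frames Optional logical mask (or list of masks) selecting the
#'   frames to summarize; default all frames.
#' @return RMS FD in mm.
#' @export
fd_summary <- function(fd, frames = NULL) {
  if (is.list(fd)) fd <- unlist(fd, use.names = FALSE)
  if (!is.null(frames)) {
    if (is.list(frames)) frames <- unlist(frames, use.names = FALSE)
    fd <- fd[frames]
  }
  stopifnot(length(fd) >= 1)
  sqrt(mean(fd^2))
}
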