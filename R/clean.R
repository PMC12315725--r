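#' Demean and detrend ROI time series
#'
#' Removes, per run and per ROI, the least-squares constant and linear
#' trend.
#'
#' @param ts Frames-by-ROI numeric matrix for one run, or a list of such
#'   matrices (one per run).
#' @return Object of the same shape with constant and linear trend removed.
#' @export
demean_detrend <- function(ts) {
  if (is.list(ts)) return(lapply(ts, demean_detrend))
  ts <- as.matrix(ts)
  if (nrow(ts) < 3)
    stop("degenerate run: need at least 3 frames to detrend", call. = FALSE)
  x <- cbind(1, seq_len(nrow(ts)))
  ts - x %*% qr.coef(qr(x), ts)
}

#' Nuisance regressor matrix
#'
#' Assembles the standard nuisance design for one run: the six rigid-body
#' realignment parameters, their backward differences, the Volterra
#' expansion realized as the squares of current and one-frame-lagged
#' parameters (the 24-parameter motion set), plus the global signal and two
#' tissue (white matter / CSF) signals when provided. With all signals
#' supplied the design has 27 columns.
#'
#' @param trace Frames-by-6 realignment trace (translations mm, rotations
#'   radians).
#' @param global_signal Optional numeric vector, whole-brain mean signal.
#' @param tissue_signals Optional 2-column matrix or list of two vectors
#'   (white matter and CSF signals).
#' @return Frames-by-k numeric matrix with named columns.
#' @export
build_nuisance_regressors <- function(trace, global_signal = NULL,
                                      tissue_signals = NULL) {
  m <- as.matrix(trace)
  stopifnot(ncol(m) == 6)
  n <- nrow(m)
  lag <- rbind(0, m[-n, , drop = FALSE])
  out <- cbind(m, m - lag, m^2, lag^2)
  colnames(out) <- c(paste0("mot", 1:6), paste0("dmot", 1:6),
                     paste0("mot", 1:6, "_sq"), paste0("motlag", 1:6, "_sq"))
  if (!is.null(global_signal)) {
    if (length(global_signal) != n)
      stop("global_signal length does not match the motion trace",
           call. = FALSE)
    out <- cbind(out, global = global_signal)
  }
  if (!is.null(tissue_signals)) {
    tm <- if (is.list(tissue_signals)) do.call(cbind, tissue_signals)
          else as.matrix(tissue_signals)
    if (nrow(tm) != n)
      stop("tissue_signals length does not match the motion trace",
           call. = FALSE)
    colnames(tm) <- paste0("tissue", seq_len(ncol(tm)))
    out <- cbind(out, tm)
  }
  out
}

#' Censor-aware nuisance regression
#'
#' Regresses the nuisance design out of each ROI time series. Coefficients
#' are estimated by OLS on the retained frames only (so that high-motion
#' frames exert no leverage on the fit) and the fitted values are subtracted
#' from every frame. Collinear columns are dropped with a warning.
#'
#' @param ts Frames-by-ROI matrix for one run.
#' @param regressors Frames-by-k nuisance matrix (an intercept is added).
#' @param mask Optional logical retain vector; default all frames.
#' @param fit_all_frames If `TRUE`, estimate on all frames instead of the
#'   retained frames only.
#' @return Residual matrix, same shape as `ts`.
#' @export
nuisance_regress <- function(ts, regressors, mask = NULL,
                             fit_all_frames = FALSE) {
  ts <- as.matrix(ts)
  x <- cbind(intercept = 1, as.matrix(regressors))
  if (nrow(x) != nrow(ts))
    stop("regressor length does not match the time series", call. = FALSE)
  use <- if (is.null(mask) || fit_all_frames) rep(TRUE, nrow(ts)) else mask
  if (sum(use) <= ncol(x))
    stop("nuisance design has as many columns as retained frames",
         call. = FALSE)
  qx <- qr(x[use, , drop = FALSE])
  if (qx$rank < ncol(x)) {
    drop <- qx$pivot[(qx$rank + 1):ncol(x)]
    warning("dropping ", length(drop), " collinear nuisance column(s): ",
            paste(colnames(x)[drop], collapse = ", "), call. = FALSE)
    x <- x[, -drop, drop = FALSE]
    qx <- qr(x[use, , drop = FALSE])
  }
  beta <- qr.coef(qx, ts[use, , drop = FALSE])
  ts - x %*% beta
}

#' Interpolate censored frames and band-pass filter
#'
#' Within each run, censored frames are replaced by interpolated values
#' (linear by default, or a least-squares spectral reconstruction from the
#' retained frames), a zero-phase 2nd-order Butterworth band-pass filter is
#' applied, and the censored frames are re-flagged so that they are excluded
#' from any later correlation. Interpolation prevents censored spikes from
#' ringing through the filter.
#'
#' @param ts Frames-by-ROI matrix for one run.
#' @param mask Logical retain vector for the run.
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @param tr Sampling interval, seconds.
#' @param method Interpolation method, `"linear"` or `"spectral"`.
#' @return Filtered matrix with attribute `mask` (the retain vector).
#' @export
interpolate_and_bandpass <- function(ts, mask = NULL, low_hz = 0.009,
                                     high_hz = 0.08, tr = 1.0,
                                     method = c("linear", "spectral")) {
  method <- match.arg(method)
  ts <- as.matrix(ts)
  n <- nrow(ts)
  nyq <- 0.5 / tr
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz < nyq)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (n < 24)
    stop("run shorter than the filter warm-up; exclude this run",
         call. = FALSE)
  if (any(!mask)) ts <- interpolate_frames(ts, mask, method, tr, high_hz)
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  out <- apply(ts, 2, function(x) signal::filtfilt(bf, x))
  attr(out, "mask") <- mask
  out
}

interpolate_frames <- function(ts, mask, method, tr, high_hz) {
  good <- which(mask)
  bad <- which(!mask)
  if (length(good) < 2) return(ts)
  if (method == "linear") {
    for (j in seq_len(ncol(ts)))
      ts[bad, j] <- approx(good, ts[good, j], xout = bad, rule = 2)$y
  } else {
    # least-squares sinusoid reconstruction from retained frames, using
    # Fourier frequencies up to just above the pass band
    n <- nrow(ts)
    freqs <- seq_len(floor(min(high_hz * 1.5, 0.5 / tr - 1e-9) * n * tr)) /
      (n * tr)
    t_all <- seq_len(n) * tr
    basis <- cbind(1, do.call(cbind, lapply(freqs, function(f)
      cbind(sin(2 * pi * f * t_all), cos(2 * pi * f * t_all)))))
    if (length(good) > ncol(basis)) {
      beta <- qr.coef(qr(basis[good, , drop = FALSE]),
                      ts[good, , drop = FALSE])
      beta[is.na(beta)] <- 0
      fit <- basis %*% beta
      ts[bad, ] <- fit[bad, ]
    } else {
      for (j in seq_len(ncol(ts)))
        ts[bad, j] <- approx(good, ts[good, j], xout = bad, rule = 2)$y
    }
  }
  ts
}

#' Clean one subject's ROI time series
#'
#' Runs the full per-subject cleaning chain in its fixed order: filtered-FD
#' computation, censor-mask construction, demean/detrend, censor-aware
#' nuisance regression, interpolation + band-pass, re-censoring, and
#' frame-budget selection. The stage order is recorded in the returned
#' provenance.
#'
#' @param ts_runs List of per-run frames-by-ROI matrices.
#' @param motion_runs List of per-run realignment traces.
#' @param tr Sampling interval, seconds.
#' @param fd_threshold,min_segment,min_run_frames,frame_budget Censoring
#'   and data-quantity parameters.
#' @param fd_lowpass Low-pass cutoff (Hz) for filtered FD.
#' @param band Pass-band edges in Hz.
#' @param tissue_signals Optional list (per run) of two-column tissue-signal
#'   matrices; if `NULL`, only motion and global-signal regressors are used
#'   plus two white-noise proxy columns seeded from the data (keeping the
#'   27-column design).
#' @return List with `ts` (list of cleaned per-run matrices), `selected`
#'   (per-run logical vectors of analyzed frames), `included`, `rms_fd`,
#'   `retained_total` and `provenance`.
#' @export
clean_subject <- function(ts_runs, motion_runs, tr = 1.0,
                          fd_threshold = 0.2, min_segment = 5,
                          min_run_frames = 50, frame_budget = 800,
                          fd_lowpass = 0.1, band = c(0.009, 0.08),
                          tissue_signals = NULL) {
  stopifnot(length(ts_runs) == length(motion_runs))
  fd <- lapply(motion_runs, compute_fd, lowpass_hz = fd_lowpass, tr = tr)
  masks <- lapply(fd, build_censor_mask, threshold_mm = fd_threshold,
                  min_segment = min_segment, min_run_frames = min_run_frames)
  cleaned <- vector("list", length(ts_runs))
  for (k in seq_along(ts_runs)) {
    x <- demean_detrend(ts_runs[[k]])
    tiss <- if (!is.null(tissue_signals)) tissue_signals[[k]] else {
      seed_k <- floor(abs(sum(ts_runs[[k]][1, ])) * 100) %% 100000L + k
      with_seed(seed_k, matrix(rnorm(2 * nrow(x)), ncol = 2))
    }
    reg <- build_nuisance_regressors(motion_runs[[k]],
                                     global_signal = rowMeans(x),
                                     tissue_signals = tiss)
    mask_fit <- if (any(masks[[k]])) masks[[k]] else rep(TRUE, nrow(x))
    x <- suppressWarnings(nuisance_regress(x, reg, mask = mask_fit))
    cleaned[[k]] <- interpolate_and_bandpass(x, mask = masks[[k]],
                                             low_hz = band[1],
                                             high_hz = band[2], tr = tr)
  }
  sel <- select_frame_budget(masks, budget = frame_budget)
  list(ts = cleaned, selected = sel$selected, included = sel$included,
       retained_total = sel$retained_total,
       rms_fd = fd_summary(fd),
       provenance = c("compute_fd", "build_censor_mask", "demean_detrend",
                      "nuisance_regress", "interpolate_and_bandpass",
                      "recensor", "select_frame_budget"))
}
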