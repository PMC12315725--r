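#' ROI-by-ROI Pearson correlation matrix
#'
#' Correlates every pair of ROI time series over the selected
#' (non-censored, within-budget) frames, concatenated across runs.
#'
#' @param ts Frames-by-ROI matrix, or list of per-run matrices.
#' @param frames Optional logical vector (or list of per-run vectors)
#'   selecting the frames to use.
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   ROIs yield `NA` rows/columns with a warning.
#' @export
correlate <- function(ts, frames = NULL) {
  if (is.list(ts)) {
    if (!is.null(frames)) {
      stopifnot(is.list(frames), length(frames) == length(ts))
      ts <- mapply(function(x, f) as.matrix(x)[f, , drop = FALSE],
                   ts, frames, SIMPLIFY = FALSE)
    }
    ts <- do.call(rbind, lapply(ts, as.matrix))
  } else {
    ts <- as.matrix(ts)
    if (!is.null(frames)) ts <- ts[frames, , drop = FALSE]
  }
  if (nrow(ts) < 3)
    stop("need at least 3 selected frames to correlate", call. = FALSE)
  if (ncol(ts) < 2)
    stop("need at least 2 ROIs to correlate", call. = FALSE)
  v <- apply(ts, 2, var)
  if (any(v == 0))
    warning(sum(v == 0), " zero-variance ROI(s); their correlations are NA",
            call. = FALSE)
  suppressWarnings(cor(ts))
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies `atanh` elementwise to the off-diagonal entries, clipping
#' `|r|` to `1 - 1e-7` beforehand so that duplicated ROIs do not produce
#' infinities. The diagonal is excluded (set to `NA`).
#'
#' @param r Correlation matrix.
#' @return Matrix of Fisher-z values with `NA` diagonal.
#' @export
fisher_z <- function(r) {
  r <- as.matrix(r)
  z <- atanh(pmax(pmin(r, 1 - 1e-7), -(1 - 1e-7)))
  diag(z) <- NA_real_
  z
}

#' Zero out negative connectivity values
#'
#' Replaces negative entries by zero, leaving positive entries untouched.
#' Global-signal regression can introduce spurious negative correlations,
#' so segregation and connectivity averages are computed over non-negative
#' entries only.
#'
#' @param z Fisher-z connectivity matrix.
#' @return Thresholded matrix (idempotent).
#' @export
threshold_negative <- function(z) {
  z <- as.matrix(z)
  z[!is.na(z) & z < 0] <- 0
  z
}
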