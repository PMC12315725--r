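#' Motion censoring mask for one run
#'
#' Retains frames with FD at or below the censoring threshold, then removes
#' every maximal retained segment shorter than `min_segment` contiguous
#' frames, and finally discards the whole run if fewer than `min_run_frames`
#' frames survive. The contiguity rule is applied within runs only, never
#' across run boundaries.
#'
#' @param fd FD vector (mm) for one run.
#' @param threshold_mm Censor frames with FD strictly greater than this.
#' @param min_segment Minimum length of a retained contiguous segment.
#' @param min_run_frames Minimum retained frames for the run to survive.
#' @return Logical retain vector, one element per frame, with attribute
#'   `retained_count`.
#' @examples
#' build_censor_mask(c(0, 0, 0.3, 0, 0, 0, 0))  # both segments < 5: all FALSE
#' @export
build_censor_mask <- function(fd, threshold_mm = 0.2, min_segment = 5,
                              min_run_frames = 50) {
  stopifnot(all(is.finite(fd)), threshold_mm > 0)
  retain <- fd <= threshold_mm
  r <- rle(retain)
  r$values[r$values & r$lengths < min_segment] <- FALSE
  retain <- inverse.rle(r)
  if (sum(retain) < min_run_frames) retain[] <- FALSE
  attr(retain, "retained_count") <- sum(retain)
  retain
}

#' Select the per-subject frame budget
#'
#' Applies the data-quantity rule: a subject is included only with at least
#' `budget` retained frames in total, and the earliest `budget` retained
#' frames in acquisition order (across runs in run order) are selected;
#' all later frames are discarded. Matching the analyzed frame count across
#' subjects prevents data quantity from biasing network measures.
#'
#' @param masks List of per-run logical retain vectors (or a single vector).
#' @param budget Number of frames to select.
#' @return List with `included` (logical), `selected` (list of per-run
#'   logical vectors marking the selected frames) and `retained_total`.
#' @examples
#' m <- list(rep(TRUE, 500), rep(TRUE, 600))
#' sel <- select_frame_budget(m, budget = 800)
#' sum(sel$selected[[2]])  # first 300 retained frames of run 2
#' @export
select_frame_budget <- function(masks, budget = 800) {
  if (!is.list(masks)) masks <- list(masks)
  total <- sum(vapply(masks, sum, 0L))
  selected <- lapply(masks, function(m) m & FALSE)
  if (total < budget)
    return(list(included = FALSE, selected = selected,
                retained_total = total))
  left <- budget
  for (k in seq_along(masks)) {
    idx <- which(masks[[k]])
    take <- utils::head(idx, left)
    selected[[k]][take] <- TRUE
    left <- left - length(take)
    if (left == 0) break
  }
  list(included = TRUE, selected = selected, retained_total = total)
}
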