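#' Write a cohort bundle to disk
#'
#' Lays out a generated cohort as plain-text files: `subjects.tsv` (the
#' `true_*` columns are planted ground truth, not observables),
#' `parcellation.tsv`, `trials/<id>.csv`, `motion/<id>_run<k>.tsv` and
#' `timeseries/<id>_run<k>.tsv`.
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  for (d in file.path(dir, c("", "trials", "motion", "timeseries")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(x, path)
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(bundle$subjects, file.path(dir, "subjects.tsv"))
  write_tsv(bundle$parcellation, file.path(dir, "parcellation.tsv"))
  for (id in bundle$subjects$subject_id) {
    write.csv(bundle$trials[[id]], file.path(dir, "trials",
                                             paste0(id, ".csv")),
              row.names = FALSE, quote = FALSE)
    for (k in seq_along(bundle$motion[[id]]))
      write_tsv(bundle$motion[[id]][[k]],
                file.path(dir, "motion", sprintf("%s_run%d.tsv", id, k)))
    if (!is.null(bundle$timeseries[[id]]))
      for (k in seq_along(bundle$timeseries[[id]]))
        write_tsv(round(bundle$timeseries[[id]][[k]], 4),
                  file.path(dir, "timeseries",
                            sprintf("%s_run%d.tsv", id, k)))
  }
  invisible(dir)
}

#' Read a parcellation table
#'
#' @param path TSV with columns `roi_id`, `network` (and optionally
#'   coordinates `x`, `y`, `z`).
#' @return Data frame.
#' @export
read_parcellation <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("roi_id", "network") %in% names(p)))
  p
}

#' Read per-subject motion traces from a cohort directory
#'
#' @param dir Cohort directory containing `motion/<id>_run<k>.tsv`.
#' @param subject_id Subject identifier.
#' @return List of per-run motion data frames, ordered by run number.
#' @export
read_motion <- function(dir, subject_id) {
  files <- sort(list.files(file.path(dir, "motion"),
                           pattern = paste0("^", subject_id, "_run\\d+\\.tsv$"),
                           full.names = TRUE))
  if (!length(files)) stop("no motion traces for ", subject_id, call. = FALSE)
  lapply(files, read.delim, stringsAsFactors = FALSE)
}

#' Read per-subject ROI time series from a cohort directory
#'
#' @inheritParams read_motion
#' @return List of per-run numeric matrices (frames x ROIs).
#' @export
read_timeseries <- function(dir, subject_id) {
  files <- sort(list.files(file.path(dir, "timeseries"),
                           pattern = paste0("^", subject_id, "_run\\d+\\.tsv$"),
                           full.names = TRUE))
  if (!length(files)) stop("no time series for ", subject_id, call. = FALSE)
  lapply(files, function(f) as.matrix(read.delim(f)))
}

#' Read trial tables from a cohort directory
#'
#' @param dir Cohort directory containing `trials/<id>.csv`.
#' @return Named list of trial tables keyed by subject id.
#' @export
read_trials <- function(dir) {
  files <- list.files(file.path(dir, "trials"), pattern = "\\.csv$",
                      full.names = TRUE)
  out <- lapply(files, read.csv, stringsAsFactors = FALSE)
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}
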