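#' Accuracy on clearly valenced trials
#'
#' Fraction of clearly valenced (control) trials answered correctly: a
#' `clear_positive` trial is correct when the response is `"positive"`, a
#' `clear_negative` trial when it is `"negative"`. Trials without a response
#' (`"none"`) are excluded from both numerator and denominator. Participants
#' below 60% accuracy fail the behavioral inclusion rule.
#'
#' @param trials Trial table with columns `valence_class`
#'   (`ambiguous`/`clear_positive`/`clear_negative`) and `response`
#'   (`positive`/`negative`/`none`).
#' @return Fraction correct in `[0, 1]`.
#' @seealso [compute_valence_bias()], [score_behavior()]
#' @export
score_clear_accuracy <- function(trials) {
  check_trials(trials)
  clear <- trials[trials$valence_class != "ambiguous" &
                    trials$response != "none", ]
  if (nrow(clear) == 0)
    stop("undefined clear-trial accuracy: no answered clearly valenced trials",
         call. = FALSE)
  expected <- ifelse(clear$valence_class == "clear_positive",
                     "positive", "negative")
  mean(clear$response == expected)
}

#' Valence bias score
#'
#' Valence bias is the percentage of ambiguous trials (surprised faces and
#' ambiguous scenes pooled) categorized as positive: `100 * positives /
#' answered ambiguous trials`. Trials with no response are excluded.
#'
#' @inheritParams score_clear_accuracy
#' @return Percent positive in `[0, 100]`.
#' @examples
#' tt <- data.frame(valence_class = rep("ambiguous", 48),
#'                  response = rep(c("positive", "negative"), c(25, 23)))
#' compute_valence_bias(tt)  # 52.083
#' @export
compute_valence_bias <- function(trials) {
  check_trials(trials)
  amb <- trials[trials$valence_class == "ambiguous" &
                  trials$response != "none", ]
  if (nrow(amb) == 0)
    stop("undefined valence bias: no answered ambiguous trials",
         call. = FALSE)
  100 * mean(amb$response == "positive")
}

#' Score a set of trial tables and apply the inclusion rule
#'
#' @param trials A single trial table, or a named list of trial tables
#'   (names taken as subject ids).
#' @param accuracy_cutoff Minimum clear-trial accuracy for inclusion
#'   (inclusive; accuracy below the cutoff excludes the subject).
#' @return Data frame with `subject_id`, `valence_bias`, `clear_accuracy`
#'   and logical `included`.
#' @export
score_behavior <- function(trials, accuracy_cutoff = 0.60) {
  if (is.data.frame(trials)) trials <- list(subject = trials)
  ids <- names(trials) %||% sprintf("sub%03d", seq_along(trials))
  out <- data.frame(
    subject_id = ids,
    valence_bias = vapply(trials, compute_valence_bias, 0),
    clear_accuracy = vapply(trials, score_clear_accuracy, 0),
    stringsAsFactors = FALSE)
  out$included <- out$clear_accuracy >= accuracy_cutoff
  rownames(out) <- NULL
  out
}

check_trials <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("valence_class", "response") %in% names(trials)))
  bad <- setdiff(unique(trials$valence_class),
                 c("ambiguous", "clear_positive", "clear_negative"))
  if (length(bad))
    stop("unknown valence_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(trials$response), c("positive", "negative", "none"))
  if (length(bad))
    stop("unknown response value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(trials)
}
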