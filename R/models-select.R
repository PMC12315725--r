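#' AIC backward elimination with forced covariates
#'
#' Starting from the full model, repeatedly removes the candidate predictor
#' whose removal yields the largest AIC decrease, stopping when no removal
#' decreases the AIC. Forced covariates are never candidates for removal.
#' Ties in AIC decrease are broken lexicographically by term name, so the
#' trace is deterministic. An optional change-in-estimate guard retains a
#' candidate whose removal would change any remaining coefficient by more
#' than `guard_threshold` (proportionally), approximating augmented
#' backward elimination.
#'
#' @param data Data frame containing the response, candidates and forced
#'   covariates.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor columns
#'   (e.g. the 11 DMN pairwise connectivities).
#' @param forced Character vector of forced covariate columns (e.g.
#'   standardized age).
#' @param guard_cie Enable the change-in-estimate guard.
#' @param guard_threshold Proportional coefficient-change threshold for the
#'   guard.
#' @return List with `fit` (final `ls_fit`), `selected` (surviving
#'   candidates) and `trace` (data frame: `step`, `removed`, `aic_before`,
#'   `aic_after`).
#' @export
backward_eliminate <- function(data, response, candidates, forced,
                               guard_cie = FALSE, guard_threshold = 0.2) {
  stopifnot(all(c(response, candidates, forced) %in% names(data)))
  current <- sort(candidates)
  fit_with <- function(terms) {
    rhs <- paste(c(forced, terms, "1"), collapse = " + ")
    fit_ols(stats::as.formula(paste(response, "~", rhs)), data)
  }
  fit <- fit_with(current)
  trace <- data.frame(step = integer(), removed = character(),
                      aic_before = numeric(), aic_after = numeric(),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (!length(current)) break
    aics <- vapply(current, function(tm) fit_with(setdiff(current, tm))$aic,
                   0)
    best <- names(aics)[order(aics, names(aics))][1]
    if (aics[best] >= fit$aic) break
    cand_fit <- fit_with(setdiff(current, best))
    if (guard_cie) {
      common <- intersect(fit$coefficients$term, cand_fit$coefficients$term)
      common <- setdiff(common, "(Intercept)")
      b_old <- fit$coefficients$B[match(common, fit$coefficients$term)]
      b_new <- cand_fit$coefficients$B[match(common,
                                             cand_fit$coefficients$term)]
      rel <- abs(b_new - b_old) / pmax(abs(b_old), 1e-12)
      if (any(rel > guard_threshold)) {
        # removal distorts remaining estimates: retain this candidate and
        # stop (no other removal decreases AIC more)
        break
      }
    }
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = best,
                                     aic_before = fit$aic,
                                     aic_after = aics[best],
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, best)
    fit <- cand_fit
  }
  rownames(trace) <- NULL
  list(fit = fit, selected = current, trace = trace)
}

#' Screen age interactions for the selected predictors
#'
#' Tests standardized age as a moderator of each selected predictor: each
#' `term x age_z` interaction is added one at a time to the main-effects
#' model, and the interactions significant at `alpha` are then retained
#' jointly in the final model.
#'
#' @param data Data frame with the response, predictors and `age_z`.
#' @param response Response column name.
#' @param selected Character vector of selected predictor columns.
#' @param moderator Moderator column name (default `"age_z"`).
#' @param alpha Significance level for retaining an interaction.
#' @return List with `fit` (final `ls_fit` including the retained
#'   interactions), `interactions` (retained interaction labels) and
#'   `screen` (data frame of per-interaction p-values).
#' @export
screen_interactions <- function(data, response, selected,
                                moderator = "age_z", alpha = 0.05) {
  stopifnot(all(c(response, selected, moderator) %in% names(data)))
  main_rhs <- paste(c(moderator, selected), collapse = " + ")
  pvals <- vapply(selected, function(tm) {
    f <- stats::as.formula(paste(response, "~", main_rhs, "+",
                                 tm, ":", moderator))
    fit <- fit_ols(f, data)
    lbl <- paste0(moderator, ":", tm)
    alt <- paste0(tm, ":", moderator)
    hit <- fit$coefficients$term %in% c(lbl, alt)
    fit$coefficients$p[hit][1]
  }, 0)
  keep <- selected[pvals < alpha]
  rhs <- paste(c(moderator, selected,
                 if (length(keep)) paste0(keep, ":", moderator)),
               collapse = " + ")
  fit <- fit_ols(stats::as.formula(paste(response, "~", rhs)), data)
  list(fit = fit,
       interactions = if (length(keep)) paste0(keep, ":", moderator)
                      else character(),
       screen = data.frame(term = selected, p_interaction = unname(pvals),
                           retained = selected %in% keep,
                           stringsAsFactors = FALSE))
}
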