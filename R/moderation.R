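#' Simple slopes of a moderated effect
#'
#' Conditional effect of a focal predictor at chosen moderator values:
#' `slope(a) = B_focal + B_interaction * a` with
#' `SE(a) = sqrt(V_focal + a^2 * V_int + 2 a * Cov)`, tested against the
#' t distribution with the fit's residual degrees of freedom. At `a = 0`
#' the slope and SE equal the focal term's own coefficient and SE.
#'
#' @param fit An `ls_fit` containing the focal and interaction terms.
#' @param focal Focal term name.
#' @param interaction Interaction term name.
#' @param at Moderator values, default one SD below, at, and above the
#'   mean (-1, 0, 1).
#' @return Data frame with `at`, `slope`, `SE`, `t`, `p`.
#' @examples
#' f <- fit_from_coefs(c("reward", "reward:age"), c(-6.435, -9.029),
#'                     c(4.311, 4.218), df_residual = 215)
#' simple_slopes(f, "reward", "reward:age")
#' @export
simple_slopes <- function(fit, focal, interaction, at = c(-1, 0, 1)) {
  cf <- moderation_coefs(fit, focal, interaction)
  slope <- cf$bf + cf$bi * at
  se <- sqrt(pmax(0, cf$vf + at^2 * cf$vi + 2 * at * cf$cv))
  t <- slope / se
  data.frame(at = at, slope = slope, SE = se, t = t,
             p = 2 * pt(abs(t), fit$df.residual, lower.tail = FALSE))
}

#' Johnson-Neyman interval for a moderated effect
#'
#' Finds the moderator values at which the conditional slope of the focal
#' predictor is exactly significant at `alpha`: the boundaries solve
#' `(B_focal + B_int a)^2 = t_crit^2 (V_focal + a^2 V_int + 2 a Cov)` via
#' the quadratic formula. With no real roots, the slope is significant
#' everywhere or nowhere, decided by the test at `a = 0`. When a moderator
#' scale is supplied, boundaries are also reported in raw units (years).
#'
#' @inheritParams simple_slopes
#' @param alpha Two-sided significance level.
#' @param scale Optional list with `mean` and `sd` (years) mapping
#'   standardized moderator values to ages.
#' @return List of class `jn_result`: `boundaries` (standardized),
#'   `boundaries_raw` (years, if `scale` given), `t_crit`, `df`, `region`
#'   (`"above"`, `"below"`, `"outside"`, `"between"`, `"everywhere"` or
#'   `"nowhere"`) describing where the slope is significant, and `slopes`
#'   (simple slopes at the boundaries).
#' @export
johnson_neyman <- function(fit, focal, interaction, alpha = 0.05,
                           scale = NULL) {
  cf <- moderation_coefs(fit, focal, interaction)
  df <- fit$df.residual
  tc <- qt(1 - alpha / 2, df)
  # quadratic in a: (bi^2 - tc^2 vi) a^2 + 2 (bf bi - tc^2 cv) a +
  #                 (bf^2 - tc^2 vf) = 0
  A <- cf$bi^2 - tc^2 * cf$vi
  B <- 2 * (cf$bf * cf$bi - tc^2 * cf$cv)
  C <- cf$bf^2 - tc^2 * cf$vf
  sig_at <- function(a) {
    s <- simple_slopes(fit, focal, interaction, at = a)
    abs(s$t) >= tc
  }
  ref <- abs(cf$bf) + sqrt(cf$vf)
  degenerate <- abs(cf$bi) < 1e-8 * max(1, ref) &&
    sqrt(cf$vi) < 1e-8 * max(1, ref)
  roots <- numeric(0)
  if (!degenerate && abs(A) > 1e-300) {
    disc <- B^2 - 4 * A * C
    if (disc >= 0) roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  } else if (!degenerate && abs(B) > 1e-300) {
    roots <- -C / B
  }
  region <- if (degenerate) {
    if (sig_at(0)) "everywhere" else "nowhere"
  } else if (length(roots) == 0) {
    if (sig_at(0)) "everywhere" else "nowhere"
  } else if (length(roots) == 1) {
    if (sig_at(roots + 1)) "above" else "below"
  } else {
    mid <- mean(roots)
    if (sig_at(mid)) "between" else "outside"
  }
  out <- list(boundaries = roots,
              boundaries_raw = if (!is.null(scale) && length(roots))
                unstandardize_age(roots, scale) else NULL,
              t_crit = tc, df = df, alpha = alpha, region = region,
              slopes = if (length(roots))
                simple_slopes(fit, focal, interaction, at = roots)
              else NULL)
  class(out) <- "jn_result"
  out
}

#' @export
print.jn_result <- function(x, ...) {
  cat("<Johnson-Neyman>\n")
  if (length(x$boundaries)) {
    cat(sprintf("  boundaries (standardized): %s\n",
                paste(round(x$boundaries, 4), collapse = ", ")))
    if (!is.null(x$boundaries_raw))
      cat(sprintf("  boundaries (years): %s\n",
                  paste(round(x$boundaries_raw, 2), collapse = ", ")))
  }
  cat(sprintf("  slope significant (alpha = %g): %s\n", x$alpha, x$region))
  invisible(x)
}

moderation_coefs <- function(fit, focal, interaction) {
  terms <- fit$coefficients$term
  alt <- function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2) paste(rev(parts), collapse = ":") else tm
  }
  find <- function(tm) {
    i <- match(tm, terms)
    if (is.na(i)) i <- match(alt(tm), terms)
    if (is.na(i)) stop("term not in fit: ", tm, call. = FALSE)
    i
  }
  i_f <- find(focal); i_i <- find(interaction)
  v <- fit$vcov
  if (is.null(v)) stop("fit has no coefficient covariance", call. = FALSE)
  list(bf = fit$coefficients$B[i_f], bi = fit$coefficients$B[i_i],
       vf = v[i_f, i_f], vi = v[i_i, i_i], cv = v[i_f, i_i])
}
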