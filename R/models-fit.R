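#' Ordinary least-squares fit with a tidy coefficient table
#'
#' Thin wrapper around [stats::lm()] returning a `ls_fit`: the coefficient
#' table (B, SE, t, p), the coefficient covariance matrix, the overall
#' F-statistic with its degrees of freedom, R-squared, AIC and sample size.
#' All downstream model operations (simple slopes, Johnson-Neyman,
#' elimination traces) consume this container.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @return Object of class `ls_fit`.
#' @export
fit_ols <- function(formula, data) {
  n <- nrow(data)
  mf <- stats::model.frame(formula, data)
  k <- ncol(stats::model.matrix(formula, mf))
  if (n <= k + 2)
    stop(sprintf("refusing to fit: n = %d with %d terms (need n > terms + 2)",
                 n, k), call. = FALSE)
  m <- lm(formula, data = data)
  if (any(is.na(coef(m))))
    stop("rank-deficient design: ",
         paste(names(coef(m))[is.na(coef(m))], collapse = ", "),
         call. = FALSE)
  s <- summary(m)
  ct <- s$coefficients
  fs <- s$fstatistic
  out <- list(
    model = m,
    terms = rownames(ct),
    coefficients = data.frame(term = rownames(ct), B = ct[, 1],
                              SE = ct[, 2], t = ct[, 3], p = ct[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    vcov = vcov(m),
    fstatistic = if (!is.null(fs))
      c(F = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
        p = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
      else c(F = NA, df1 = NA, df2 = NA, p = NA),
    r.squared = s$r.squared,
    df.residual = m$df.residual,
    aic = AIC(m),
    n = n)
  class(out) <- "ls_fit"
  out
}

#' @export
print.ls_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<ls_fit> n = %d, F(%g, %g) = %.4g, p = %.3g, R^2 = %.3f\n",
              x$n, x$fstatistic["df1"], x$fstatistic["df2"],
              x$fstatistic["F"], x$fstatistic["p"], x$r.squared))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Construct an `ls_fit` from printed coefficients
#'
#' Builds a minimal model container from reported coefficients and standard
#' errors (e.g. a published regression table), for evaluating simple slopes
#' or Johnson-Neyman intervals when only the printed table is available.
#' Coefficient covariances other than the variances default to zero unless
#' supplied.
#'
#' @param terms Character vector of term names.
#' @param B Coefficients.
#' @param SE Standard errors.
#' @param df_residual Residual degrees of freedom.
#' @param n Sample size (defaults to `df_residual + length(terms)`).
#' @param vcov Optional full coefficient covariance matrix; default
#'   `diag(SE^2)`.
#' @return Object of class `ls_fit` (without a fitted `model` element).
#' @export
fit_from_coefs <- function(terms, B, SE, df_residual, n = NULL,
                           vcov = NULL) {
  stopifnot(length(terms) == length(B), length(B) == length(SE))
  if (is.null(vcov)) vcov <- diag(SE^2, nrow = length(SE))
  dimnames(vcov) <- list(terms, terms)
  t <- B / SE
  out <- list(model = NULL, terms = terms,
              coefficients = data.frame(term = terms, B = B, SE = SE, t = t,
                                        p = 2 * pt(abs(t), df_residual,
                                                   lower.tail = FALSE),
                                        stringsAsFactors = FALSE),
              vcov = vcov,
              fstatistic = c(F = NA, df1 = NA, df2 = NA, p = NA),
              r.squared = NA_real_, df.residual = df_residual,
              aic = NA_real_, n = n %||% (df_residual + length(terms)))
  class(out) <- "ls_fit"
  out
}

#' Regress motion out of network measures
#'
#' Replaces each measure by its residual from an OLS regression on the
#' per-subject root-mean-square framewise displacement, removing residual
#' motion-related variance before the age and behavior models.
#'
#' @param measures Data frame of per-subject measures.
#' @param rms_fd Numeric vector, one value per row of `measures`.
#' @param cols Columns to residualize (default: `within`, `between`,
#'   `segregation` where present).
#' @param keep_mean If `TRUE`, add each measure's mean back to its
#'   residuals; default residuals are centered at zero.
#' @return `measures` with the named columns residualized.
#' @export
residualize_fd <- function(measures, rms_fd,
                           cols = intersect(c("within", "between",
                                              "segregation"),
                                            names(measures)),
                           keep_mean = FALSE) {
  stopifnot(length(rms_fd) == nrow(measures))
  if (sd(rms_fd) == 0) {
    warning("rms_fd is constant; residualization skipped", call. = FALSE)
    return(measures)
  }
  for (cl in cols) {
    y <- measures[[cl]]
    ok <- is.finite(y)
    r <- residuals(lm(y[ok] ~ rms_fd[ok]))
    measures[[cl]][ok] <- r + if (keep_mean) mean(y[ok]) else 0
  }
  measures
}

#' Standardize age
#'
#' Centers and scales age in years; by default the sample mean and SD are
#' used, or supply a fixed scale (e.g. a reference cohort's
#' mean 34.06, SD 21.06) so that moderator values map onto interpretable
#' ages.
#'
#' @param age Ages in years.
#' @param scale Optional list with `mean` and `sd` (years).
#' @return Standardized ages with attribute `scale`.
#' @seealso [unstandardize_age()]
#' @export
standardize_age <- function(age, scale = NULL) {
  if (is.null(scale)) scale <- list(mean = mean(age), sd = sd(age))
  stopifnot(scale$sd > 0)
  structure((age - scale$mean) / scale$sd, scale = scale)
}

#' Map standardized age back to years
#'
#' @param age_z Standardized ages (or moderator values).
#' @param scale List with `mean` and `sd` in years, or a vector carrying a
#'   `scale` attribute from [standardize_age()].
#' @return Ages in years.
#' @export
unstandardize_age <- function(age_z, scale) {
  if (!is.list(scale)) scale <- attr(scale, "scale")
  scale$mean + as.numeric(age_z) * scale$sd
}

#' Linear or quadratic age model for a network measure
#'
#' Fits `y ~ age_z` and `y ~ age_z + age_z^2`. In `"auto"` mode the
#' quadratic model is reported when its quadratic term is significant at
#' `alpha`, otherwise the linear model; `"on"`/`"off"` force the choice.
#'
#' @param y Outcome (typically an FD-residualized network measure).
#' @param age_z Standardized age.
#' @param quadratic `"auto"`, `"on"` or `"off"`.
#' @param alpha Significance level for the quadratic-retention rule.
#' @return An `ls_fit` with extra elements `quadratic` (logical) and
#'   `quadratic_p` (the quadratic term's p-value in the quadratic fit).
#' @export
fit_age_model <- function(y, age_z, quadratic = c("auto", "on", "off"),
                          alpha = 0.05) {
  quadratic <- match.arg(quadratic)
  d <- data.frame(y = y, age_z = as.numeric(age_z))
  lin <- fit_ols(y ~ age_z, d)
  quad <- fit_ols(y ~ age_z + I(age_z^2), d)
  qrow <- quad$coefficients[quad$coefficients$term == "I(age_z^2)", ]
  p_quad <- qrow$p
  # a (near-)saturated fit yields meaningless p-values; fall back on the
  # coefficient magnitude
  sigma <- sqrt(sum(residuals(quad$model)^2) / quad$df.residual)
  saturated <- !is.finite(p_quad) || sigma < 1e-10 * max(sd(y), 1e-300)
  auto_quad <- if (saturated)
    abs(qrow$B) > 1e-8 * max(1, max(abs(quad$coefficients$B)))
  else p_quad < alpha
  use_quad <- switch(quadratic, on = TRUE, off = FALSE, auto = auto_quad)
  out <- if (use_quad) quad else lin
  out$quadratic <- use_quad
  out$quadratic_p <- p_quad
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate adjustment of p-values, as applied to the
#' overall model fits across the 12 networks.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (monotone, `>=` raw, `<= 1`).
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Valence-bias model with an age covariate
#'
#' Fits OLS of valence bias on standardized age plus a set of connectivity
#' predictors (already FD-residualized).
#'
#' @param bias Valence bias scores (percent).
#' @param predictors Data frame (or named list) of predictor columns.
#' @param age_z Standardized age.
#' @return An `ls_fit`.
#' @export
fit_bias_model <- function(bias, predictors, age_z) {
  d <- data.frame(bias = bias, age_z = as.numeric(age_z),
                  as.data.frame(predictors))
  rhs <- paste(c("age_z", setdiff(names(d), c("bias", "age_z"))),
               collapse = " + ")
  fit_ols(stats::as.formula(paste("bias ~", rhs)), d)
}

#' Flag extreme outliers
#'
#' Default rule: values beyond `median(x) +/- k * IQR(x)` are flagged. The
#' flagged indices and values are attached so exclusions can be logged.
#'
#' @param x Numeric values.
#' @param k Multiplier on the interquartile range.
#' @return Integer vector of flagged indices, with attribute `values`.
#' @export
detect_outliers <- function(x, k = 3) {
  stopifnot(length(x) >= 4)
  med <- median(x, na.rm = TRUE)
  iqr <- IQR(x, na.rm = TRUE)
  idx <- which(!is.na(x) & abs(x - med) > k * iqr)
  attr(idx, "values") <- x[idx]
  idx
}
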