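write_tsv_out <- function(x, path) {
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], signif, digits = 6)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(result, matrices = NULL) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_out(result$manifest, file.path(dir, "manifest.tsv"))
  write_tsv_out(result$behavior, file.path(dir, "behavior_scores.tsv"))
  write_tsv_out(result$qc, file.path(dir, "qc_report.tsv"))
  if (!is.null(result$measures))
    write_tsv_out(result$measures, file.path(dir, "measures.tsv"))
  if (!is.null(result$pairwise))
    write_tsv_out(result$pairwise, file.path(dir, "pairwise.tsv"))
  if (!is.null(matrices) && length(matrices)) {
    mdir <- file.path(dir, "matrices")
    dir.create(mdir, showWarnings = FALSE)
    for (id in names(matrices))
      write.table(round(matrices[[id]], 6),
                  file.path(mdir, paste0(id, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  m <- result$models
  if (!is.null(m) && is.null(m$error)) {
    write_tsv_out(age_models_table(m), file.path(dir, "table1.tsv"))
    write_tsv_out(m$network_age, file.path(dir, "network_age_models.tsv"))
    write_tsv_out(final_model_table(m), file.path(dir, "table2.tsv"))
    if (nrow(m$elimination$trace))
      write_tsv_out(m$elimination$trace,
                    file.path(dir, "elimination_trace.tsv"))
    if (!is.null(m$moderation))
      write_tsv_out(moderation_table(m), file.path(dir, "moderation.tsv"))
  }
  make_report(result, file.path(dir, "report.txt"))
  invisible(dir)
}

# Age models (segregation / within / between), one row per coefficient.
age_models_table <- function(m) {
  rows <- lapply(names(m$age_models), function(nm) {
    f <- m$age_models[[nm]]
    ct <- f$coefficients
    ct$term <- sub("\\(Intercept\\)", "Intercept", ct$term)
    ct$term <- sub("I\\(age_z\\^2\\)", "Age (quadratic)", ct$term)
    ct$term <- sub("^age_z$", "Age", ct$term)
    data.frame(model = nm, term = ct$term, B = ct$B, SE = ct$SE,
               t = ct$t, p = ct$p, F = unname(f$fstatistic["F"]),
               df1 = unname(f$fstatistic["df1"]),
               df2 = unname(f$fstatistic["df2"]),
               p_model = unname(f$fstatistic["p"]),
               r_squared = f$r.squared, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Final bias model, terms ordered: Intercept, Age, connectivity terms,
# then interactions.
final_model_table <- function(m) {
  ct <- m$final$fit$coefficients
  is_int <- grepl(":", ct$term)
  ord <- c(which(ct$term == "(Intercept)"),
           which(ct$term == "age_z"),
           which(!is_int & !ct$term %in% c("(Intercept)", "age_z")),
           which(is_int))
  ct <- ct[ord, ]
  ct$term <- sub("\\(Intercept\\)", "Intercept", ct$term)
  ct$term <- sub("^age_z$", "Age", ct$term)
  rownames(ct) <- NULL
  ct
}

moderation_table <- function(m) {
  rows <- lapply(m$moderation, function(md) {
    s <- md$slopes
    s$focal <- md$focal
    s$jn_lower <- if (length(md$jn$boundaries)) min(md$jn$boundaries) else NA
    s$jn_upper <- if (length(md$jn$boundaries)) max(md$jn$boundaries) else NA
    s$jn_lower_years <- if (!is.null(md$jn$boundaries_raw))
      min(md$jn$boundaries_raw) else NA
    s$jn_upper_years <- if (!is.null(md$jn$boundaries_raw))
      max(md$jn$boundaries_raw) else NA
    s$jn_region <- md$jn$region
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("focal", "at", "slope", "SE", "t", "p", "jn_lower", "jn_upper",
          "jn_lower_years", "jn_upper_years", "jn_region")]
}

#' Render the text report
#'
#' Writes a plain-text summary: the exclusion flow, the age models for the
#' global network measures, the per-network age effects with FDR-adjusted
#' model p-values, the final valence-bias model, and the moderation
#' (simple slopes / Johnson-Neyman) section.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param path Output file; `NULL` returns the report lines invisibly.
#' @return The report lines, invisibly.
#' @export
make_report <- function(result, path = NULL) {
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("segbias pipeline report (version %s, config %s)", result$version,
      substr(result$config_hash, 1, 8))
  add("")
  add("== Exclusion flow ==")
  tab <- table(result$manifest$status)
  for (s in names(tab)) add("  %-20s %d", s, tab[[s]])
  add("  %-20s %d", "total", nrow(result$manifest))
  m <- result$models
  if (is.null(m)) {
    add(""); add("Too few analyzable subjects; model stage skipped.")
  } else if (!is.null(m$error)) {
    add(""); add("Model stage failed: %s", m$error)
  } else {
    add(""); add("== Age models (network measures, FD-residualized) ==")
    if (length(m$outliers))
      add("  extreme outlier(s) removed: %s",
          paste(m$outliers, collapse = ", "))
    t1 <- age_models_table(m)
    for (nm in unique(t1$model)) {
      f <- t1[t1$model == nm, ]
      add("  %s (F(%g, %g) = %.2f, p = %.3g, R^2 = %.3f)", nm,
          f$df1[1], f$df2[1], f$F[1], f$p_model[1], f$r_squared[1])
      for (i in seq_len(nrow(f)))
        add("    %-16s B = %8.3f  SE = %6.3f  t = %7.3f  p = %.3g",
            f$term[i], f$B[i], f$SE[i], f$t[i], f$p[i])
    }
    add(""); add("== Per-network segregation ~ age (FDR across networks) ==")
    na <- m$network_age
    for (i in seq_len(nrow(na)))
      add("  %-9s B_age = %8.3f  p_model(FDR) = %.3g%s", na$network[i],
          na$B_age[i], na$p_model_fdr[i],
          if (na$quadratic[i]) "  [quadratic]" else "")
    add(""); add("== Final valence-bias model ==")
    add("  n = %d, F(%g, %g) = %.3f, p = %.3g, R^2 = %.3f", m$n_model,
        m$final$fit$fstatistic["df1"], m$final$fit$fstatistic["df2"],
        m$final$fit$fstatistic["F"], m$final$fit$fstatistic["p"],
        m$final$fit$r.squared)
    t2 <- final_model_table(m)
    for (i in seq_len(nrow(t2)))
      add("    %-24s B = %8.3f  SE = %6.3f  t = %7.3f  p = %.3g",
          t2$term[i], t2$B[i], t2$SE[i], t2$t[i], t2$p[i])
    add(""); add("== Moderation ==")
    if (is.null(m$moderation)) {
      add("  no moderation detected (no significant age interactions)")
    } else {
      for (md in m$moderation) {
        add("  %s x age:", md$focal)
        s <- md$slopes
        for (i in seq_len(nrow(s)))
          add("    slope at age_z = %+g: %8.3f (SE %.3f, t = %.3f, p = %.3g)",
              s$at[i], s$slope[i], s$SE[i], s$t[i], s$p[i])
        if (length(md$jn$boundaries)) {
          add("    Johnson-Neyman: significant %s %s (years: %s)",
              md$jn$region,
              paste(round(md$jn$boundaries, 3), collapse = " / "),
              paste(round(md$jn$boundaries_raw, 2), collapse = " / "))
        } else {
          add("    Johnson-Neyman: significant %s", md$jn$region)
        }
      }
    }
  }
  if (!is.null(path)) writeLines(ln, path)
  invisible(ln)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(make_report(x), sep = "\n")
  invisible(x)
}
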