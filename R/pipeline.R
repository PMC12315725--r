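#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis in one validated object:
#' censoring thresholds (0.2 mm filtered FD, 5-frame contiguity, 50-frame
#' runs, 800-frame budget), the 0.009-0.08 Hz pass band, the 60% behavioral
#' accuracy cutoff, the model alpha, and the synthetic-cohort parameters.
#' Configurations round-trip losslessly through YAML.
#'
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @param data_dir Existing cohort directory to analyze; `NULL` simulates a
#'   cohort from `cohort` instead.
#' @param cohort Named list of [cohort_spec()] arguments for simulation.
#' @param fd_threshold Censoring threshold on filtered FD, mm.
#' @param fd_lowpass Low-pass cutoff for filtered FD, Hz.
#' @param rotation_radius Rotation-to-mm conversion radius, mm.
#' @param min_segment Minimum retained contiguous segment, frames.
#' @param min_run Minimum retained frames per run.
#' @param frame_budget Selected frames per subject.
#' @param band Pass-band edges, Hz.
#' @param accuracy_cutoff Behavioral inclusion cutoff (fraction correct).
#' @param alpha Significance level for model decisions.
#' @param quadratic Quadratic-age rule for age models
#'   (`"auto"`/`"on"`/`"off"`).
#' @param guard_cie Change-in-estimate guard in backward elimination.
#' @param outlier_iqr IQR multiplier for the extreme-outlier rule.
#' @param seed Integer seed for all randomness.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, data_dir = NULL,
                            cohort = list(n_subjects = 24),
                            fd_threshold = 0.2, fd_lowpass = 0.1,
                            rotation_radius = 50, min_segment = 5,
                            min_run = 50, frame_budget = 800,
                            band = c(0.009, 0.08),
                            accuracy_cutoff = 0.60, alpha = 0.05,
                            quadratic = "auto", guard_cie = FALSE,
                            outlier_iqr = 3, seed = 1L) {
  cfg <- list(out_dir = out_dir, data_dir = data_dir, cohort = cohort,
              fd_threshold = fd_threshold, fd_lowpass = fd_lowpass,
              rotation_radius = rotation_radius, min_segment = min_segment,
              min_run = min_run, frame_budget = frame_budget,
              band = as.numeric(band), accuracy_cutoff = accuracy_cutoff,
              alpha = alpha, quadratic = quadratic, guard_cie = guard_cie,
              outlier_iqr = outlier_iqr, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$fd_threshold > 0, cfg$min_segment >= 1, cfg$min_run >= 1,
            cfg$frame_budget >= 1, length(cfg$band) == 2,
            cfg$band[1] > 0, cfg$band[1] < cfg$band[2],
            cfg$accuracy_cutoff >= 0, cfg$accuracy_cutoff <= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$outlier_iqr > 0)
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg A `pipeline_config`.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order: simulate (or load) the cohort,
#' score behavior and apply the accuracy cutoff, motion QC and time-series
#' cleaning with frame-budget selection, connectivity and network measures,
#' lifespan models (age models with FDR across networks, the valence-bias
#' model with AIC backward elimination over the 11 DMN between-network
#' connectivities, interaction screening, simple slopes and Johnson-Neyman),
#' and report rendering. Identical config + seed yields identical outputs.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return List of class `pipeline_result` with `manifest` (per-subject
#'   terminal status), stage outputs (`behavior`, `qc`, `measures`,
#'   `pairwise`, `models`) and the `config`; written as TSV files under
#'   `out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  validate_pipeline_config(config)

  # --- stage: cohort ------------------------------------------------------
  if (is.null(config$data_dir)) {
    spec <- do.call(cohort_spec,
                    modifyList(config$cohort, list(seed = config$seed)))
    bundle <- generate_cohort(spec, include_timeseries = FALSE)
    get_ts <- function(i) generate_timeseries(spec, bundle$plant[[i]],
      motion_runs = bundle$motion[[i]],
      seed = child_seed(spec$seed, i, 5L))
    parcellation <- bundle$parcellation
    subjects <- bundle$subjects
    trials <- bundle$trials
    motion <- bundle$motion
    tr <- spec$tr
  } else {
    subjects <- read.delim(file.path(config$data_dir, "subjects.tsv"),
                           stringsAsFactors = FALSE)
    parcellation <- read_parcellation(file.path(config$data_dir,
                                                "parcellation.tsv"))
    trials <- read_trials(config$data_dir)
    motion <- lapply(subjects$subject_id,
                     function(id) read_motion(config$data_dir, id))
    names(motion) <- subjects$subject_id
    get_ts <- function(i) read_timeseries(config$data_dir,
                                          subjects$subject_id[i])
    tr <- config$cohort$tr %||% 1.0
  }
  ids <- subjects$subject_id
  n <- length(ids)

  # --- stage: behavior ----------------------------------------------------
  behavior <- score_behavior(trials[ids],
                             accuracy_cutoff = config$accuracy_cutoff)
  status <- setNames(rep("included", n), ids)
  status[!behavior$included] <- "excluded:behavior"

  # --- stage: qc + connectivity (streamed per subject) --------------------
  labels14 <- parcellation$network
  labels12 <- merge_networks(labels14)
  keep_roi <- setdiff(seq_along(labels14), attr(labels12, "dropped_rois"))
  qc <- data.frame(subject_id = ids, retained_frames = NA_integer_,
                   rms_fd = NA_real_, included = FALSE,
                   stringsAsFactors = FALSE)
  matrices <- list()
  for (i in seq_len(n)) {
    if (status[i] != "included") next
    cl <- tryCatch(
      clean_subject(get_ts(i), motion[[ids[i]]], tr = tr,
                    fd_threshold = config$fd_threshold,
                    min_segment = config$min_segment,
                    min_run_frames = config$min_run,
                    frame_budget = config$frame_budget,
                    fd_lowpass = config$fd_lowpass, band = config$band),
      error = function(e) stop("stage qc failed for subject ", ids[i],
                               ": ", conditionMessage(e), call. = FALSE))
    qc$retained_frames[i] <- cl$retained_total
    qc$rms_fd[i] <- cl$rms_fd
    qc$included[i] <- cl$included
    if (!cl$included) {
      status[i] <- "excluded:frames"
      next
    }
    r <- correlate(cl$ts, frames = cl$selected)
    z <- threshold_negative(fisher_z(r)[keep_roi, keep_roi])
    matrices[[ids[i]]] <- z
  }

  # --- stage: network measures --------------------------------------------
  measures <- pairwise <- NULL
  models <- NULL
  if (length(matrices) >= 2) {
    cm <- cohort_measures(matrices, as.character(labels12),
                          qc = qc[qc$included, ],
                          behavior = behavior[behavior$included, ])
    measures <- cm$measures
    pairwise <- cm$pairwise
    models <- tryCatch(
      fit_lifespan_models(measures, pairwise, subjects, config),
      error = function(e) list(error = conditionMessage(e)))
  }

  manifest <- data.frame(subject_id = ids, status = unname(status),
                         stringsAsFactors = FALSE)
  result <- list(manifest = manifest, behavior = behavior, qc = qc,
                 measures = measures, pairwise = pairwise, models = models,
                 config = config, config_hash = config_hash(config),
                 version = as.character(utils::packageVersion("segbias")))
  class(result) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, matrices)
  result
}

# The statistical stage: age models (with FDR across networks), the bias
# model with backward elimination over DMN between-network connectivity,
# interaction screening and moderation analysis.
fit_lifespan_models <- function(measures, pairwise, subjects, config) {
  glob <- measures[measures$network == "global", ]
  glob <- merge(glob, subjects[, c("subject_id", "age")], by = "subject_id")
  glob <- residualize_fd(glob, glob$rms_fd)

  # extreme-outlier rule on residualized segregation (age analysis only)
  out_idx <- detect_outliers(glob$segregation, k = config$outlier_iqr)
  age_data <- if (length(out_idx)) glob[-out_idx, ] else glob
  age_z_age <- standardize_age(age_data$age)
  age_models <- list(
    segregation = fit_age_model(age_data$segregation, age_z_age,
                                config$quadratic, config$alpha),
    within = fit_age_model(age_data$within, age_z_age,
                           config$quadratic, config$alpha),
    between = fit_age_model(age_data$between, age_z_age,
                            config$quadratic, config$alpha))

  # per-network segregation ~ age, FDR across the 12 overall model fits
  net_rows <- lapply(NETWORKS_12, function(k) {
    d <- measures[measures$network == k, ]
    d <- merge(d, subjects[, c("subject_id", "age")], by = "subject_id")
    d <- residualize_fd(d, d$rms_fd, cols = "segregation")
    if (length(out_idx)) d <- d[!(d$subject_id %in%
                                    glob$subject_id[out_idx]), ]
    f <- fit_age_model(d$segregation, standardize_age(d$age),
                       config$quadratic, config$alpha)
    b_age <- f$coefficients[f$coefficients$term == "age_z", ]
    data.frame(network = k, quadratic = f$quadratic,
               B_age = b_age$B, SE_age = b_age$SE, t_age = b_age$t,
               p_age = b_age$p, F = unname(f$fstatistic["F"]),
               p_model = unname(f$fstatistic["p"]),
               r_squared = f$r.squared, stringsAsFactors = FALSE)
  })
  network_age <- do.call(rbind, net_rows)
  network_age$p_model_fdr <- fdr_adjust(network_age$p_model)
  rownames(network_age) <- NULL

  # bias stage: full sample of imaging-included subjects
  age_z <- standardize_age(glob$age)
  age_scale <- attr(age_z, "scale")

  # DMN segregation model (bias ~ age + DMN segregation)
  dmn <- measures[measures$network == "DMN", ]
  dmn <- merge(dmn, subjects[, c("subject_id", "age")], by = "subject_id")
  dmn <- residualize_fd(dmn, dmn$rms_fd)
  dmn_seg_model <- fit_bias_model(dmn$valence_bias,
                                  data.frame(dmn_segregation =
                                               dmn$segregation),
                                  standardize_age(dmn$age))

  # 11 DMN pairwise between-network connectivities as candidates
  dp <- pairwise[pairwise$net_a == "DMN" | pairwise$net_b == "DMN", ]
  dp$partner <- ifelse(dp$net_a == "DMN", dp$net_b, dp$net_a)
  wide <- stats::reshape(dp[, c("subject_id", "partner", "z")],
                         idvar = "subject_id", timevar = "partner",
                         direction = "wide")
  names(wide) <- sub("^z\\.", "dmn_", tolower(names(wide)))
  names(wide)[1] <- "subject_id"
  cand <- setdiff(names(wide), "subject_id")
  d <- merge(glob[, c("subject_id", "age", "rms_fd")], wide,
             by = "subject_id")
  d <- merge(d, measures[measures$network == "global",
                         c("subject_id", "valence_bias")],
             by = "subject_id")
  d <- residualize_fd(d, d$rms_fd, cols = cand)
  d$age_z <- as.numeric(standardize_age(d$age, age_scale))

  elim <- backward_eliminate(d, "valence_bias", cand, forced = "age_z",
                             guard_cie = config$guard_cie)
  screen <- screen_interactions(d, "valence_bias", elim$selected,
                                moderator = "age_z", alpha = config$alpha)
  moderation <- NULL
  if (length(screen$interactions)) {
    moderation <- lapply(screen$interactions, function(int) {
      focal <- sub(":age_z$", "", int)
      list(focal = focal, interaction = int,
           slopes = simple_slopes(screen$fit, focal, int),
           jn = johnson_neyman(screen$fit, focal, int,
                               alpha = config$alpha, scale = age_scale))
    })
    names(moderation) <- vapply(moderation, `[[`, "", "focal")
  }
  list(age_models = age_models, network_age = network_age,
       outliers = glob$subject_id[out_idx],
       dmn_seg_model = dmn_seg_model, elimination = elim,
       final = screen, moderation = moderation, age_scale = age_scale,
       n_model = nrow(d))
}
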