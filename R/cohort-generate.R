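#' Generate a synthetic lifespan cohort
#'
#' Draws a full synthetic cohort from a [cohort_spec()]: a subject table with
#' planted ground truth, per-subject behavioral trial tables, per-run motion
#' traces, and (optionally) per-run ROI time series drawn from a latent
#' factor model whose within- and between-network correlation targets follow
#' the planted age profiles.
#'
#' The factor model gives each ROI in network *k* a loading on a network
#' factor, on one shared cross-network factor, and (for DMN, CO, VAN and
#' Reward ROIs) on pair-specific factors that realize the subject-specific
#' DMN-CO, DMN-VAN and DMN-Reward couplings. Loadings are solved so that
#' the population correlations hit the planted targets exactly, which keeps
#' every implied covariance positive semi-definite at any target.
#'
#' @param spec A [cohort_spec()].
#' @param include_timeseries If `FALSE`, ROI time series are not generated
#'   up front; use [generate_timeseries()] per subject instead (useful for
#'   large cohorts processed in a streaming fashion).
#' @param include_trials,include_motion Set to `FALSE` to skip generating
#'   trial tables / motion traces (subject-table-only simulation studies).
#' @return A list of class `cohort_bundle` with elements `spec`,
#'   `parcellation`, `subjects`, `trials` (list of trial tables), `motion`
#'   (list of per-run motion traces) and `timeseries` (list of per-run
#'   frames-by-ROI matrices, or `NULL`s).
#' @examples
#' b <- generate_cohort(cohort_spec(n_subjects = 2, n_rois = 42,
#'                                  n_frames = 100, seed = 7))
#' b$subjects[, c("subject_id", "age", "true_bias")]
#' @seealso [generate_trials()], [generate_motion()], [generate_timeseries()]
#' @export
generate_cohort <- function(spec, include_timeseries = TRUE,
                            include_trials = TRUE, include_motion = TRUE) {
  if (include_timeseries) include_motion <- TRUE
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  parcellation <- make_parcellation(spec)

  # population age scale of the uniform age distribution: fixed by the spec,
  # so planted profiles do not depend on the realized sample
  mu <- mean(spec$age_range)
  sigma <- diff(spec$age_range) / sqrt(12)

  subjects <- with_seed(child_seed(spec$seed, 0L, 1L), {
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    age_z <- (age - mu) / sigma
    acc <- ifelse(runif(n) < spec$low_accuracy_rate,
                  runif(n, 0.40, 0.58), spec$accuracy_clear)
    data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
               age = age, age_z = age_z, accuracy_clear = acc,
               stringsAsFactors = FALSE)
  })

  plant <- vector("list", n)
  extra <- with_seed(child_seed(spec$seed, 0L, 2L), {
    rows <- lapply(seq_len(n), function(i) {
      p <- plant_targets(spec, subjects$age_z[i])
      plant[[i]] <<- p
      noise <- rnorm(1, 0, spec$bias_noise_sd)
      bias <- spec$bias_intercept +
        spec$beta_age_bias * subjects$age_z[i] +
        spec$gamma_co * p$delta_z["CO"] +
        spec$gamma_van * p$delta_z["VAN"] +
        spec$gamma_reward_by_age * subjects$age_z[i] * p$delta_z["Reward"] +
        noise
      data.frame(true_bias = min(100, max(0, bias)),
                 true_within = mean(p$r_w), true_between = p$r_b,
                 true_z_dmn_co = p$z_pair["CO"],
                 true_z_dmn_van = p$z_pair["VAN"],
                 true_z_dmn_reward = p$z_pair["Reward"],
                 delta_co = p$delta_z["CO"],
                 delta_van = p$delta_z["VAN"],
                 delta_reward = p$delta_z["Reward"])
    })
    do.call(rbind, rows)
  })
  rownames(extra) <- NULL
  subjects <- cbind(subjects, extra)
  subjects$spike_rate <- pmin(0.9, spec$motion_spike_rate *
                                (0.5 + 0.5 * subjects$age_z^2))

  trials <- motion <- timeseries <- setNames(vector("list", n),
                                             subjects$subject_id)
  run_len <- run_lengths(spec$n_frames, spec$n_runs)
  for (i in seq_len(n)) {
    if (include_trials)
      trials[[i]] <- generate_trials(subjects[i, ],
                                     seed = child_seed(spec$seed, i, 3L))
    if (include_motion)
      motion[[i]] <- lapply(seq_along(run_len), function(k)
        generate_motion(run_len[k], tr = spec$tr,
                        spike_rate = subjects$spike_rate[i],
                        drift_sd = spec$drift_sd,
                        seed = child_seed(spec$seed, i, 4L) + k))
    if (include_timeseries)
      timeseries[[i]] <- generate_timeseries(spec, plant[[i]],
        motion_runs = motion[[i]], seed = child_seed(spec$seed, i, 5L))
  }

  structure(list(spec = spec, parcellation = parcellation,
                 subjects = subjects, plant = plant, trials = trials,
                 motion = motion, timeseries = timeseries,
                 age_scale = list(mean = mu, sd = sigma)),
            class = "cohort_bundle")
}

# Split n_frames into n_runs contiguous runs of near-equal length.
run_lengths <- function(n_frames, n_runs) {
  base <- n_frames %/% n_runs
  len <- rep(base, n_runs)
  len[seq_len(n_frames %% n_runs)] <- base + 1L
  len
}

#' Parcellation table for a cohort spec
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with `roi_id`, display coordinates `x`, `y`, `z` (mm)
#'   and `network` label (14 networks).
#' @export
make_parcellation <- function(spec) {
  sizes <- spec$network_sizes[NETWORKS_14]
  with_seed(child_seed(spec$seed, 0L, 0L), {
    data.frame(roi_id = seq_len(spec$n_rois),
               x = round(runif(spec$n_rois, -70, 70), 1),
               y = round(runif(spec$n_rois, -105, 70), 1),
               z = round(runif(spec$n_rois, -45, 75), 1),
               network = rep(names(sizes), sizes),
               stringsAsFactors = FALSE)
  })
}

# Planted correlation targets for one subject. Called inside a seeded
# context. Returns within-network targets r_w (per network), the common
# between-network target r_b, the realized pairwise DMN-{CO,VAN,Reward}
# correlations and their Fisher-z deviations from atanh(r_b).
plant_targets <- function(spec, age_z) {
  offsets <- seq(-0.04, 0.04, length.out = 14)
  names(offsets) <- NETWORKS_14
  r_w <- pmin(pmax(spec$within_base + offsets + spec$beta_age_seg * age_z,
                   0.12), 0.85)
  r_b <- spec$between_base + spec$between_lin * age_z +
    spec$beta_between_quad * age_z^2
  r_b <- min(min(r_w) - 0.07, max(0.01, r_b))

  pairs <- c("CO", "VAN", "Reward")
  delta <- rnorm(3, 0, spec$pair_sd)
  names(delta) <- pairs
  r_pair <- tanh(atanh(r_b) + delta)
  # feasibility: partner network loading budget
  for (p in pairs) {
    hi <- r_w[p] - 0.02
    r_pair[p] <- min(max(r_pair[p], 0.005), r_b + (hi - r_b))
    r_pair[p] <- min(r_pair[p], hi)
  }
  d_r <- r_pair - r_b
  # feasibility: DMN loading budget across all three pair factors
  budget <- r_w["DMN"] - r_b - 0.02
  tot <- sum(abs(d_r))
  if (tot > budget) d_r <- d_r * (budget / tot)
  r_pair <- r_b + d_r
  z_pair <- atanh(r_pair)
  list(r_w = r_w, r_b = r_b, d_r = d_r, z_pair = z_pair,
       delta_z = z_pair - atanh(r_b))
}

#' Generate behavioral trial tables for one subject
#'
#' Builds the 96-trial valence bias task: four blocks (two face, two scene),
#' each with 12 ambiguous and 12 clearly valenced trials (6 positive,
#' 6 negative). Each ambiguous response is positive with probability
#' `true_bias / 100` (exact count at the task's 1/48 resolution, randomly
#' placed); clear responses are correct with probability `accuracy_clear`;
#' a fraction `omit_rate` of responses is replaced by `"none"` (omissions).
#'
#' @param subject One-row data frame (or list) with `true_bias` (percent,
#'   0-100) and `accuracy_clear` (fraction).
#' @param seed Integer seed.
#' @param omit_rate Probability a trial receives no response.
#' @return Data frame with `trial_id`, `block`, `stimulus_type`,
#'   `valence_class` and `response`.
#' @examples
#' tt <- generate_trials(list(true_bias = 60, accuracy_clear = 0.97), seed = 1)
#' table(tt$valence_class)
#' @export
generate_trials <- function(subject, seed, omit_rate = 0) {
  stopifnot(subject$true_bias >= 0, subject$true_bias <= 100)
  with_seed(seed, {
    blocks <- lapply(1:4, function(b) {
      cls <- sample(c(rep("ambiguous", 12),
                      rep("clear_positive", 6), rep("clear_negative", 6)))
      data.frame(block = b,
                 stimulus_type = c("face", "scene", "face", "scene")[b],
                 valence_class = cls, stringsAsFactors = FALSE)
    })
    tt <- do.call(rbind, blocks)
    tt$trial_id <- seq_len(nrow(tt))
    amb <- tt$valence_class == "ambiguous"
    resp <- character(nrow(tt))
    # exact positive count at the task's resolution, random placement:
    # each ambiguous trial is marginally positive w.p. true_bias/100 and
    # scoring recovers the planted bias up to rounding to 1/48
    n_amb <- sum(amb)
    n_pos <- round(subject$true_bias / 100 * n_amb)
    resp[amb] <- sample(rep(c("positive", "negative"),
                            c(n_pos, n_amb - n_pos)))
    correct <- runif(sum(!amb)) < subject$accuracy_clear
    true_resp <- ifelse(tt$valence_class[!amb] == "clear_positive",
                        "positive", "negative")
    flip <- ifelse(true_resp == "positive", "negative", "positive")
    resp[!amb] <- ifelse(correct, true_resp, flip)
    if (omit_rate > 0)
      resp[runif(nrow(tt)) < omit_rate] <- "none"
    tt$response <- resp
    tt[, c("trial_id", "block", "stimulus_type", "valence_class", "response")]
  })
}

#' Generate a synthetic realignment (motion) trace for one run
#'
#' Produces a frames-by-6 table of rigid-body realignment estimates: three
#' translations (mm) and three rotations (radians). The baseline is a
#' low-amplitude random-walk drift; head motion events are injected as
#' sustained translation steps (1.2-2.5 mm on a random axis) whose
#' low-pass-filtered framewise displacement exceeds the 0.2 mm censoring
#' threshold over roughly five frames per event, so that the fraction of
#' suprathreshold frames approximates `spike_rate`. Rotations stay
#' sub-threshold.
#'
#' @param n_frames Number of frames in the run.
#' @param tr Sampling interval, seconds.
#' @param spike_rate Target fraction of frames with filtered FD > 0.2 mm.
#' @param drift_sd Per-frame SD of the translational drift (mm); rotational
#'   drift uses `drift_sd / 100` radians.
#' @param seed Integer seed.
#' @return Data frame with columns `trans_x`, `trans_y`, `trans_z` (mm) and
#'   `rot_x`, `rot_y`, `rot_z` (radians); attribute `spike_frames` holds the
#'   indices of the injected step events.
#' @examples
#' m <- generate_motion(200, spike_rate = 0.1, seed = 3)
#' head(m)
#' @export
generate_motion <- function(n_frames, tr = 1.0, spike_rate = 0.05,
                            drift_sd = 0.01, seed = 1L) {
  stopifnot(spike_rate >= 0, spike_rate <= 1, n_frames >= 2)
  with_seed(seed, {
    trans <- apply(matrix(rnorm(n_frames * 3, 0, drift_sd), ncol = 3), 2,
                   cumsum)
    rot <- apply(matrix(rnorm(n_frames * 3, 0, drift_sd / 100), ncol = 3), 2,
                 cumsum)
    # each sustained step yields ~5 frames of filtered FD above 0.2 mm
    event_rate <- spike_rate / 5
    events <- which(runif(n_frames - 1) < event_rate) + 1L
    for (e in events) {
      axis <- sample(3, 1)
      amp <- sample(c(-1, 1), 1) * runif(1, 1.2, 2.5)
      trans[e:n_frames, axis] <- trans[e:n_frames, axis] + amp
    }
    out <- data.frame(trans_x = trans[, 1], trans_y = trans[, 2],
                      trans_z = trans[, 3], rot_x = rot[, 1],
                      rot_y = rot[, 2], rot_z = rot[, 3])
    attr(out, "spike_frames") <- events
    attr(out, "tr") <- tr
    out
  })
}

#' Generate ROI time series for one subject
#'
#' Draws per-run frames-by-ROI matrices from the subject's planted latent
#' factor model (see [generate_cohort()]), adds a per-ROI mean and slow
#' linear trend (removed downstream by detrending), and corrupts frames at
#' motion step events with a shared additive artifact (removed downstream by
#' censoring/nuisance regression).
#'
#' @param spec A [cohort_spec()].
#' @param plant Planted targets for the subject, as produced inside
#'   [generate_cohort()] (elements `r_w`, `r_b`, `d_r`).
#' @param motion_runs List of motion traces (one per run) whose
#'   `spike_frames` attributes mark artifact frames; `NULL` for none.
#' @param seed Integer seed.
#' @param n_frames Total frames; defaults to `spec$n_frames`.
#' @return List of per-run numeric matrices (frames x ROIs).
#' @export
generate_timeseries <- function(spec, plant, motion_runs = NULL, seed = 1L,
                                n_frames = spec$n_frames) {
  sizes <- spec$network_sizes[NETWORKS_14]
  L <- factor_loadings(sizes, plant)
  noise_sd <- sqrt(pmax(0, 1 - rowSums(L^2)))
  n_rois <- nrow(L)
  run_len <- if (is.null(motion_runs)) run_lengths(n_frames, spec$n_runs)
             else vapply(motion_runs, nrow, 1L)
  with_seed(seed, {
    roi_mean <- rnorm(n_rois, 100, 10)
    roi_drift <- runif(n_rois, -5, 5)  # total scanner drift over a run
    lapply(seq_along(run_len), function(k) {
      nf <- run_len[k]
      f <- matrix(rnorm(nf * ncol(L)), nf, ncol(L))
      x <- f %*% t(L) + matrix(rnorm(nf * n_rois), nf, n_rois) *
        rep(noise_sd, each = nf)
      x <- 10 * x + rep(roi_mean, each = nf) +
        outer(seq_len(nf) / nf, roi_drift)
      if (!is.null(motion_runs)) {
        sf <- attr(motion_runs[[k]], "spike_frames")
        if (length(sf)) x[sf, ] <- x[sf, ] + rnorm(length(sf), 0, 20)
      }
      colnames(x) <- sprintf("roi%03d", seq_len(n_rois))
      x
    })
  })
}

# Loading matrix (ROIs x factors) realizing the planted targets.
# Factors: 14 network factors, 1 shared global factor, 3 DMN-pair factors.
factor_loadings <- function(sizes, plant) {
  nets <- rep(names(sizes), sizes)
  n_rois <- length(nets)
  pairs <- c("CO", "VAN", "Reward")
  L <- matrix(0, n_rois, 14 + 1 + 3)
  colnames(L) <- c(names(sizes), "global", paste0("pair_", pairs))
  b2 <- plant$r_b
  for (k in names(sizes)) {
    idx <- nets == k
    extra <- if (k == "DMN") sum(abs(plant$d_r))
             else if (k %in% pairs) abs(plant$d_r[k]) else 0
    a2 <- plant$r_w[k] - b2 - extra
    stopifnot(a2 >= 0)
    L[idx, k] <- sqrt(a2)
  }
  L[, "global"] <- sqrt(b2)
  for (p in pairs) {
    d <- plant$d_r[p]
    L[nets == "DMN", paste0("pair_", p)] <- sqrt(abs(d))
    L[nets == p, paste0("pair_", p)] <- sign(d) * sqrt(abs(d))
  }
  L
}
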