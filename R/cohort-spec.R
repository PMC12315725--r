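#' Specification of a synthetic lifespan cohort
#'
#' Defines the generative conditions for a synthetic resting-state cohort:
#' sample size and age range, parcellation geometry, per-subject scan length,
#' the planted age profiles of within- and between-network connectivity, the
#' planted connectivity effects on valence bias, and motion characteristics.
#' All downstream stages (behavior scoring, censoring, connectivity, models)
#' can be exercised on data drawn from such a specification.
#'
#' Connectivity targets are expressed as Pearson correlations. Within-network
#' correlation declines linearly with standardized age (slope `beta_age_seg`),
#' which induces the planted decline in network segregation; between-network
#' correlation follows an inverted-U profile in age with quadratic coefficient
#' `beta_between_quad`. Subject-specific deviations of the DMN-CO, DMN-VAN and
#' DMN-Reward couplings (SD `pair_sd`, Fisher-z units) carry the planted
#' behavioral effects: valence bias is built as
#' `bias_intercept + beta_age_bias * age_z + gamma_co * d_co +
#'  gamma_van * d_van + gamma_reward_by_age * age_z * d_reward + noise`,
#' truncated to the 0-100 scale.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Two-element numeric, minimum and maximum age in years.
#' @param n_rois Number of ROIs in the parcellation.
#' @param network_sizes Named integer vector of ROI counts per network
#'   (14 networks, summing to `n_rois`). Default: equal sizes with the
#'   remainder assigned to `Unassigned`.
#' @param n_frames Frames per subject (total across runs).
#' @param n_runs Number of resting-state runs per subject.
#' @param tr Sampling interval in seconds.
#' @param within_base Within-network correlation at the mean age.
#' @param beta_age_seg Change in within-network correlation per standardized
#'   age unit (negative: segregation declines with age).
#' @param between_base Between-network correlation at the mean age.
#' @param between_lin Linear age coefficient for between-network correlation.
#' @param beta_between_quad Quadratic age coefficient for between-network
#'   correlation (negative: inverted U).
#' @param pair_sd SD (Fisher-z units) of subject-specific deviations of the
#'   DMN-CO, DMN-VAN and DMN-Reward couplings.
#' @param bias_intercept Mean valence bias (percent) at mean age with zero
#'   connectivity deviations.
#' @param beta_age_bias Valence-bias points per standardized age unit.
#' @param gamma_co,gamma_van Valence-bias points per unit DMN-CO / DMN-VAN
#'   Fisher-z deviation (positive).
#' @param gamma_reward_by_age Valence-bias points per unit DMN-Reward z
#'   deviation per standardized age unit (negative at older ages).
#' @param bias_noise_sd SD of the Gaussian bias noise, percentage points.
#' @param motion_spike_rate Target fraction of frames whose filtered FD
#'   exceeds 0.2 mm at the mean age; the realized rate is U-shaped in age.
#' @param drift_sd Per-frame SD of the translational drift random walk (mm).
#' @param accuracy_clear Probability of a correct response on clearly
#'   valenced trials for compliant subjects.
#' @param low_accuracy_rate Fraction of subjects simulated as non-compliant
#'   (clear-trial accuracy drawn below the 60% inclusion cutoff).
#' @param seed Integer seed; all generation is deterministic given the spec.
#'
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_subjects = 10, seed = 1)
#' spec$network_sizes
#' @export
cohort_spec <- function(n_subjects,
                        age_range = c(6, 80),
                        n_rois = 300,
                        network_sizes = NULL,
                        n_frames = 1000,
                        n_runs = 1,
                        tr = 1.0,
                        within_base = 0.40,
                        beta_age_seg = -0.04,
                        between_base = 0.12,
                        between_lin = 0.01,
                        beta_between_quad = -0.015,
                        pair_sd = 0.15,
                        bias_intercept = 50,
                        beta_age_bias = 5,
                        gamma_co = 25,
                        gamma_van = 12,
                        gamma_reward_by_age = -55,
                        bias_noise_sd = 15,
                        motion_spike_rate = 0.05,
                        drift_sd = 0.01,
                        accuracy_clear = 0.97,
                        low_accuracy_rate = 0.03,
                        seed = 1L) {
  if (is.null(network_sizes)) network_sizes <- default_network_sizes(n_rois)
  spec <- list(
    n_subjects = as.integer(n_subjects), age_range = as.numeric(age_range),
    n_rois = as.integer(n_rois), network_sizes = network_sizes,
    n_frames = as.integer(n_frames), n_runs = as.integer(n_runs), tr = tr,
    within_base = within_base, beta_age_seg = beta_age_seg,
    between_base = between_base, between_lin = between_lin,
    beta_between_quad = beta_between_quad, pair_sd = pair_sd,
    bias_intercept = bias_intercept, beta_age_bias = beta_age_bias,
    gamma_co = gamma_co, gamma_van = gamma_van,
    gamma_reward_by_age = gamma_reward_by_age,
    bias_noise_sd = bias_noise_sd,
    motion_spike_rate = motion_spike_rate, drift_sd = drift_sd,
    accuracy_clear = accuracy_clear, low_accuracy_rate = low_accuracy_rate,
    seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Equal network sizes with the remainder assigned to Unassigned
#'
#' @param n_rois Total number of ROIs.
#' @return Named integer vector over the 14 networks summing to `n_rois`.
#' @export
default_network_sizes <- function(n_rois = 300) {
  base <- n_rois %/% 14L
  if (base < 2L) stop("n_rois too small: each network needs at least 2 ROIs",
                      call. = FALSE)
  sizes <- rep(base, 14L)
  names(sizes) <- NETWORKS_14
  sizes["Unassigned"] <- sizes["Unassigned"] + n_rois %% 14L
  sizes
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, msg)
    stop(sprintf("invalid cohort spec: field '%s' %s", field, msg),
         call. = FALSE)
  if (is.na(spec$n_subjects) || spec$n_subjects < 1L)
    fail("n_subjects", "must be a positive integer")
  if (length(spec$age_range) != 2 || spec$age_range[1] >= spec$age_range[2])
    fail("age_range", "must be (min, max) with min < max")
  if (spec$n_frames < 1L) fail("n_frames", "must be >= 1")
  if (spec$n_runs < 1L || spec$n_frames %/% spec$n_runs < 2L)
    fail("n_runs", "must leave at least 2 frames per run")
  if (length(spec$network_sizes) != 14L ||
      !setequal(names(spec$network_sizes), NETWORKS_14))
    fail("network_sizes", "must be named over the 14 canonical networks")
  if (sum(spec$network_sizes) != spec$n_rois)
    fail("network_sizes", sprintf("must sum to n_rois (%d != %d)",
                                  sum(spec$network_sizes), spec$n_rois))
  if (any(spec$network_sizes < 2L))
    fail("network_sizes", "every network needs >= 2 ROIs")
  for (f in c("motion_spike_rate", "low_accuracy_rate", "accuracy_clear"))
    if (spec[[f]] < 0 || spec[[f]] > 1) fail(f, "must lie in [0, 1]")
  if (spec$within_base <= 0 || spec$within_base >= 1)
    fail("within_base", "must lie in (0, 1)")
  if (spec$between_base <= 0 || spec$between_base >= spec$within_base)
    fail("between_base", "must lie in (0, within_base)")
  if (spec$bias_noise_sd < 0) fail("bias_noise_sd", "must be >= 0")
  if (spec$pair_sd < 0) fail("pair_sd", "must be >= 0")
  if (spec$tr <= 0) fail("tr", "must be > 0")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects, ages %g-%g, %d ROIs / 14 networks, %d frames (%d run%s, TR %gs), seed %d\n",
              x$n_subjects, x$age_range[1], x$age_range[2], x$n_rois,
              x$n_frames, x$n_runs, if (x$n_runs > 1) "s" else "", x$tr,
              x$seed))
  cat(sprintf("  planted: within %.2f%+.3f*age_z, between %.2f%+.3f*age_z%+.3f*age_z^2\n",
              x$within_base, x$beta_age_seg, x$between_base, x$between_lin,
              x$beta_between_quad))
  cat(sprintf("  bias: %g %+g*age_z %+g*dCO %+g*dVAN %+g*age_z*dReward + N(0,%g)\n",
              x$bias_intercept, x$beta_age_bias, x$gamma_co, x$gamma_van,
              x$gamma_reward_by_age, x$bias_noise_sd))
  invisible(x)
}
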