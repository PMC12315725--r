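# Run the full pipeline on one seeded synthetic cohort and extract the signs
# of the three planted effects: the age slope of global segregation, the
# DMN-CO connectivity effect on valence bias, and the age x DMN-Reward
# interaction. The bias effects are read from the final-form model (age +
# DMN-CO + DMN-VAN + DMN-Reward + DMN-Reward x age) fitted on the measured,
# FD-residualized predictors: with a purely interactive Reward effect the
# Reward main effect is zero by construction, so AIC elimination legitimately
# drops it and the final-form fit is where the planted signs are read out.
recover_signs <- function(seed, n_subjects = 250, n_rois = 112) {
  cohort <- list(n_subjects = n_subjects, n_rois = n_rois, n_frames = 1000)
  cfg <- pipeline_config(cohort = cohort, seed = seed)
  res <- run_pipeline(cfg)
  age_b <- res$models$age_models$segregation$coefficients
  s_age <- sign(age_b$B[age_b$term == "age_z"])

  glob <- res$measures[res$measures$network == "global", ]
  dp <- res$pairwise[res$pairwise$net_a == "DMN" |
                       res$pairwise$net_b == "DMN", ]
  dp$partner <- ifelse(dp$net_a == "DMN", dp$net_b, dp$net_a)
  keep <- dp$partner %in% c("CO", "VAN", "Reward")
  wide <- stats::reshape(dp[keep, c("subject_id", "partner", "z")],
                         idvar = "subject_id", timevar = "partner",
                         direction = "wide")
  names(wide) <- c("subject_id", paste0("dmn_",
                                        tolower(sub("^z\\.", "",
                                                    names(wide)[-1]))))
  d <- merge(glob[, c("subject_id", "valence_bias", "rms_fd")], wide,
             by = "subject_id")
  spec <- do.call(cohort_spec, utils::modifyList(cohort, list(seed = seed)))
  subjects <- generate_cohort(spec, include_timeseries = FALSE,
                              include_trials = FALSE,
                              include_motion = FALSE)$subjects
  d <- merge(d, subjects[, c("subject_id", "age")], by = "subject_id")
  d <- residualize_fd(d, d$rms_fd,
                      cols = c("dmn_co", "dmn_van", "dmn_reward"))
  d$age_z <- as.numeric(standardize_age(d$age))
  f <- fit_ols(valence_bias ~ age_z + dmn_co + dmn_van + dmn_reward +
                 dmn_reward:age_z, d)
  ct <- f$coefficients
  c(age_seg = s_age,
    dmn_co = sign(ct$B[ct$term == "dmn_co"]),
    reward_by_age = sign(ct$B[ct$term == "age_z:dmn_reward"]))
}
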