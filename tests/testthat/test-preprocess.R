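test_that("framewise displacement matches hand finite differences", {
  zero <- as.data.frame(matrix(0, 20, 6))
  expect_equal(compute_fd(zero, lowpass_hz = NULL), rep(0, 20),
               ignore_attr = TRUE)
  # sustained 0.2 mm x-translation step at frame 10: FD 0.2 there, 0 elsewhere
  step <- zero
  step[10:20, 1] <- 0.2
  fd <- compute_fd(step, lowpass_hz = NULL)
  expect_equal(fd[10], 0.2)
  expect_equal(fd[-10], rep(0, 19), ignore_attr = TRUE)
  # 0.004 rad pitch step at 50 mm radius is also exactly 0.2 mm
  pitch <- zero
  pitch[10:20, 4] <- 0.004
  fd <- compute_fd(pitch, rotation_radius_mm = 50, lowpass_hz = NULL)
  expect_equal(fd[10], 0.2)
  expect_equal(fd[1], 0)
  expect_error(compute_fd(zero[1, , drop = FALSE]), "2 frames")
})

test_that("FD low-pass filtering attenuates single-frame pseudo-motion", {
  tr <- as.data.frame(matrix(0, 200, 6))
  tr[100, 1] <- 1  # one-frame displacement excursion
  raw <- compute_fd(tr, lowpass_hz = NULL)
  filt <- compute_fd(tr, lowpass_hz = 0.1)
  expect_equal(max(raw), 1)
  expect_lt(max(filt), 0.25 * max(raw))
})

test_that("censor mask reproduces the contiguity and run-length rules", {
  # both surviving segments shorter than 5 frames: everything goes
  m <- build_censor_mask(c(0, 0, 0.3, 0, 0, 0, 0), min_run_frames = 1)
  expect_equal(sum(m), 0)
  # clean 60-frame run is fully retained
  m <- build_censor_mask(rep(0.05, 60))
  expect_true(all(m))
  # 55-frame run, spike at frame 53: left 52 kept, right 2 dropped
  fd <- rep(0.1, 55); fd[53] <- 0.5
  m <- build_censor_mask(fd)
  expect_equal(sum(m), 52)
  expect_true(all(m[1:52]))
  expect_false(any(m[53:55]))
  # run-length rule zeroes whole runs below 50 retained frames
  fd <- rep(0.1, 49)
  expect_equal(sum(build_censor_mask(fd)), 0)
})

test_that("censor mask agrees with the scan-based oracle on random traces", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(20:120, 1)
    fd <- c(0, runif(n - 1, 0, 0.45))
    thr <- sample(c(0.15, 0.2, 0.3), 1)
    seg <- sample(2:6, 1)
    run <- sample(c(1, 20, 50), 1)
    got <- build_censor_mask(fd, threshold_mm = thr, min_segment = seg,
                             min_run_frames = run)
    expect_equal(as.logical(got), censor_oracle(fd, thr, seg, run))
  }
})

test_that("censoring is idempotent and monotone in the threshold", {
  set.seed(7)
  for (rep in 1:20) {
    fd <- c(0, runif(99, 0, 0.4))
    m <- build_censor_mask(fd)
    fd2 <- fd
    fd2[!m] <- 1  # already-censored frames stay censored
    expect_equal(as.logical(build_censor_mask(fd2)), as.logical(m))
    r_low <- sum(build_censor_mask(fd, threshold_mm = 0.15))
    r_high <- sum(build_censor_mask(fd, threshold_mm = 0.25))
    expect_lte(r_low, r_high)
  }
})

test_that("frame budget selects the earliest retained frames across runs", {
  expect_false(select_frame_budget(rep(TRUE, 799))$included)
  sel <- select_frame_budget(rep(TRUE, 800))
  expect_true(sel$included)
  expect_equal(sum(sel$selected[[1]]), 800)
  # 500 retained in run 1 + 600 in run 2: take 500 + first 300
  m1 <- rep(TRUE, 500)
  m2 <- rep(c(FALSE, TRUE), c(50, 600))
  sel <- select_frame_budget(list(m1, m2))
  expect_true(sel$included)
  expect_equal(sum(sel$selected[[1]]), 500)
  expect_equal(sum(sel$selected[[2]]), 300)
  expect_equal(which(sel$selected[[2]]), 51:350)
  # prefix property: the selection is a prefix of the retained sequence
  set.seed(12)
  masks <- lapply(1:3, function(k) runif(400) > 0.2)
  sel <- select_frame_budget(masks, budget = 800)
  flat_m <- unlist(masks)
  flat_s <- unlist(sel$selected)
  retained_pos <- which(flat_m)
  expect_equal(which(flat_s), retained_pos[seq_len(sum(flat_s))])
})

test_that("demean/detrend removes exactly the affine component", {
  const <- matrix(5, 10, 2)
  expect_equal(demean_detrend(const), matrix(0, 10, 2), ignore_attr = TRUE)
  ramp <- cbind(seq_len(10) * 2 + 3, seq_len(10) * -1)
  expect_equal(max(abs(demean_detrend(ramp))), 0, tolerance = 1e-12)
  # ramp + spike: residual equals the spike minus its projection on {1, t}
  y <- c(1, 2, 3, 4, 5) + c(0, 0, 10, 0, 0)
  X <- cbind(1, 1:5)
  expect_equal(demean_detrend(matrix(y))[, 1],
               y - X %*% ols_oracle(X, y), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_error(demean_detrend(matrix(1, 2, 1)), "3 frames")
})

test_that("nuisance design has the 27-column layout", {
  set.seed(5)
  tr <- matrix(rnorm(60), 10, 6)
  X <- build_nuisance_regressors(tr, global_signal = rnorm(10),
                                 tissue_signals = matrix(rnorm(20), 10, 2))
  expect_equal(ncol(X), 27)
  expect_equal(ncol(build_nuisance_regressors(tr)), 24)
  zero <- build_nuisance_regressors(matrix(0, 10, 6))
  expect_equal(max(abs(zero)), 0)
  expect_error(build_nuisance_regressors(tr, global_signal = rnorm(9)),
               "length")
})

test_that("censor-aware nuisance regression matches the OLS oracle", {
  set.seed(8)
  x <- rnorm(10)
  y <- 2 * x + rnorm(10, 0, 0.3)
  res <- nuisance_regress(matrix(y), matrix(x, ncol = 1))
  X <- cbind(1, x)
  expect_equal(res[, 1], y - X %*% ols_oracle(X, y), ignore_attr = TRUE,
               tolerance = 1e-10)
  # a series equal to a regressor is annihilated
  res <- nuisance_regress(matrix(x), matrix(x, ncol = 1))
  expect_lt(max(abs(res)), 1e-10)
  # a series orthogonal to the design on retained frames is unchanged there
  mask <- rep(c(TRUE, FALSE), c(8, 2))
  z <- residuals(lm(rnorm(10) ~ x, weights = as.numeric(mask)))
  res <- nuisance_regress(matrix(z), matrix(x, ncol = 1), mask = mask)
  expect_equal(res[mask, 1], z[mask], tolerance = 1e-10,
               ignore_attr = TRUE)
  # collinear columns are dropped with a warning
  expect_warning(
    nuisance_regress(matrix(y), cbind(x, x), mask = NULL),
    "collinear")
  # coefficients estimated on retained frames only: a spike confined to
  # censored frames does not tilt the fit
  y2 <- x
  y2[9:10] <- y2[9:10] + 50
  res <- nuisance_regress(matrix(y2), matrix(x, ncol = 1), mask = mask)
  expect_lt(max(abs(res[mask, 1])), 1e-8)
})

test_that("band-pass filter has the expected frequency response", {
  t <- 0:999
  in_band <- sin(2 * pi * 0.04 * t)
  out <- interpolate_and_bandpass(matrix(in_band), mask = NULL)
  mid <- 300:700
  expect_equal(sd(out[mid, 1]) / sd(in_band[mid]), 1, tolerance = 0.05)
  high <- sin(2 * pi * 0.2 * t)
  out <- interpolate_and_bandpass(matrix(high), mask = NULL)
  expect_lt(sd(out[mid, 1]) / sd(high[mid]), 0.10)
  const <- interpolate_and_bandpass(matrix(rep(3, 1000)), mask = NULL)
  expect_lt(max(abs(const[mid, 1])), 1e-4)
  expect_error(interpolate_and_bandpass(matrix(rnorm(10)), mask = NULL),
               "exclude")
})

test_that("interpolation keeps censored spikes out of the filtered signal", {
  t <- 0:999
  clean <- sin(2 * pi * 0.03 * t)
  spiked <- clean
  spiked[500] <- 80
  mask <- rep(TRUE, 1000); mask[500] <- FALSE
  ref <- interpolate_and_bandpass(matrix(clean), mask = NULL)
  for (method in c("linear", "spectral")) {
    got <- interpolate_and_bandpass(matrix(spiked), mask = mask,
                                    method = method)
    expect_lt(max(abs(got[300:700, 1] - ref[300:700, 1])), 0.05)
  }
})

test_that("rms FD summarizes motion as the root mean square", {
  expect_equal(fd_summary(rep(0, 10)), 0)
  expect_equal(fd_summary(c(0.3, 0.4)), sqrt((0.09 + 0.16) / 2),
               tolerance = 1e-12)
  expect_equal(fd_summary(rep(0.17, 25)), 0.17)
  expect_equal(fd_summary(list(c(0.3), c(0.4))), fd_summary(c(0.3, 0.4)))
})

test_that("subject cleaning records the fixed stage order and budgets frames", {
  spec <- cohort_spec(n_subjects = 1, n_rois = 42, n_frames = 900,
                      n_runs = 2, seed = 3)
  b <- generate_cohort(spec)
  cl <- clean_subject(b$timeseries[[1]], b$motion[[1]],
                      frame_budget = 500)
  expect_equal(cl$provenance,
               c("compute_fd", "build_censor_mask", "demean_detrend",
                 "nuisance_regress", "interpolate_and_bandpass",
                 "recensor", "select_frame_budget"))
  expect_true(cl$included)
  expect_equal(sum(vapply(cl$selected, sum, 0L)), 500)
  expect_equal(length(cl$ts), 2)
})
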