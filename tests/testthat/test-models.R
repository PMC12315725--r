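test_that("FD residualization matches the normal-equations oracle", {
  fd <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  y <- c(1.0, 0.8, 1.2, 0.6, 1.4)
  d <- data.frame(segregation = y)
  got <- residualize_fd(d, fd)$segregation
  X <- cbind(1, fd)
  expect_equal(got, y - X %*% ols_oracle(X, y), ignore_attr = TRUE,
               tolerance = 1e-10)
  # a measure proportional to FD is annihilated
  d2 <- data.frame(segregation = 2 * fd)
  expect_lt(max(abs(residualize_fd(d2, fd)$segregation)), 1e-12)
  # uncorrelated measure comes back demeaned
  y3 <- c(1, -1, 1, -1, 0)
  y3 <- residuals(lm(y3 ~ fd)) + 5
  d3 <- data.frame(segregation = y3)
  expect_equal(residualize_fd(d3, fd)$segregation, y3 - mean(y3),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_warning(residualize_fd(d, rep(0.3, 5)), "constant")
})

test_that("age standardization reproduces the lifespan anchors", {
  scale <- list(mean = 34.06, sd = 21.06)
  expect_equal(as.numeric(standardize_age(34.06, scale)), 0)
  expect_equal(as.numeric(standardize_age(55.12, scale)), 1.0)
  expect_equal(unstandardize_age(1.0, scale), 55.12)
  z <- standardize_age(c(10, 20, 30))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
})

test_that("age models recover noiseless effects and match the OLS oracle", {
  age_z <- seq(-2, 2, length.out = 20)
  # noiseless recovery; lm warns about the saturated fit, by design here
  f <- suppressWarnings(fit_age_model(3 * age_z, age_z))
  expect_false(f$quadratic)
  expect_equal(f$coefficients$B[f$coefficients$term == "age_z"], 3,
               tolerance = 1e-10)
  f2 <- suppressWarnings(fit_age_model(-age_z^2 + 0.5 * age_z, age_z))
  expect_true(f2$quadratic)
  expect_equal(f2$coefficients$B[f2$coefficients$term == "I(age_z^2)"], -1,
               tolerance = 1e-10)
  # 8-point toy against the normal equations
  set.seed(3)
  a8 <- rnorm(8)
  y8 <- 1 + 0.5 * a8 - 0.3 * a8^2 + rnorm(8, 0, 0.1)
  f3 <- fit_age_model(y8, a8, quadratic = "on")
  X <- cbind(1, a8, a8^2)
  expect_equal(f3$coefficients$B, unname(ols_oracle(X, y8)),
               tolerance = 1e-10)
})

test_that("all OLS fits agree with the normal equations on small instances", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(15:50, 1)
    k <- sample(1:4, 1)
    d <- as.data.frame(matrix(rnorm(n * k), n, k))
    names(d) <- paste0("x", seq_len(k))
    d$y <- rnorm(n)
    f <- fit_ols(y ~ ., d)
    X <- cbind(1, as.matrix(d[paste0("x", seq_len(k))]))
    expect_equal(f$coefficients$B, unname(ols_oracle(X, d$y)),
                 tolerance = 1e-10)
  }
  expect_error(fit_ols(y ~ x, data.frame(y = 1:4, x = c(1, 2, 3, 4))),
               "n > terms")
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(fdr_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
         0.216, 0.222, 0.251)
  # exact equality with the definitional oracle under every permutation
  set.seed(2)
  for (rep in 1:25) {
    perm <- sample(length(p))
    expect_equal(fdr_adjust(p[perm]), bh_oracle(p[perm]))
  }
  set.seed(4)
  for (rep in 1:25) {
    q <- runif(sample(3:15, 1))
    expect_equal(fdr_adjust(q), bh_oracle(q))
  }
})

test_that("bias models carry the age covariate and match the oracle", {
  set.seed(21)
  n <- 40
  age_z <- rnorm(n)
  x <- rnorm(n)
  bias <- 50 + 4 * age_z  # noiseless, no predictor effect
  f <- suppressWarnings(fit_bias_model(bias, data.frame(x = x), age_z))
  expect_equal(f$coefficients$B[f$coefficients$term == "x"], 0,
               tolerance = 1e-9)
  y <- 50 + 4 * age_z + 3 * x + rnorm(n)
  f2 <- fit_bias_model(y, data.frame(x = x), age_z)
  X <- cbind(1, age_z, x)
  expect_equal(f2$coefficients$B, unname(ols_oracle(X, y)),
               tolerance = 1e-10)
})

test_that("backward elimination follows the greedy AIC path exactly", {
  # oracle: independent greedy AIC search straight from lm/AIC
  greedy_oracle <- function(d, response, cands, forced) {
    cur <- sort(cands)
    fit_aic <- function(terms) AIC(lm(stats::reformulate(c(forced, terms,
                                                           "1"), response),
                                      data = d))
    a_cur <- fit_aic(cur)
    repeat {
      if (!length(cur)) break
      aics <- vapply(cur, function(tm) fit_aic(setdiff(cur, tm)), 0)
      best <- names(aics)[order(aics, names(aics))][1]
      if (aics[best] >= a_cur) break
      cur <- setdiff(cur, best)
      a_cur <- aics[best]
    }
    cur
  }
  set.seed(9)
  for (rep in 1:5) {
    n <- 30
    d <- data.frame(age_z = rnorm(n), a = rnorm(n), b = rnorm(n),
                    c = rnorm(n))
    d$y <- 2 * d$age_z + 1.5 * d$a + rnorm(n)
    got <- backward_eliminate(d, "y", c("a", "b", "c"), forced = "age_z")
    expect_equal(sort(got$selected),
                 sort(greedy_oracle(d, "y", c("a", "b", "c"), "age_z")))
    # AIC never increases along accepted removals; forced term survives
    if (nrow(got$trace))
      expect_true(all(got$trace$aic_after < got$trace$aic_before))
    expect_true("age_z" %in% got$fit$coefficients$term)
    expect_lte(got$fit$aic,
               fit_ols(y ~ age_z + a + b + c, d)$aic + 1e-9)
  }
})

test_that("elimination keeps a true effect and prunes noise candidates", {
  set.seed(17)
  kept_true <- 0
  removed_noise <- numeric(20)
  for (s in 1:20) {
    n <- 500
    d <- as.data.frame(matrix(rnorm(n * 11), n, 11))
    names(d) <- c("signal", paste0("noise", 1:10))
    d$age_z <- rnorm(n)
    d$y <- 1.0 * d$signal + 0.5 * d$age_z + rnorm(n, 0, 0.5)
    got <- backward_eliminate(d, "y", setdiff(names(d), c("y", "age_z")),
                              forced = "age_z")
    kept_true <- kept_true + ("signal" %in% got$selected)
    removed_noise[s] <- 10 - sum(grepl("^noise", got$selected))
  }
  expect_equal(kept_true, 20)
  expect_gte(mean(removed_noise), 8)
})

test_that("interaction screening retains planted moderation and little else", {
  retained_true <- 0
  false_pos <- 0
  for (s in 1:30) {
    spec <- cohort_spec(n_subjects = 250, seed = 500 + s)
    b <- generate_cohort(spec, include_timeseries = FALSE,
                         include_motion = FALSE, include_trials = FALSE)
    d <- data.frame(y = b$subjects$true_bias, age_z = b$subjects$age_z,
                    co = b$subjects$delta_co, van = b$subjects$delta_van,
                    reward = b$subjects$delta_reward)
    sc <- screen_interactions(d, "y", c("co", "van", "reward"))
    retained_true <- retained_true + ("reward:age_z" %in% sc$interactions)
    false_pos <- false_pos + sum(c("co:age_z", "van:age_z") %in%
                                   sc$interactions)
  }
  expect_gte(retained_true, 27)           # planted age x Reward moderation
  expect_lte(false_pos / 60, 0.15)        # null interactions near alpha
})

test_that("simple slopes reproduce the reported final-model arithmetic", {
  f <- fit_from_coefs(c("dmn_reward", "dmn_reward:age_z"),
                      B = c(-6.435, -9.029), SE = c(4.311, 4.218),
                      df_residual = 215)
  s <- simple_slopes(f, "dmn_reward", "dmn_reward:age_z", at = c(-1, 0, 1))
  expect_equal(round(s$slope[s$at == 1], 2), -15.46)
  expect_equal(s$slope[s$at == 0], -6.435)
  expect_equal(s$slope[s$at == -1], 2.594)
  # SE at the mean equals the focal term's SE
  expect_equal(s$SE[s$at == 0], 4.311)
})

test_that("Johnson-Neyman boundaries satisfy their defining equation", {
  set.seed(33)
  n <- 120
  a <- rnorm(n); x <- rnorm(n)
  y <- 0.3 * x + 0.8 * x * a + rnorm(n)
  f <- fit_ols(y ~ a + x + a:x, data.frame(y = y, a = a, x = x))
  jn <- johnson_neyman(f, "x", "a:x")
  expect_length(jn$boundaries, 2)
  s <- simple_slopes(f, "x", "a:x", at = jn$boundaries)
  expect_equal(abs(s$t), rep(jn$t_crit, 2), tolerance = 1e-6)
  # grid-search oracle agreement on a toy fit
  f2 <- fit_from_coefs(c("x", "x:m"), B = c(0, 1), SE = sqrt(c(0.01, 0.01)),
                       df_residual = 10000)
  jn2 <- johnson_neyman(f2, "x", "x:m")
  oracle <- jn_grid_oracle(0, 1, 0.01, 0.01, 0, jn2$t_crit)
  expect_equal(sort(jn2$boundaries), sort(oracle), tolerance = 1e-4)
  # raw-unit conversion through the lifespan age scale
  jn3 <- johnson_neyman(f, "x", "a:x",
                        scale = list(mean = 34.06, sd = 21.06))
  expect_equal(jn3$boundaries_raw, 34.06 + 21.06 * jn3$boundaries)
  expect_equal(unstandardize_age(1, list(mean = 34.06, sd = 21.06)), 55.12)
})

test_that("Johnson-Neyman is invariant to rescaling the outcome", {
  set.seed(44)
  n <- 90
  a <- rnorm(n); x <- rnorm(n)
  y <- 0.4 * x + 0.6 * x * a + rnorm(n)
  d <- data.frame(y = y, y10 = 10 * y, a = a, x = x)
  j1 <- johnson_neyman(fit_ols(y ~ a + x + a:x, d), "x", "a:x")
  j2 <- johnson_neyman(fit_ols(y10 ~ a + x + a:x, d), "x", "a:x")
  expect_equal(j1$boundaries, j2$boundaries, tolerance = 1e-9)
  expect_equal(j1$region, j2$region)
})

test_that("Johnson-Neyman handles no-root and degenerate cases", {
  # strong effect, negligible interaction: significant everywhere
  f <- fit_from_coefs(c("x", "x:m"), B = c(5, 1e-13), SE = c(0.1, 1e-160),
                      df_residual = 100)
  expect_equal(johnson_neyman(f, "x", "x:m")$region, "everywhere")
  f0 <- fit_from_coefs(c("x", "x:m"), B = c(0.01, 1e-13),
                       SE = c(0.1, 1e-160), df_residual = 100)
  expect_equal(johnson_neyman(f0, "x", "x:m")$region, "nowhere")
})

test_that("the extreme-outlier rule flags only gross deviations", {
  expect_length(detect_outliers(rep(2.5, 10)), 0)
  set.seed(10)
  x <- c(rnorm(100), 50)
  idx <- detect_outliers(x)
  expect_equal(as.integer(idx), 101L)
  expect_equal(attr(idx, "values"), 50)
  expect_equal(as.integer(detect_outliers(-x)), 101L)
})
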