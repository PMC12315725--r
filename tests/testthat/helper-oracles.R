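# Independent oracles used to check the implementation. Deliberately written
# as plain, slow reference code with no shared internals.

# OLS via the normal equations.
ols_oracle <- function(X, y) {
  X <- as.matrix(X)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Censoring rules by explicit scan: threshold, then walk the retained
# segments and drop short ones, then the run-length rule.
censor_oracle <- function(fd, threshold = 0.2, min_segment = 5,
                          min_run = 50) {
  keep <- fd <= threshold
  n <- length(keep)
  i <- 1
  while (i <= n) {
    if (keep[i]) {
      j <- i
      while (j < n && keep[j + 1]) j <- j + 1
      if (j - i + 1 < min_segment) keep[i:j] <- FALSE
      i <- j + 1
    } else i <- i + 1
  }
  if (sum(keep) < min_run) keep[] <- FALSE
  keep
}

# Network measures by brute-force double loop over all ROI pairs.
netmeas_oracle <- function(z, labels) {
  nets <- unique(labels)
  n <- nrow(z)
  w_sum <- w_n <- b_sum <- b_n <- setNames(numeric(length(nets)), nets)
  pair_sum <- pair_n <- matrix(0, length(nets), length(nets),
                               dimnames = list(nets, nets))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- labels[i]; b <- labels[j]
    if (a == b) {
      if (i < j) { w_sum[a] <- w_sum[a] + z[i, j]; w_n[a] <- w_n[a] + 1 }
    } else {
      b_sum[a] <- b_sum[a] + z[i, j]; b_n[a] <- b_n[a] + 1
      pair_sum[a, b] <- pair_sum[a, b] + z[i, j]
      pair_n[a, b] <- pair_n[a, b] + 1
    }
  }
  zw <- w_sum / w_n
  zb <- b_sum / b_n
  list(within = zw, between = zb, segregation = (zw - zb) / zw,
       pairwise = pair_sum / pair_n,
       global = c(W = mean(zw), B = mean(zb),
                  segregation = (mean(zw) - mean(zb)) / mean(zw)))
}

# Benjamini-Hochberg step-up from its definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Johnson-Neyman boundaries by grid search + bisection on |t(a)| - t_crit.
jn_grid_oracle <- function(bf, bi, vf, vi, cv, t_crit,
                           lo = -10, hi = 10, step = 0.001) {
  g <- function(a) abs((bf + bi * a) / sqrt(vf + a^2 * vi + 2 * a * cv)) -
    t_crit
  grid <- seq(lo, hi, by = step)
  vals <- g(grid)
  roots <- c()
  for (i in seq_len(length(grid) - 1)) {
    if (is.finite(vals[i]) && is.finite(vals[i + 1]) &&
        vals[i] * vals[i + 1] < 0)
      roots <- c(roots, uniroot(g, c(grid[i], grid[i + 1]),
                                tol = 1e-10)$root)
  }
  roots
}

# Small trial-table factory for behavior tests.
make_trials <- function(n_amb_pos, n_amb_neg, n_clear_correct = 48,
                        n_clear_wrong = 0, n_amb_none = 0) {
  amb_resp <- rep(c("positive", "negative", "none"),
                  c(n_amb_pos, n_amb_neg, n_amb_none))
  amb <- data.frame(valence_class = rep("ambiguous", length(amb_resp)),
                    response = amb_resp)
  ncl <- n_clear_correct + n_clear_wrong
  cls <- rep(c("clear_positive", "clear_negative"), length.out = ncl)
  correct <- rep(c(TRUE, FALSE), c(n_clear_correct, n_clear_wrong))
  resp <- ifelse(cls == "clear_positive", "positive", "negative")
  resp[!correct] <- ifelse(resp[!correct] == "positive",
                           "negative", "positive")
  clear <- data.frame(valence_class = cls, response = resp)
  out <- rbind(amb, clear)
  out$trial_id <- seq_len(nrow(out))
  out$block <- rep(1:4, length.out = nrow(out))
  out$stimulus_type <- rep(c("face", "scene"), length.out = nrow(out))
  out
}

# Symmetric non-negative test matrix with NA diagonal.
random_z_matrix <- function(n) {
  z <- matrix(runif(n * n, 0, 0.8), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- NA
  z
}
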