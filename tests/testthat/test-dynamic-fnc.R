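test_that("sliding windows honour the count formula and boundaries", {
  tc <- icn_timecourses(matrix(rnorm(400 * 4), 400, 4))
  w <- sliding_windows(tc, dfnc_config(window_tr = 20, step_tr = 1))
  expect_length(w$segments, 381L)
  expect_equal(w$window_starts[1:3], c(1, 2, 3))

  tc20 <- icn_timecourses(matrix(rnorm(20 * 4), 20, 4))
  w1 <- sliding_windows(tc20, dfnc_config(window_tr = 20))
  expect_length(w1$segments, 1L)
  expect_equal(w1$segments[[1]], tc20$data)

  # step = window partitions the series
  w2 <- sliding_windows(tc, dfnc_config(window_tr = 20, step_tr = 20))
  expect_equal(do.call(rbind, w2$segments), tc$data)

  expect_error(sliding_windows(tc20, dfnc_config(window_tr = 40)), "short")
})

test_that("graphical lasso shrinks as expected in closed-form cases", {
  # full shrinkage: independent columns + large penalty -> identity
  set.seed(1)
  seg <- matrix(rnorm(200 * 4), 200, 4)
  R <- glasso_fnc(seg, dfnc_config(glasso_lambda = 2, tol = 1e-8))
  expect_equal(unclass(R), diag(4), tolerance = 1e-8, ignore_attr = TRUE)

  # 2 x 2: off-diagonal equals soft(s12, lambda) / (1 + lambda)
  set.seed(2)
  x <- rnorm(50)
  seg2 <- cbind(x, 0.9 * x + 0.3 * rnorm(50))
  s12 <- cor(seg2)[1, 2]
  lam <- 0.2
  R2 <- glasso_fnc(seg2, dfnc_config(glasso_lambda = lam, tol = 1e-9,
                                     max_iter = 2000))
  expect_equal(R2[1, 2], sign(s12) * max(abs(s12) - lam, 0) / (1 + lam),
               tolerance = 1e-7)
  expect_lt(abs(R2[1, 2]), abs(s12))
  expect_equal(sign(R2[1, 2]), sign(s12))

  # unpenalized limit: lambda -> 0 with many rows recovers the sample
  # correlation
  set.seed(3)
  seg3 <- matrix(rnorm(500 * 5), 500, 5) %*% matrix(rnorm(25), 5)
  R3 <- glasso_fnc(seg3, dfnc_config(glasso_lambda = 1e-7, tol = 1e-9,
                                     max_iter = 2000))
  expect_equal(unclass(R3), cor(seg3), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("graphical lasso agrees with a proximal-gradient oracle", {
  set.seed(4)
  for (p in c(2, 5)) {
    seg <- matrix(rnorm(60 * p), 60, p) %*% matrix(rnorm(p * p), p)
    S <- cor(seg)
    lam <- 0.15
    R <- glasso_fnc(seg, dfnc_config(glasso_lambda = lam, tol = 1e-9,
                                     max_iter = 5000))
    Th <- oracle_glasso_precision(S, lam)
    expect_lt(max(abs(unclass(R) - cov2cor(solve(Th)))), 1e-6)
    expect_lt(max(abs(attr(R, "precision") - Th)), 1e-6)
  }
})

test_that("penalty increase never inflates the two-variable precision", {
  set.seed(5)
  x <- rnorm(80)
  seg <- cbind(x, 0.7 * x + 0.5 * rnorm(80))
  lams <- c(0.01, 0.05, 0.1, 0.2, 0.4)
  offs <- vapply(lams, function(l) {
    R <- glasso_fnc(seg, dfnc_config(glasso_lambda = l, tol = 1e-9,
                                     max_iter = 2000))
    abs(attr(R, "precision")[1, 2])
  }, 0)
  expect_true(all(diff(offs) <= 1e-8))
})

test_that("windowed estimates are SPD and fluctuate around the static FNC", {
  cfg <- cohort_config(n_subjects = 1, n_icns = 8, n_timepoints = 300,
                       n_latent_states = 1, spike_rate = 0, drift_sd = 0,
                       motion_coupling = 0, seed = 6)
  coh <- generate_cohort(cfg)
  tc <- coh$timecourses[[1]]
  wf <- compute_dfnc(tc, dfnc_config(window_tr = 20, step_tr = 4,
                                     glasso_lambda = 0.1))
  expect_equal(dim(wf$values), c(71, 8, 8))
  ev <- apply(wf$values, 1, function(v)
    min(eigen(matrix(v, 8, 8), symmetric = TRUE, only.values = TRUE)$values))
  expect_gt(min(ev), 0)
  expect_true(all(abs(apply(wf$values, 1, function(v) diag(matrix(v, 8, 8))) - 1) < 1e-10))

  # mean across windows approximates the (shrunk) static estimate
  static <- compute_sfnc(tc)
  mean_w <- apply(wf$values, c(2, 3), mean)
  ut <- upper.tri(static)
  expect_gt(cor(mean_w[ut], static[ut]), 0.9)
})

test_that("two-state scans show state-dependent window connectivity", {
  cfg <- cohort_config(n_subjects = 1, n_icns = 6, n_timepoints = 400,
                       n_latent_states = 2, state_dwell = 100,
                       dwell_log_sd = 0, spike_rate = 0, drift_sd = 0,
                       motion_coupling = 0, seed = 7)
  coh <- generate_cohort(cfg)
  key <- names(coh$timecourses)[1]
  seq_s <- coh$ground_truth$state_sequences[[key]]
  wf <- compute_dfnc(coh$timecourses[[key]],
                     dfnc_config(window_tr = 20, step_tr = 1))
  vec <- vectorize_windows(wf)
  states <- coh$ground_truth$state_corr
  ut_idx <- cbind(upper_pair_index(6)$i, upper_pair_index(6)$j)
  targets <- lapply(states, function(m) m[ut_idx])
  # windows fully inside one state sit closer to that state's correlation
  purity <- vapply(seq_along(wf$window_starts), function(w) {
    rows <- wf$window_starts[w]:(wf$window_starts[w] + 19)
    s_in <- seq_s[rows]
    if (length(unique(s_in)) > 1L) return(NA_integer_)
    unique(s_in)
  }, 1L)
  pure <- which(!is.na(purity))
  d <- vapply(pure, function(w) {
    v <- vec[w, ]
    d1 <- sqrt(mean((v - targets[[1]])^2))
    d2 <- sqrt(mean((v - targets[[2]])^2))
    ifelse(purity[w] == 1L, d1 < d2, d2 < d1)
  }, TRUE)
  expect_gt(mean(d), 0.8)
})
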