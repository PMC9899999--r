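test_that("cohort bookkeeping: shapes, naming, and phenotype rows", {
  cfg <- cohort_config(n_subjects = 10, n_icns = 53, n_timepoints = 400,
                       seed = 2)
  coh <- generate_cohort(cfg)
  expect_length(coh$timecourses, 20L)
  expect_true(all(vapply(coh$timecourses, function(tc)
    identical(dim(tc$data), c(400L, 53L)), TRUE)))
  expect_equal(nrow(coh$phenotype), 10L)
  expect_setequal(names(coh$timecourses),
                  paste0(rep(sprintf("S%02d", 1:10), each = 2), "_",
                         c("v1", "v3")))
  expect_false(anyNA(coh$ground_truth$delta_static))
})

test_that("zero effects and zero noise give exactly zero outcome change", {
  cfg <- cohort_config(n_subjects = 5, n_icns = 8, n_timepoints = 60,
                       noise_sd = 0, spike_rate = 0, seed = 4)
  coh <- generate_cohort(cfg)
  pct <- percentage_change(coh$phenotype$score_v1, coh$phenotype$score_v3)
  expect_equal(pct, rep(0, 5))
})

test_that("identical seed reproduces the cohort bit for bit", {
  cfg <- cohort_config(n_subjects = 3, n_icns = 6, n_timepoints = 80,
                       seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$timecourses[["S02_v3"]]$data,
                   b$timecourses[["S02_v3"]]$data)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$ground_truth$signal, b$ground_truth$signal)
})

test_that("single-state time courses converge to the generating correlation", {
  cfg <- cohort_config(n_subjects = 1, n_icns = 6, n_timepoints = 6000,
                       n_latent_states = 1, spike_rate = 0, drift_sd = 0,
                       motion_coupling = 0, seed = 8)
  coh <- generate_cohort(cfg)
  emp <- cor(coh$timecourses[[1]]$data)
  truth <- coh$ground_truth$state_corr[[1]]
  # Monte-Carlo error of a correlation at T = 6000 is below ~0.013 per
  # entry; allow a generous multiple across the whole matrix
  expect_lt(max(abs(emp - truth)), 0.07)
})

test_that("realized dwell times match the configured mean", {
  cfg <- cohort_config(n_subjects = 10, n_icns = 6, n_timepoints = 2000,
                       n_latent_states = 3, state_dwell = 25,
                       dwell_log_sd = 0, seed = 13)
  coh <- generate_cohort(cfg)
  dwells <- unlist(lapply(coh$ground_truth$state_sequences, function(s) {
    r <- rle(s)
    # drop the truncated final run
    head(r$lengths, -1L)
  }))
  se <- sd(dwells) / sqrt(length(dwells))
  expect_lt(abs(mean(dwells) - 25), 4 * se + 1)
})

test_that("static effects drive outcomes; dynamism stays independent", {
  p_feat <- 10 * 9 / 2
  eff <- c(rep(20, 5))
  names(eff) <- 1:5
  cfg <- cohort_config(n_subjects = 120, n_icns = 10, n_timepoints = 60,
                       effect_static = eff, noise_sd = 1,
                       static_delta_sd = 0.15, seed = 21)
  coh <- generate_cohort(cfg)
  pct <- percentage_change(coh$phenotype$score_v1, coh$phenotype$score_v3)
  planted_sum <- coh$ground_truth$delta_static[, 1:5] %*% rep(1, 5)
  expect_gt(cor(pct, planted_sum), 0.8)
  dyn_cor <- suppressWarnings(cor(pct, coh$ground_truth$delta_dynamism))
  expect_true(all(abs(dyn_cor) < 0.35, na.rm = TRUE))
})

test_that("oracle R-squared calibration hits the requested value", {
  eff <- c("1" = 25, "5" = 25, "9" = 25)
  cfg <- cohort_config(n_subjects = 200, n_icns = 8, n_timepoints = 60,
                       effect_static = eff, target_r2 = 0.4, seed = 5)
  coh <- generate_cohort(cfg)
  expect_equal(coh$ground_truth$oracle_r2, 0.4, tolerance = 1e-10)
  pct <- percentage_change(coh$phenotype$score_v1, coh$phenotype$score_v3)
  r2_emp <- cor(pct, coh$ground_truth$signal)^2
  expect_gt(r2_emp, 0.25)
  expect_lt(r2_emp, 0.55)
})

test_that("invalid configurations and states are rejected", {
  expect_error(cohort_config(n_icns = 1), "n_icns")
  expect_error(cohort_config(n_timepoints = 20), "admit")
  expect_error(cohort_config(spike_rate = 1), "spike_rate")
  expect_error(cohort_config(effect_dynamism = 1:3), "length 4")
  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 1.5  # not positive definite
  expect_error(
    cohort_config(n_icns = 4, n_latent_states = 1,
                  state_corr = list(bad)),
    "positive definite")
})
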