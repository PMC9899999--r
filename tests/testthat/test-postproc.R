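make_tc <- function(X, motion = NULL, tr = 0.745) {
  icn_timecourses(X, motion, tr_seconds = tr)
}

test_that("polynomial detrending removes exactly the fitted trends", {
  t_idx <- 1:200
  X <- cbind(5 + 2 * t_idx + t_idx^2 + t_idx^3,
             -3 + 0.5 * t_idx)
  out <- detrend_polynomial(make_tc(X), order = 3)
  expect_lt(max(abs(out$data)), 1e-6)

  # order 0 is mean-centering only
  set.seed(1)
  X <- matrix(rnorm(300), 100, 3) + 7
  out0 <- detrend_polynomial(make_tc(X), order = 0)
  expect_equal(out0$data, scale(X, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)

  # residuals orthogonal to the polynomial basis (QR oracle)
  out3 <- detrend_polynomial(make_tc(X), order = 3)
  basis <- cbind(1, poly(1:100, 3))
  expect_lt(max(abs(crossprod(basis, out3$data))), 1e-8)
  oracle <- qr.resid(qr(basis), X)
  expect_equal(out3$data, oracle, ignore_attr = TRUE, tolerance = 1e-10)

  expect_error(detrend_polynomial(make_tc(X[1:4, ]), order = 3), "degenerate")
})

test_that("motion regression residualizes against parameters and derivatives", {
  set.seed(2)
  motion <- matrix(rnorm(600), 100, 6)
  X <- cbind(3 * motion[, 1], rnorm(100))
  out <- regress_nuisance(make_tc(X, motion))
  expect_lt(max(abs(out$data[, 1])), 1e-8)

  # residuals orthogonal to the full design; match a QR oracle
  design <- cbind(1, motion, rbind(0, diff(motion)))
  expect_lt(max(abs(crossprod(design, out$data))), 1e-6)
  oracle <- qr.resid(qr(design), X)
  expect_equal(out$data, oracle, ignore_attr = TRUE, tolerance = 1e-10)

  # all-zero motion collapses to mean-centering (rank-deficiency warned)
  expect_warning(out0 <- regress_nuisance(make_tc(X, matrix(0, 100, 6))),
                 "rank deficient")
  expect_equal(out0$data, scale(X, scale = FALSE), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("despiking flags planted spikes and interpolates them", {
  x <- rep(2, 50)
  x[25] <- 100
  out <- despike(make_tc(cbind(x, rnorm(50))), threshold = 4)
  mask <- attr(out, "spike_mask")
  expect_true(mask[25, 1])
  expect_equal(unname(out$data[25, 1]), 2)

  # conservative threshold on clean Gaussian noise: no flags
  set.seed(3)
  clean <- matrix(rnorm(400), 200, 2)
  out2 <- despike(make_tc(clean), threshold = 10)
  expect_equal(sum(attr(out2, "spike_mask")), 0L)

  # generator-planted spikes are mostly recovered at the default threshold
  coh <- tiny_cohort(n_subjects = 2, n_icns = 6, n_timepoints = 300,
                     seed = 9, spike_rate = 0.01)
  hits <- 0; planted <- 0
  for (key in names(coh$timecourses)) {
    tc <- despike(coh$timecourses[[key]], threshold = 4)
    mask <- attr(tc, "spike_mask")
    truth <- coh$ground_truth$spike_masks[[key]]
    hits <- hits + sum(mask & truth)
    planted <- planted + sum(truth)
  }
  expect_gt(planted, 0)
  expect_gt(hits / planted, 0.8)
})

test_that("band-pass keeps passband amplitude and rejects stopband and DC", {
  tr <- 0.745
  t_sec <- (0:1999) * tr
  cfg <- postproc_config()
  amp <- function(x) sqrt(mean(x^2)) * sqrt(2)

  pass <- sin(2 * pi * 0.05 * t_sec)
  out <- bandpass(make_tc(cbind(pass, pass)), cfg)
  expect_equal(amp(out$data[500:1500, 1]), 1, tolerance = 0.05)

  stopb <- sin(2 * pi * 0.4 * t_sec)
  outs <- bandpass(make_tc(cbind(stopb, stopb)), cfg)
  expect_lt(amp(outs$data[500:1500, 1]), 0.1)

  dc <- matrix(5, 2000, 2)
  outd <- bandpass(make_tc(dc), cfg)
  expect_lt(max(abs(outd$data)), 1e-6)

  expect_error(bandpass(make_tc(cbind(pass, pass)),
                        postproc_config(band_high_hz = 0.7)), "Nyquist")
})

test_that("the chain applies in order and its null configuration is identity", {
  coh <- tiny_cohort(seed = 10, spike_rate = 0.02)
  tc <- coh$timecourses[[1]]

  off <- postproc_config(do_detrend = FALSE, do_regress = FALSE,
                         do_despike = FALSE, do_bandpass = FALSE)
  expect_identical(postprocess(tc, off)$data, tc$data)

  # swapping filtering before despiking changes the result on spiked input
  cfg <- postproc_config()
  standard <- postprocess(tc, cfg)
  swapped <- bandpass(despike(regress_nuisance(
    detrend_polynomial(tc, cfg$detrend_order)),
    cfg$despike_mad_threshold), cfg)
  reversed <- despike(bandpass(regress_nuisance(
    detrend_polynomial(tc, cfg$detrend_order)), cfg),
    cfg$despike_mad_threshold)
  expect_equal(standard$data, swapped$data, tolerance = 1e-10)
  expect_gt(max(abs(swapped$data - reversed$data)), 1e-3)

  # contract: no missing values, near-zero column means
  out <- postprocess(tc, cfg)
  expect_false(anyNA(out$data))
  expect_lt(max(abs(colMeans(out$data))), 0.05)
})

test_that("detrending and nuisance regression are projections", {
  coh <- tiny_cohort(seed = 12)
  tc <- coh$timecourses[[2]]
  d1 <- detrend_polynomial(tc, 3)
  d2 <- detrend_polynomial(d1, 3)
  expect_equal(d1$data, d2$data, tolerance = 1e-8)
  r1 <- regress_nuisance(tc)
  r2 <- regress_nuisance(r1)
  expect_equal(r1$data, r2$data, tolerance = 1e-8)
})
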