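test_that("percentage change follows the baseline-minus-followup convention", {
  expect_equal(percentage_change(40, 10), 75)
  expect_equal(percentage_change(20, 20), 0)
  expect_equal(percentage_change(20, 25), -25)
  expect_equal(percentage_change(c(40, 20), c(10, 25)), c(75, -25))
  expect_error(percentage_change(0, 5), "zero baseline")
})

test_that("PLS regression matches oracles and exact special cases", {
  # rank-1: outcome exactly linear in one feature; with mutually
  # orthogonal predictors a single component reproduces it exactly
  set.seed(1)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(30 * 6), 30, 6))))[, 2:7] * 5
  y <- 2 + 3 * X[, 4]
  fit <- plsr_fit(X, y, 1)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)

  # independently coded SIMPLS oracle on random 20 x 10 problems
  set.seed(2)
  for (i in 1:5) {
    Xr <- matrix(rnorm(200), 20, 10)
    yr <- rnorm(20)
    for (a in c(1, 4, 7)) {
      expect_equal(coef(plsr_fit(Xr, yr, a)), oracle_simpls(Xr, yr, a),
                   tolerance = 1e-8)
    }
  }

  # full-rank limit equals ordinary least squares
  Xf <- matrix(rnorm(200), 20, 10)
  yf <- rnorm(20)
  b_pls <- coef(plsr_fit(Xf, yf, 10))
  b_ols <- unname(coef(lm(yf ~ Xf))[-1])
  expect_equal(b_pls, b_ols, tolerance = 1e-8)

  expect_error(plsr_fit(Xf, rep(1, 20), 2), "zero-variance")
  expect_error(plsr_fit(Xf, yf, 25), "n_components")
})

test_that("repeated CV is deterministic, honest under the null, and sized", {
  set.seed(3)
  X <- matrix(rnorm(40 * 25), 40, 25)
  y <- rnorm(40)
  a <- repeated_cv(X, y, folds = 5, repetitions = 20, n_components = 3,
                   select = "fixed", seed = 42)
  b <- repeated_cv(X, y, folds = 5, repetitions = 20, n_components = 3,
                   select = "fixed", seed = 42)
  expect_identical(a$per_repetition_r, b$per_repetition_r)
  expect_identical(a$coefficient_maps, b$coefficient_maps)
  expect_equal(nrow(a$coefficient_maps), 100L)

  # pure-noise outcome: mean r near zero (cross-validated r skews slightly
  # negative under the null)
  expect_lt(abs(mean(a$per_repetition_r)), 0.25)
  expect_true(all(abs(a$per_repetition_r) <= 1))

  expect_error(repeated_cv(X, y, folds = 30, repetitions = 2), "folds")
})

test_that("repeated CV recovers a planted linear signal", {
  set.seed(4)
  n <- 100
  X <- matrix(rnorm(n * 10), n, 10)
  signal <- 2 * X[, 1]
  noise <- rnorm(n, sd = sd(signal))      # oracle R2 = 0.5
  y <- as.numeric(signal + noise)
  res <- repeated_cv(X, y, folds = 10, repetitions = 30, seed = 9)
  oracle_r <- as.numeric(cor(signal, y))
  band <- tanh(atanh(oracle_r) + c(-1.96, 1.96) / sqrt(n - 3))
  m <- mean(res$per_repetition_r)
  expect_gt(m, band[1])
  expect_lt(m, band[2])
})

test_that("permutation test honours its formula and order properties", {
  set.seed(5)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- as.numeric(X[, 1] * 3 + rnorm(30, sd = 0.5))
  pt <- permutation_test(X, y, folds = 5, repetitions = 2,
                         n_components = 2, select = "fixed",
                         n_perm = 100, seed = 1)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_distribution >= pt$observed)) / 101)
  # strong signal: observed beats every permutation
  expect_equal(pt$p_value, 1 / 101)

  # observed below the null median implies p > 0.5
  pt_low <- permutation_test(X, rnorm(30), folds = 5, repetitions = 2,
                             n_components = 2, select = "fixed",
                             n_perm = 50, seed = 2,
                             observed_mean_r = -0.9)
  expect_gt(pt_low$p_value, 0.5)

  expect_error(permutation_test(X, y, n_perm = 0), "n_perm")
})

test_that("confound regression leaves residuals orthogonal to covariates", {
  set.seed(6)
  covars <- data.frame(age = rnorm(40, 65, 9),
                       sex = sample(c("F", "M"), 40, TRUE),
                       current_mA = sample(c(600, 700, 800), 40, TRUE))
  X <- matrix(rnorm(40 * 6), 40, 6)
  X[, 1] <- covars$age * 0.5

  out <- deconfound(X, covars)
  expect_lt(max(abs(out[, 1])), 1e-8)

  design <- stats::model.matrix(~ ., covars)
  expect_lt(max(abs(crossprod(design, out))), 1e-6)
  oracle <- qr.resid(qr(design), X)
  expect_equal(unclass(out), oracle, ignore_attr = TRUE, tolerance = 1e-10)

  # covariates orthogonal to a feature leave it unchanged up to centering
  ortho <- qr.resid(qr(design), rnorm(40))
  out2 <- deconfound(cbind(ortho, X[, 2]), covars)
  expect_equal(out2[, 1], ortho - mean(ortho), tolerance = 1e-8)

  expect_warning(deconfound(X, cbind(covars, age2 = covars$age)),
                 "rank deficient")
})

test_that("model comparison reports the combined-minus-static contrast", {
  fake <- function(r) structure(list(per_repetition_r = r),
                                class = "prediction_result")
  r0 <- rnorm(200, 0.5, 0.03)
  same <- compare_models(fake(r0), fake(r0))
  expect_equal(same$t, 0)

  shifted <- compare_models(fake(r0), fake(r0 + 0.02))
  expect_gt(shifted$t, 3)

  set.seed(7)
  ra <- rnorm(150, 0.4, 0.05)
  rb <- rnorm(150, 0.45, 0.04)
  cm <- compare_models(fake(ra), fake(rb))
  expect_equal(cm$t, oracle_welch_t(rb, ra), tolerance = 1e-10)

  expect_error(compare_models(fake(ra), fake(rb[1:10])), "length")
})

test_that("feature tables carry the static/combined contract", {
  ds <- matrix(rnorm(6 * 10), 6, 10)
  st <- build_feature_table(ds)
  expect_equal(attr(st, "feature_set"), "static")
  dd <- matrix(rnorm(24), 6, 4)
  cb <- build_feature_table(ds, dd)
  expect_equal(attr(cb, "feature_set"), "combined")
  expect_equal(ncol(cb), 14L)
  expect_error(build_feature_table(ds, dd[1:3, ]), "N")
  expect_error(build_feature_table(matrix(0, 6, 11)), "C")
})
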