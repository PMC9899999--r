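#' Percentage change of a clinical score between visits
#'
#' `100 * (score_v1 - score_v3) / score_v1`: positive values mean a score
#' reduction (improvement, for severity instruments) from baseline to
#' post-series.
#'
#' @param score_v1 Baseline score(s); must be non-zero.
#' @param score_v3 Post-series score(s).
#' @return Percentage change, vectorized over subjects.
#' @export
percentage_change <- function(score_v1, score_v3) {
  if (any(score_v1 == 0)) stop("zero baseline score: percentage change undefined")
  100 * (score_v1 - score_v3) / score_v1
}

#' Fit a partial least squares regression (univariate response)
#'
#' NIPALS PLS1: predictors and response are centred, then latent
#' components are extracted sequentially (weights proportional to the
#' deflated covariance X'y). Coefficients for every component count up to
#' `n_components` are recoverable from one fit. Deterministic given the
#' inputs. Feature scaling is the caller's responsibility (the CV harness
#' standardizes within training folds).
#'
#' @param X Numeric N x P predictor matrix.
#' @param y Numeric response of length N (must not be constant).
#' @param n_components Number of latent components (<= min(N-1, P)).
#' @return An object of class `plsr_fit` with score weights, loadings,
#'   centring constants, and `n_components` actually extracted (extraction
#'   stops early if X is exhausted).
#' @export
plsr_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y disagree on the number of rows")
  if (var(y) == 0) stop("zero-variance response")
  if (n_components < 1L || n_components > min(n - 1L, p))
    stop("n_components must be in 1..min(N-1, P)")
  x_means <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2L, x_means)
  f <- y - y_mean
  Wm <- matrix(0, p, n_components)
  Pm <- matrix(0, p, n_components)
  qv <- numeric(n_components)
  a_done <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_sc <- E %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p_load <- crossprod(E, t_sc) / tt
    q <- sum(f * t_sc) / tt
    E <- E - tcrossprod(t_sc, p_load)
    f <- f - q * t_sc
    Wm[, a] <- w; Pm[, a] <- p_load; qv[a] <- q
    a_done <- a
  }
  if (a_done == 0L) stop("no predictive component could be extracted")
  structure(list(weights = Wm[, seq_len(a_done), drop = FALSE],
                 loadings = Pm[, seq_len(a_done), drop = FALSE],
                 q = qv[seq_len(a_done)],
                 x_means = x_means, y_mean = y_mean,
                 n_components = a_done),
            class = "plsr_fit")
}

#' Regression coefficients of a PLS fit
#'
#' @param object A [plsr_fit()] object.
#' @param n_components Component count to use (default: all extracted).
#' @param ... Unused.
#' @return Numeric coefficient vector of length P (for centred predictors;
#'   the intercept is `y_mean - x_means %*% beta`).
#' @export
coef.plsr_fit <- function(object, n_components = object$n_components, ...) {
  a <- min(n_components, object$n_components)
  Wa <- object$weights[, seq_len(a), drop = FALSE]
  Pa <- object$loadings[, seq_len(a), drop = FALSE]
  R <- Wa %*% solve(crossprod(Pa, Wa))
  as.numeric(R %*% object$q[seq_len(a)])
}

#' Predict from a PLS fit
#'
#' @param object A [plsr_fit()] object.
#' @param newdata Numeric matrix on the same feature scale as the training
#'   predictors.
#' @param n_components Component count to use (default: all extracted).
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.plsr_fit <- function(object, newdata,
                             n_components = object$n_components, ...) {
  beta <- coef(object, n_components)
  newdata <- as.matrix(newdata)
  as.numeric(sweep(newdata, 2L, object$x_means) %*% beta + object$y_mean)
}

# inner k-fold selection of the component count on the training partition
select_components_cv <- function(X, y, max_components, inner_folds = 5L) {
  n <- nrow(X)
  fold <- sample(rep(seq_len(inner_folds), length.out = n))
  max_components <- min(max_components,
                        n - ceiling(n / inner_folds) - 1L, ncol(X))
  if (max_components < 1L) return(1L)
  sse <- numeric(max_components)
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    if (sum(tr) < 3L || var(y[tr]) == 0) next
    fit <- plsr_fit(X[tr, , drop = FALSE], y[tr], max_components)
    for (a in seq_len(max_components)) {
      pred <- predict(fit, X[!tr, , drop = FALSE], n_components = a)
      sse[a] <- sse[a] + sum((y[!tr] - pred)^2)
    }
  }
  which.min(sse)
}

#' Repeated k-fold cross-validated PLS prediction
#'
#' The prediction harness: per repetition, subjects are randomly assigned
#' to `folds` folds; per fold, features are standardized with
#' training-fold statistics, a PLS model is fitted on the training 90%,
#' and its coefficients are applied unchanged to the held-out 10%. Pooled
#' out-of-fold predictions give one accuracy (correlation r between actual
#' and predicted, and R-squared) per repetition; every fold-level
#' coefficient vector is retained for weight-map analysis, so a run with
#' 1000 repetitions x 10 folds yields 10,000 coefficient maps.
#'
#' @param features Numeric N x P feature matrix (e.g. from
#'   [build_feature_table()]).
#' @param y Outcome vector of length N.
#' @param folds Number of CV folds (default 10).
#' @param repetitions Number of shuffle-split repetitions (default 100).
#' @param n_components PLS component count: the upper bound of the inner
#'   CV search when `select = "cv"` (default 10), or the fixed count when
#'   `select = "fixed"`.
#' @param select `"cv"` (default) picks the component count per training
#'   fold by inner 5-fold CV over 1..`n_components`, then refits on the
#'   full training fold; `"fixed"` uses `n_components` directly (faster,
#'   useful for large bookkeeping runs).
#' @param seed RNG seed; the fold-assignment stream is fully determined by
#'   it, so two calls with the same seed (e.g. static and combined feature
#'   sets) see identical partitions.
#' @param store_maps Keep the (repetitions x folds) x P coefficient map
#'   matrix (default `TRUE`; disable inside permutation loops).
#' @return An object of class `prediction_result`: `per_repetition_r`,
#'   `per_repetition_R2`, `coefficient_maps` (standardized-feature scale),
#'   `components_used`, and `config`.
#' @export
repeated_cv <- function(features, y, folds = 10L, repetitions = 100L,
                        n_components = 10L, select = c("cv", "fixed"),
                        seed = 1L, store_maps = TRUE) {
  select <- match.arg(select)
  X <- as.matrix(features)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("features and outcome disagree on N")
  if (anyNA(X) || anyNA(y)) stop("missing values in features or outcome")
  if (n < folds) stop("fewer subjects than folds")
  if (floor(n / folds) < 2L)
    stop("folds would contain fewer than 2 subjects")
  set.seed(seed)
  r_rep <- numeric(repetitions)
  r2_rep <- numeric(repetitions)
  maps <- if (store_maps) matrix(NA_real_, repetitions * folds, p) else NULL
  comps <- integer(repetitions * folds)
  y_ss <- NULL
  for (rep_i in seq_len(repetitions)) {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      Xtr <- X[tr, , drop = FALSE]
      n_tr <- nrow(Xtr)
      mu <- colMeans(Xtr)
      sdv <- sqrt(pmax(colMeans(Xtr * Xtr) - mu * mu, 0) * n_tr / (n_tr - 1))
      sdv[sdv < .Machine$double.eps^0.5] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
      a <- if (select == "cv") {
        select_components_cv(Xtr, y[tr], n_components)
      } else {
        min(n_components, sum(tr) - 1L, p)
      }
      fit <- plsr_fit(Xtr, y[tr], a)
      pred[!tr] <- predict(fit, Xte)
      slot <- (rep_i - 1L) * folds + f
      comps[slot] <- fit$n_components
      if (store_maps) maps[slot, ] <- coef(fit)
    }
    r_rep[rep_i] <- cor(y, pred)
    r2_rep[rep_i] <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  if (store_maps && !is.null(colnames(X))) colnames(maps) <- colnames(X)
  structure(list(per_repetition_r = r_rep, per_repetition_R2 = r2_rep,
                 coefficient_maps = maps, components_used = comps,
                 config = list(folds = folds, repetitions = repetitions,
                               n_components = n_components, select = select,
                               seed = seed, n = n, p = p,
                               feature_labels = colnames(X),
                               feature_set = attr(features, "feature_set"))),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(paste0("<prediction_result> %d reps x %d folds, N = %d, ",
                     "P = %d\n  mean r = %.4f (sd %.4f), mean R2 = %.4f\n"),
              x$config$repetitions, x$config$folds, x$config$n, x$config$p,
              mean(x$per_repetition_r), sd(x$per_repetition_r),
              mean(x$per_repetition_R2)))
  invisible(x)
}

#' Permutation test of cross-validated prediction accuracy
#'
#' Permutes the outcome labels `n_perm` times and recomputes the full CV
#' accuracy for each permutation (optionally at a reduced repetition
#' count, which is recorded in the output). The p-value is
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param features,y,folds,n_components,select As for [repeated_cv()].
#' @param repetitions CV repetitions used for each permutation (and for
#'   the observed statistic if it is not supplied).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Master seed; permutation b uses seed + b.
#' @param observed_mean_r Observed mean r from the identical CV
#'   configuration; recomputed here when `NULL`.
#' @return A list: `p_value`, `observed`, `null_distribution`, and the
#'   settings used.
#' @export
permutation_test <- function(features, y, folds = 10L, repetitions = 10L,
                             n_components = 10L, select = "cv",
                             n_perm = 1000L, seed = 1L,
                             observed_mean_r = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (is.null(observed_mean_r)) {
    obs_res <- repeated_cv(features, y, folds = folds,
                           repetitions = repetitions,
                           n_components = n_components, select = select,
                           seed = seed, store_maps = FALSE)
    observed_mean_r <- mean(obs_res$per_repetition_r)
  }
  null_r <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + 7919L * b)
    y_perm <- sample(y)
    res <- repeated_cv(features, y_perm, folds = folds,
                       repetitions = repetitions,
                       n_components = n_components, select = select,
                       seed = seed + b, store_maps = FALSE)
    null_r[b] <- mean(res$per_repetition_r)
  }
  p <- (1 + sum(null_r >= observed_mean_r)) / (1 + n_perm)
  list(p_value = p, observed = observed_mean_r, null_distribution = null_r,
       n_perm = n_perm, repetitions = repetitions, folds = folds,
       seed = seed)
}

#' Regress confounds out of a feature table
#'
#' Replaces every feature column by its residual from a least-squares
#' regression on the covariates (plus intercept); residuals are orthogonal
#' to all covariate columns. Collinear covariate columns are dropped with
#' a warning.
#'
#' @param features Numeric N x P matrix.
#' @param covariates Data frame or matrix of confounds aligned with the
#'   feature rows (factors/characters are expanded to indicators), e.g.
#'   age, sex, current amplitude, treatment number and pulse width.
#' @return The deconfounded feature matrix (same shape and attributes).
#' @export
deconfound <- function(features, covariates) {
  X <- as.matrix(features)
  if (is.null(dim(covariates))) covariates <- data.frame(cov = covariates)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(X))
    stop("covariates are not aligned with the feature rows")
  design <- stats::model.matrix(~ ., data = covariates)
  out <- qr_residualize(X, design)
  attributes(out)[c("feature_set")] <- attributes(features)[c("feature_set")]
  dimnames(out) <- dimnames(X)
  out
}

#' Compare static-only and combined prediction accuracies
#'
#' Two-sample Welch t-test between the per-repetition accuracy vectors of
#' two models run on identical CV partitions (same seed). Positive t means
#' the combined model outperforms the static-only model. A paired test is
#' available since repetitions share partitions.
#'
#' @param result_static,result_combined [repeated_cv()] results of equal
#'   repetition count.
#' @param paired Use a paired t-test instead of Welch (default `FALSE`).
#' @return A list with `t`, `p`, `mean_static`, `mean_combined`, `paired`.
#' @export
compare_models <- function(result_static, result_combined, paired = FALSE) {
  rs <- result_static$per_repetition_r
  rc <- result_combined$per_repetition_r
  if (length(rs) != length(rc))
    stop("accuracy vectors differ in length")
  ht <- t.test(rc, rs, paired = paired)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_static = mean(rs), mean_combined = mean(rc), paired = paired)
}

#' Assemble the model feature table
#'
#' Binds the N x C(C-1)/2 static connectivity change features with,
#' optionally, the N x 4 dynamism change features, yielding the static
#' (P = 1378 for C = 53) or combined (P = 1382) feature set.
#'
#' @param delta_static Numeric N x C(C-1)/2 matrix of v1 - v3 static
#'   connectivity features.
#' @param delta_dynamism Optional N x 4 matrix of v1 - v3 dynamism
#'   features.
#' @return Numeric matrix with attribute `feature_set` set to `"static"`
#'   or `"combined"`.
#' @export
build_feature_table <- function(delta_static, delta_dynamism = NULL) {
  X <- as.matrix(delta_static)
  if (anyNA(X)) stop("missing values in static features")
  C <- (1 + sqrt(1 + 8 * ncol(X))) / 2
  if (C != round(C))
    stop("static feature count is not C(C-1)/2 for any integer C")
  if (is.null(colnames(X)))
    colnames(X) <- upper_pair_index(as.integer(C))$pair
  if (is.null(delta_dynamism)) {
    attr(X, "feature_set") <- "static"
    return(X)
  }
  D <- as.matrix(delta_dynamism)
  if (ncol(D) != 4L) stop("dynamism features must have 4 columns")
  if (nrow(D) != nrow(X)) stop("feature blocks disagree on N")
  if (anyNA(D)) stop("missing values in dynamism features")
  colnames(D) <- dynamism_names()
  out <- cbind(X, D)
  attr(out, "feature_set") <- "combined"
  out
}
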