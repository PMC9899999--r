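#' Dynamic FNC configuration
#'
#' Sliding-window settings and graphical-lasso penalty for per-window
#' connectivity estimation. Defaults follow the common resting-state
#' convention of 20-TR rectangular windows slid by 1 TR.
#'
#' @param window_tr Window length in TRs (default 20).
#' @param step_tr Window step in TRs (default 1).
#' @param glasso_lambda L1 penalty on the per-window precision matrix
#'   (default 0.1); fixed rather than tuned per subject for determinism.
#' @param max_iter Maximum outer sweeps of the block coordinate descent.
#' @param tol Relative convergence tolerance on the covariance iterates.
#' @return A list of class `dfnc_config`.
#' @export
dfnc_config <- function(window_tr = 20L, step_tr = 1L, glasso_lambda = 0.1,
                        max_iter = 200L, tol = 1e-4) {
  if (window_tr < 3L) stop("window_tr must be at least 3")
  if (step_tr < 1L) stop("step_tr must be at least 1")
  if (glasso_lambda <= 0) stop("glasso_lambda must be positive")
  if (tol <= 0) stop("tol must be positive")
  structure(list(window_tr = as.integer(window_tr),
                 step_tr = as.integer(step_tr),
                 glasso_lambda = glasso_lambda,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "dfnc_config")
}

#' Cut a scan into sliding windows
#'
#' Rectangular (untapered) segments of `window_tr` rows starting at
#' 1, 1+step, 1+2*step, ...; the number of windows is
#' `floor((T - window_tr) / step_tr) + 1`.
#'
#' @param tc An [icn_timecourses()] object.
#' @param config A [dfnc_config()].
#' @return A list with `segments` (list of window_tr x C matrices) and
#'   `window_starts` (1-based start indices).
#' @export
sliding_windows <- function(tc, config = dfnc_config()) {
  stopifnot_tc(tc)
  Tn <- nrow(tc$data)
  w <- config$window_tr
  if (Tn < w)
    stop(sprintf("scan too short: %d timepoints for a %d-TR window", Tn, w))
  starts <- seq.int(1L, Tn - w + 1L, by = config$step_tr)
  segs <- lapply(starts, function(s) tc$data[s:(s + w - 1L), , drop = FALSE])
  list(segments = segs, window_starts = starts)
}

#' Graphical-lasso connectivity estimate for one window
#'
#' Estimates a sparse inverse covariance by L1-penalized maximum
#' likelihood on the window's standardized columns (block coordinate
#' descent on the covariance dual), then returns the correlation matrix
#' implied by the inverse of the estimated precision: symmetric, unit
#' diagonal, positive definite.
#'
#' @param segment Numeric matrix with at least 3 rows (one sliding window).
#' @param config A [dfnc_config()] supplying penalty and tolerances.
#' @param warm Optional warm start, the `fit` component of a previous
#'   window's result (speeds up window sequences).
#' @return The regularized correlation matrix (`fnc_matrix`,
#'   `kind = "regularized"`) with the precision matrix in attribute
#'   `precision` and the raw solver state in attribute `fit`.
#' @export
glasso_fnc <- function(segment, config = dfnc_config(), warm = NULL) {
  segment <- as.matrix(segment)
  if (nrow(segment) < 3L) stop("window needs at least 3 rows")
  s <- apply(segment, 2L, sd)
  if (any(s == 0))
    stop(sprintf("zero-variance column(s) in window: %s",
                 paste(colnames(segment)[s == 0], collapse = ", ")))
  S <- cor(segment)
  fit <- glasso_cpp(S, config$glasso_lambda, config$max_iter, config$tol,
                    w_init = warm$w, b_init = warm$beta)
  if (!fit$converged && !is.null(warm)) {
    # a stale warm start can stall the block descent; retry cold
    fit <- glasso_cpp(S, config$glasso_lambda, config$max_iter, config$tol)
  }
  if (!fit$converged)
    stop(sprintf("graphical lasso did not converge within %d sweeps",
                 config$max_iter))
  R <- cov2cor(fit$w)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- dimnames(S)
  structure(R, class = c("fnc_matrix", "matrix"), kind = "regularized",
            precision = fit$theta, fit = fit)
}

#' Sliding-window dynamic FNC for one scan
#'
#' Applies [glasso_fnc()] to every window (warm-starting each window from
#' the previous one), producing the W x C x C dynamic connectivity array.
#'
#' @param tc An [icn_timecourses()] object (post-processed).
#' @param config A [dfnc_config()].
#' @return A list of class `windowed_fnc`: `values` (W x C x C array),
#'   `window_starts`, `icn_labels`, and `iterations` (solver sweeps per
#'   window).
#' @export
compute_dfnc <- function(tc, config = dfnc_config()) {
  win <- sliding_windows(tc, config)
  C <- ncol(tc$data)
  W <- length(win$segments)
  values <- array(NA_real_, c(W, C, C))
  iters <- integer(W)
  warm <- NULL
  for (w in seq_len(W)) {
    R <- tryCatch(glasso_fnc(win$segments[[w]], config, warm = warm),
                  error = function(e)
                    stop(sprintf("window %d (start %d): %s", w,
                                 win$window_starts[w], conditionMessage(e)),
                         call. = FALSE))
    values[w, , ] <- R
    iters[w] <- attr(R, "fit")$iterations
    warm <- attr(R, "fit")
  }
  structure(list(values = values, window_starts = win$window_starts,
                 icn_labels = colnames(tc$data), iterations = iters,
                 subject_id = tc$subject_id, session_id = tc$session_id),
            class = "windowed_fnc")
}

#' @export
print.windowed_fnc <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<windowed_fnc> %s/%s: %d windows of %d x %d\n",
              x$subject_id, x$session_id, d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Vectorize every window of a dynamic FNC array
#'
#' Stacks the upper triangle of each window matrix (frozen pair order)
#' into a W x C(C-1)/2 matrix, the representation clustered by
#' [fit_patterns()].
#'
#' @param wfnc A `windowed_fnc` from [compute_dfnc()].
#' @return Numeric W x C(C-1)/2 matrix.
#' @export
vectorize_windows <- function(wfnc) {
  if (!inherits(wfnc, "windowed_fnc")) stop("expected a 'windowed_fnc'")
  d <- dim(wfnc$values)
  C <- d[2L]
  pairs <- upper_pair_index(C, wfnc$icn_labels)
  idx <- cbind(pairs$i, pairs$j)
  out <- t(apply(wfnc$values, 1L, function(m) m[idx]))
  colnames(out) <- pairs$pair
  out
}
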