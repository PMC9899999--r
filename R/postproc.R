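#' Post-processing configuration
#'
#' The cleaning chain applied to each scan's ICN time courses, in fixed
#' order: polynomial detrending, regression of the six realignment
#' parameters and their temporal derivatives, outlier despiking, band-pass
#' filtering. Each step can be switched off individually (a configuration
#' with all steps off is the identity).
#'
#' @param detrend_order Polynomial order removed per column (default 3:
#'   linear, quadratic and cubic trends; 0 is mean-centering only).
#' @param despike_mad_threshold Outlier threshold in units of the
#'   column-wise median absolute deviation (default 4).
#' @param band_low_hz,band_high_hz Band-pass corner frequencies (defaults
#'   0.01 and 0.15 Hz).
#' @param filter_order Butterworth prototype order (default 5), applied
#'   forward-backward for zero phase.
#' @param do_detrend,do_regress,do_despike,do_bandpass Logical switches for
#'   the individual steps.
#' @return A list of class `postproc_config`.
#' @export
postproc_config <- function(detrend_order = 3L, despike_mad_threshold = 4,
                            band_low_hz = 0.01, band_high_hz = 0.15,
                            filter_order = 5L,
                            do_detrend = TRUE, do_regress = TRUE,
                            do_despike = TRUE, do_bandpass = TRUE) {
  if (detrend_order < 0L) stop("detrend_order must be >= 0")
  if (despike_mad_threshold <= 0) stop("despike_mad_threshold must be positive")
  if (band_low_hz <= 0 || band_high_hz <= band_low_hz)
    stop("need 0 < band_low_hz < band_high_hz")
  if (filter_order < 1L) stop("filter_order must be >= 1")
  structure(list(detrend_order = as.integer(detrend_order),
                 despike_mad_threshold = despike_mad_threshold,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 filter_order = as.integer(filter_order),
                 do_detrend = isTRUE(do_detrend),
                 do_regress = isTRUE(do_regress),
                 do_despike = isTRUE(do_despike),
                 do_bandpass = isTRUE(do_bandpass)),
            class = "postproc_config")
}

# residualize columns of y on a design matrix (intercept assumed included),
# dropping collinear columns via pivoted QR
qr_residualize <- function(y, design, warn_rank = TRUE) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design) && warn_rank)
    warning(sprintf("design is rank deficient (%d of %d columns used)",
                    qrd$rank, ncol(design)))
  y - qr.fitted(qrd, y)
}

#' Remove polynomial trends from each ICN time course
#'
#' Each column is replaced by its residual from a least-squares fit of
#' polynomials in time up to `order` (intercept included), so residual
#' columns are mean-zero and orthogonal to the polynomial basis.
#'
#' @param tc An [icn_timecourses()] object.
#' @param order Highest polynomial order to remove; `order = 0` is
#'   mean-centering.
#' @return The detrended [icn_timecourses()].
#' @export
detrend_polynomial <- function(tc, order = 3L) {
  stopifnot_tc(tc)
  Tn <- nrow(tc$data)
  if (order >= Tn - 1L)
    stop(sprintf("degenerate fit: order %d with only %d timepoints", order, Tn))
  design <- if (order == 0L) {
    matrix(1, Tn, 1L)
  } else {
    cbind(1, poly(seq_len(Tn), degree = order))
  }
  tc$data <- qr_residualize(tc$data, design, warn_rank = FALSE)
  tc
}

#' Regress motion parameters and their derivatives out of the time courses
#'
#' Multiple regression of each column on the six realignment parameters,
#' their backward-difference temporal derivatives (first row zero), and an
#' intercept. Residuals are orthogonal to all regressors.
#'
#' @param tc An [icn_timecourses()] object with a motion matrix.
#' @return The cleaned [icn_timecourses()].
#' @export
regress_nuisance <- function(tc) {
  stopifnot_tc(tc)
  motion <- tc$motion
  deriv <- rbind(0, diff(motion))
  design <- cbind(1, motion, deriv)
  tc$data <- qr_residualize(tc$data, design)
  tc
}

#' Detect and interpolate outlier timepoints
#'
#' Flags, per column, timepoints farther than `threshold` x MAD from the
#' column median, and replaces them by linear interpolation from the
#' nearest unflagged neighbours (edge flags take the nearest unflagged
#' value). The spike mask is attached for audit.
#'
#' @param tc An [icn_timecourses()] object with at least 3 timepoints.
#' @param threshold Positive MAD multiplier (default 4).
#' @return The despiked [icn_timecourses()] with a `spike_mask` attribute
#'   (T x C logical matrix).
#' @export
despike <- function(tc, threshold = 4) {
  stopifnot_tc(tc)
  X <- tc$data
  Tn <- nrow(X)
  if (Tn < 3L) stop("despike needs at least 3 timepoints")
  mask <- matrix(FALSE, Tn, ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    m <- median(x)
    s <- mad(x)
    if (s == 0) s <- .Machine$double.eps  # constant column: flag any deviant
    flag <- abs(x - m) > threshold * s
    if (all(flag))
      stop(sprintf("degenerate input: every timepoint of %s flagged",
                   colnames(X)[j]))
    if (any(flag)) {
      keep <- which(!flag)
      X[flag, j] <- approx(keep, x[keep], xout = which(flag),
                           rule = 2)$y
    }
    mask[, j] <- flag
  }
  tc$data <- X
  attr(tc, "spike_mask") <- mask
  tc
}

#' Zero-phase band-pass filter the time courses
#'
#' Butterworth band-pass (see [postproc_config()]) applied forward and
#' backward per column so the filter is zero-phase: passband sinusoids keep
#' their amplitude and timing, stopband components (including the DC level)
#' are strongly attenuated.
#'
#' @param tc An [icn_timecourses()] object.
#' @param config A [postproc_config()] supplying the band and filter order.
#' @return The filtered [icn_timecourses()].
#' @export
bandpass <- function(tc, config = postproc_config()) {
  stopifnot_tc(tc)
  nyq <- 1 / (2 * tc$tr_seconds)
  if (config$band_high_hz >= nyq)
    stop(sprintf("band_high_hz (%.3f) must be below Nyquist (%.3f Hz)",
                 config$band_high_hz, nyq))
  bf <- signal::butter(config$filter_order,
                       c(config$band_low_hz, config$band_high_hz) / nyq,
                       type = "pass")
  # remove the column mean first: DC sits outside the passband anyway and
  # a large offset would otherwise leak in through edge transients
  tc$data <- apply(tc$data, 2L, function(x)
    signal::filtfilt(bf, x - mean(x)))
  tc
}

#' Run the full post-processing chain on one scan
#'
#' Applies, in order: polynomial detrending, motion-parameter regression,
#' despiking, band-pass filtering. Steps disabled in the configuration are
#' skipped; a configuration with every step off returns the input
#' unchanged. A per-step log (enabled steps, spike counts) is attached as
#' the `postproc_log` attribute.
#'
#' @param tc An [icn_timecourses()] object.
#' @param config A [postproc_config()].
#' @return The post-processed [icn_timecourses()] with attributes
#'   `spike_mask` (if despiking ran) and `postproc_log`.
#' @export
postprocess <- function(tc, config = postproc_config()) {
  stopifnot_tc(tc)
  log <- list()
  if (config$do_detrend) {
    tc <- detrend_polynomial(tc, config$detrend_order)
    log$detrend <- list(order = config$detrend_order)
  }
  if (config$do_regress) {
    tc <- regress_nuisance(tc)
    log$regress <- list(n_regressors = 13L)
  }
  mask <- NULL
  if (config$do_despike) {
    tc <- despike(tc, config$despike_mad_threshold)
    mask <- attr(tc, "spike_mask")
    log$despike <- list(threshold = config$despike_mad_threshold,
                        n_flagged = sum(mask))
  }
  if (config$do_bandpass) {
    tc <- bandpass(tc, config)
    log$bandpass <- list(band_hz = c(config$band_low_hz, config$band_high_hz),
                         order = config$filter_order)
  }
  if (!is.null(mask)) attr(tc, "spike_mask") <- mask
  attr(tc, "postproc_log") <- log
  tc
}
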