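#' Configuration for the synthetic two-session cohort generator
#'
#' The generator emulates the structure of a two-visit (pre/post treatment)
#' resting-state study: per subject and session a T x C ICN time-course
#' matrix is simulated from a semi-Markov mixture of state-specific
#' covariances, contaminated with polynomial drift, motion-coupled nuisance
#' signal and sparse spikes. The outcome (percentage change of a clinical
#' score between visits v1 and v3) is a planted linear combination of the
#' subject's *true* v1-v3 connectivity differences and *true* dynamism
#' differences, plus Gaussian noise, so that downstream recovery can be
#' scored against known ground truth.
#'
#' @param n_subjects Number of subjects (default 50).
#' @param n_icns Number of ICNs C (default 53).
#' @param n_timepoints Volumes per scan T (default 400, i.e. a 4:58
#'   acquisition at TR 0.745 s).
#' @param tr_seconds Sampling interval (default 0.745).
#' @param n_latent_states Number of latent covariance states per scan.
#' @param state_dwell Mean dwell time per state, in timepoints.
#' @param effect_static Planted outcome weights on static connectivity
#'   change features: a named numeric vector whose names are upper-triangle
#'   feature indices (see [upper_pair_index()]), or a full length-C(C-1)/2
#'   vector, or `NULL` for no static effect.
#' @param effect_dynamism Planted outcome weights on the four dynamism
#'   change measures (length 4), or `NULL` for none.
#' @param noise_sd Outcome noise standard deviation (percentage points).
#' @param target_r2 If non-`NULL`, overrides `noise_sd` so that the planted
#'   signal's oracle R-squared (signal variance over total outcome variance)
#'   equals this value across the cohort.
#' @param spike_rate Per-timepoint, per-column probability of an artifact
#'   spike, in `[0, 1)`.
#' @param static_delta_sd SD of the per-subject, per-session loading on the
#'   planted connectivity-change pattern (correlation units).
#' @param dwell_log_sd SD of the per-subject, per-session log-normal dwell
#'   multiplier; drives between-subject dynamism differences.
#' @param drift_sd Amplitude of the random cubic drift (signal SD units).
#' @param motion_coupling SD of the motion-to-signal mixing weights.
#' @param precision_density Off-diagonal density of the random sparse state
#'   precision matrices.
#' @param state_corr Optional list of `n_latent_states` user-supplied C x C
#'   state correlation matrices (must be positive definite); by default
#'   states are built from random sparse diagonally dominant precisions.
#' @param outcome_baseline Constant added to every subject's percentage
#'   change (default 0).
#' @param seed RNG seed; identical seeds give bit-identical cohorts.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50L, n_icns = 53L,
                          n_timepoints = 400L, tr_seconds = 0.745,
                          n_latent_states = 3L, state_dwell = 40,
                          effect_static = NULL, effect_dynamism = NULL,
                          noise_sd = 5, target_r2 = NULL,
                          spike_rate = 0.005,
                          static_delta_sd = 0.1, dwell_log_sd = 0.4,
                          drift_sd = 1, motion_coupling = 0.5,
                          precision_density = 0.08, state_corr = NULL,
                          outcome_baseline = 0, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_icns = as.integer(n_icns),
              n_timepoints = as.integer(n_timepoints),
              tr_seconds = tr_seconds,
              n_latent_states = as.integer(n_latent_states),
              state_dwell = state_dwell,
              effect_static = effect_static,
              effect_dynamism = effect_dynamism,
              noise_sd = noise_sd, target_r2 = target_r2,
              spike_rate = spike_rate,
              static_delta_sd = static_delta_sd,
              dwell_log_sd = dwell_log_sd,
              drift_sd = drift_sd, motion_coupling = motion_coupling,
              precision_density = precision_density,
              state_corr = state_corr,
              outcome_baseline = outcome_baseline,
              seed = as.integer(seed))
  with(cfg, {
    if (n_subjects < 1L) stop("n_subjects must be positive")
    if (n_icns < 2L) stop("n_icns must be at least 2")
    if (n_timepoints <= 20L)
      stop("n_timepoints must exceed 20 (must admit at least one window)")
    if (tr_seconds <= 0) stop("tr_seconds must be positive")
    if (n_latent_states < 1L) stop("n_latent_states must be positive")
    if (state_dwell < 1) stop("state_dwell must be at least 1 timepoint")
    if (spike_rate < 0 || spike_rate >= 1) stop("spike_rate must be in [0, 1)")
    if (noise_sd < 0) stop("noise_sd must be non-negative")
    if (!is.null(target_r2) && (target_r2 <= 0 || target_r2 >= 1))
      stop("target_r2 must be in (0, 1)")
    if (!is.null(effect_dynamism) && length(effect_dynamism) != 4L)
      stop("effect_dynamism must have length 4")
  })
  p_feat <- cfg$n_icns * (cfg$n_icns - 1L) / 2L
  cfg$effect_static <- expand_static_effect(cfg$effect_static, p_feat)
  if (is.null(cfg$effect_dynamism)) cfg$effect_dynamism <- numeric(4L)
  if (!is.null(cfg$state_corr)) {
    if (length(cfg$state_corr) != cfg$n_latent_states)
      stop("state_corr must supply one matrix per latent state")
    for (s in seq_along(cfg$state_corr)) {
      m <- cfg$state_corr[[s]]
      if (!is.matrix(m) || nrow(m) != cfg$n_icns || ncol(m) != cfg$n_icns)
        stop("state_corr matrices must be n_icns x n_icns")
      ev <- min(eigen((m + t(m)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
      if (ev <= 0)
        stop(sprintf(
          "state covariance %d is not positive definite (min eigenvalue %.3g)",
          s, ev))
    }
  }
  class(cfg) <- "cohort_config"
  cfg
}

expand_static_effect <- function(effect, p_feat) {
  if (is.null(effect)) return(numeric(p_feat))
  if (!is.null(names(effect)) && all(names(effect) != "")) {
    idx <- as.integer(names(effect))
    if (anyNA(idx) || any(idx < 1L) || any(idx > p_feat))
      stop("effect_static names must be feature indices in 1..C(C-1)/2")
    w <- numeric(p_feat)
    w[idx] <- as.numeric(effect)
    return(w)
  }
  if (length(effect) != p_feat)
    stop("unnamed effect_static must have length C(C-1)/2")
  as.numeric(effect)
}

# random sparse diagonally dominant precision -> correlation matrix
random_state_correlation <- function(C, density) {
  omega <- random_sparse_precision(C, density)
  cov2cor(solve(omega))
}

random_sparse_precision <- function(C, density, lo = 0.3, hi = 0.7) {
  n_off <- C * (C - 1L) / 2L
  vals <- numeric(n_off)
  on <- runif(n_off) < density
  vals[on] <- sample(c(-1, 1), sum(on), replace = TRUE) * runif(sum(on), lo, hi)
  omega <- matrix(0, C, C)
  omega[upper.tri(omega)] <- vals
  omega <- omega + t(omega)
  diag(omega) <- rowSums(abs(omega)) + runif(C, 0.3, 0.6)
  omega
}

# k latent states sharing a sparse backbone precision, each adding a
# strongly connected module on its own contiguous block of networks, so
# distinct states stay separable from short-window estimates of any draw
make_state_correlations <- function(C, k, density) {
  base <- random_sparse_precision(C, density)
  if (k == 1L) return(list(cov2cor(solve(base))))
  blocks <- split(seq_len(C), sort(rep_len(seq_len(k), C)))
  lapply(seq_len(k), function(s) {
    omega <- base
    idx <- blocks[[s]]
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b) {
        v <- -runif(1L, 0.6, 0.9)
        omega[idx[a], idx[b]] <- omega[idx[a], idx[b]] + v
        omega[idx[b], idx[a]] <- omega[idx[a], idx[b]]
      }
    }
    diag(omega) <- rowSums(abs(omega)) - diag(abs(omega)) + runif(C, 0.3, 0.6)
    cov2cor(solve(omega))
  })
}

# add a symmetric edge pattern to a correlation matrix and restore PD-ness
modulate_correlation <- function(R, pattern, amount, floor = 1e-3) {
  M <- R + amount * pattern
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < floor) {
    v <- pmax(e$values, floor)
    M <- e$vectors %*% (v * t(e$vectors))
    M <- cov2cor(M)
  }
  M <- (M + t(M)) / 2
  diag(M) <- 1
  M
}

# semi-Markov latent state sequence: dwell ~ 1 + Geometric(1/mean_dwell);
# states are visited in cyclic order from a random start, which keeps the
# long-run occupancy of every state balanced whatever the dwell time, so
# switching speed and time-averaged covariance stay separately identifiable
sample_state_sequence <- function(n_timepoints, n_states, mean_dwell) {
  if (n_states == 1L) return(rep(1L, n_timepoints))
  s <- integer(0)
  cur <- sample.int(n_states, 1L)
  p <- 1 / mean_dwell
  while (length(s) < n_timepoints) {
    d <- 1L + rgeom(1L, p)
    s <- c(s, rep(cur, d))
    cur <- cur %% n_states + 1L
  }
  s[seq_len(n_timepoints)]
}

# latent sequence -> signed one-hot meta-state rows (+1 current, -1 others)
latent_metastate_rows <- function(seq, n_states) {
  m <- matrix(-1L, length(seq), max(n_states, 1L))
  m[cbind(seq_along(seq), seq)] <- 1L
  m
}

#' Generate a synthetic two-session cohort
#'
#' Produces per-subject, per-session ICN time courses, a phenotype table,
#' and a ground-truth record of every planted quantity. See
#' [cohort_config()] for the generative model.
#'
#' @param config A [cohort_config()] object.
#' @return A list with components:
#'   \describe{
#'   \item{timecourses}{Named list of [icn_timecourses()] objects, one per
#'     subject/session, named `"S01_v1"`, `"S01_v3"`, ...}
#'   \item{phenotype}{Data frame with one row per subject: `subject_id`,
#'     `score_v1`, `score_v3`, `age`, `sex`, `current_mA`,
#'     `treatment_number`, `pulse_width_ms`.}
#'   \item{ground_truth}{List recording planted effects, per-scan true
#'     connectivity and dynamism, spike masks, state sequences, the planted
#'     signal, realized noise SD and oracle R-squared.}
#'   \item{config}{The configuration used.}
#'   }
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  set.seed(config$seed)
  C <- config$n_icns
  Tn <- config$n_timepoints
  N <- config$n_subjects
  k <- config$n_latent_states
  p_feat <- C * (C - 1L) / 2L
  pairs <- upper_pair_index(C)
  ut <- cbind(pairs$i, pairs$j)

  states <- config$state_corr
  if (is.null(states))
    states <- make_state_correlations(C, k, config$precision_density)

  pattern <- matrix(0, C, C)
  planted <- which(config$effect_static != 0)
  if (length(planted)) {
    pattern[ut[planted, , drop = FALSE]] <- 1
    pattern <- pattern + t(pattern)
  }

  icn_labels <- sprintf("ICN%02d", seq_len(C))
  sessions <- c("v1", "v3")
  tcs <- list()
  static_true <- array(NA_real_, c(N, 2L, p_feat))
  dyn_true <- array(NA_real_, c(N, 2L, 4L))
  spike_masks <- list()
  state_seqs <- list()
  loadings <- matrix(NA_real_, N, 2L, dimnames = list(NULL, sessions))
  dwells <- matrix(NA_real_, N, 2L, dimnames = list(NULL, sessions))

  for (i in seq_len(N)) {
    sid <- sprintf("S%02d", i)
    for (v in 1:2) {
      a_iv <- rnorm(1L, 0, config$static_delta_sd)
      dwell_iv <- config$state_dwell * exp(rnorm(1L, 0, config$dwell_log_sd))
      dwell_iv <- max(dwell_iv, 1)
      loadings[i, v] <- a_iv
      dwells[i, v] <- dwell_iv

      scan_states <- if (length(planted)) {
        lapply(states, modulate_correlation, pattern = pattern, amount = a_iv)
      } else states
      chols <- lapply(scan_states, chol)

      seq_iv <- sample_state_sequence(Tn, k, dwell_iv)
      occ <- tabulate(seq_iv, nbins = k) / Tn
      true_corr <- Reduce(`+`, Map(`*`, scan_states, occ))
      static_true[i, v, ] <- true_corr[ut]
      dyn_true[i, v, ] <- dynamism_measures(latent_metastate_rows(seq_iv, k))

      # state-conditional Gaussian draws
      Z <- matrix(rnorm(Tn * C), Tn, C)
      X <- matrix(0, Tn, C)
      for (s in seq_len(k)) {
        rows <- which(seq_iv == s)
        if (length(rows))
          X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[s]]
      }

      # polynomial drift (up to cubic) on scaled time
      u <- seq(-1, 1, length.out = Tn)
      drift_coef <- matrix(rnorm(3L * C, 0, config$drift_sd / 2), 3L, C)
      X <- X + cbind(u, u^2, u^3) %*% drift_coef

      # motion: slow random walks; nuisance is a linear mixture of them
      motion <- apply(matrix(rnorm(Tn * 6L, 0, 0.01), Tn, 6L), 2L, cumsum)
      B <- matrix(rnorm(6L * C, 0, config$motion_coupling), 6L, C)
      X <- X + motion %*% B

      # sparse artifact spikes
      mask <- matrix(rbinom(Tn * C, 1L, config$spike_rate) == 1L, Tn, C)
      if (any(mask)) {
        amp <- sample(c(-1, 1), sum(mask), TRUE) * runif(sum(mask), 6, 10)
        X[mask] <- X[mask] + amp
      }

      colnames(X) <- icn_labels
      key <- paste0(sid, "_", sessions[v])
      tcs[[key]] <- icn_timecourses(X, motion, config$tr_seconds,
                                    subject_id = sid,
                                    session_id = sessions[v])
      spike_masks[[key]] <- mask
      state_seqs[[key]] <- seq_iv
    }
  }

  delta_static <- static_true[, 1L, ] - static_true[, 2L, ]
  delta_static <- matrix(delta_static, N, p_feat)
  delta_dyn <- matrix(dyn_true[, 1L, ] - dyn_true[, 2L, ], N, 4L,
                      dimnames = list(NULL, dynamism_names()))

  static_term <- as.numeric(delta_static %*% config$effect_static)
  dyn_term <- as.numeric(delta_dyn %*% config$effect_dynamism)
  signal <- static_term + dyn_term

  noise_sd <- config$noise_sd
  if (!is.null(config$target_r2)) {
    s_sd <- sd(signal)
    if (!is.finite(s_sd) || s_sd == 0)
      stop("target_r2 requires a non-degenerate planted signal")
    noise_sd <- s_sd * sqrt((1 - config$target_r2) / config$target_r2)
  }
  noise <- if (noise_sd > 0) rnorm(N, 0, noise_sd) else numeric(N)
  pct_change <- config$outcome_baseline + signal + noise

  score_v1 <- pmax(round(rnorm(N, 35, 6)), 18)
  score_v3 <- score_v1 * (1 - pct_change / 100)

  phenotype <- data.frame(
    subject_id = sprintf("S%02d", seq_len(N)),
    score_v1 = score_v1, score_v3 = score_v3,
    age = round(rnorm(N, 65.54, 8.92), 1),
    sex = sample(c("F", "M"), N, TRUE),
    current_mA = sample(c(600, 700, 800), N, TRUE),
    treatment_number = 4L + stats::rpois(N, 6),
    pulse_width_ms = sample(c(0.3, 1.0), N, TRUE),
    stringsAsFactors = FALSE)

  v_sig <- if (N > 1L) var(signal) else 0
  ground_truth <- list(
    static_true_v1 = matrix(static_true[, 1L, ], N, p_feat),
    static_true_v3 = matrix(static_true[, 2L, ], N, p_feat),
    delta_static = delta_static,
    dyn_true_v1 = matrix(dyn_true[, 1L, ], N, 4L,
                         dimnames = list(NULL, dynamism_names())),
    dyn_true_v3 = matrix(dyn_true[, 2L, ], N, 4L,
                         dimnames = list(NULL, dynamism_names())),
    delta_dynamism = delta_dyn,
    effect_static = config$effect_static,
    effect_dynamism = config$effect_dynamism,
    static_term = static_term, dynamism_term = dyn_term,
    signal = signal, pct_change = pct_change,
    noise_sd = noise_sd,
    oracle_r2 = if (v_sig + noise_sd^2 > 0) v_sig / (v_sig + noise_sd^2) else 0,
    state_corr = states, loadings = loadings, dwells = dwells,
    spike_masks = spike_masks, state_sequences = state_seqs)

  list(timecourses = tcs, phenotype = phenotype,
       ground_truth = ground_truth, config = config)
}
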