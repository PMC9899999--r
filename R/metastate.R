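dynamism_names <- function() {
  c("n_states", "n_switches", "state_span", "total_distance")
}

#' Fit group-level connectivity patterns by fuzzy k-means
#'
#' Clusters vectorized window matrices pooled over all subjects and
#' sessions into `k` connectivity patterns with fuzzy c-means, returning
#' the pattern centroids and the per-window membership weights (length-k
#' rows in [0, 1] summing to 1). Group-level fitting keeps meta-states
#' comparable across subjects.
#'
#' @param windows Numeric n x P matrix of vectorized windows (rows pooled
#'   over the cohort, e.g. `rbind` of [vectorize_windows()] outputs).
#' @param k Number of connectivity patterns (default 5).
#' @param fuzziness Membership exponent (> 1; default 2).
#' @param seed RNG seed for the centroid initialization; fitting is
#'   deterministic given the seed. Degenerate fits (duplicated or empty
#'   centroids) are refit with an incremented seed, with a warning.
#' @param max_refits Maximum number of reseeded refits.
#' @return A list of class `pattern_model`: `patterns` (k x P centroid
#'   matrix), `memberships` (n x k), `k`, `fuzziness`, `seed_used`.
#' @export
fit_patterns <- function(windows, k = 5L, fuzziness = 2,
                         seed = 1L, max_refits = 5L) {
  windows <- as.matrix(windows)
  if (k < 2L) stop("k must be at least 2")
  if (fuzziness <= 1) stop("fuzziness must exceed 1")
  if (nrow(windows) < 10L * k)
    stop("too few windows to fit the requested number of patterns")
  for (attempt in 0:max_refits) {
    set.seed(seed + attempt)
    fit <- e1071::cmeans(windows, centers = k, m = fuzziness,
                         iter.max = 200L, method = "cmeans")
    centers <- fit$centers
    # degenerate fit: coincident centroids or a pattern no window favours
    dup <- any(stats::dist(centers) < 1e-8)
    empty <- any(tabulate(fit$cluster, nbins = k) == 0L)
    if (!dup && !empty) {
      if (attempt > 0L)
        warning(sprintf("pattern fit reseeded %d time(s) after degenerate fit",
                        attempt))
      return(structure(list(patterns = centers,
                            memberships = fit$membership,
                            k = as.integer(k), fuzziness = fuzziness,
                            seed_used = seed + attempt),
                       class = "pattern_model"))
    }
  }
  stop("fuzzy k-means repeatedly produced degenerate patterns")
}

#' Cohort-wide discretization thresholds for pattern weights
#'
#' For each pattern, the membership-weight distribution pooled over the
#' cohort is split into 8 signed bins: the column is centred on its cohort
#' median and each half is cut at its quartiles, i.e. the breaks are the
#' pooled octiles. Values below the lowest octile map to -4, values above
#' the highest to +4.
#'
#' @param memberships Pooled n x k membership matrix from [fit_patterns()].
#' @return A 7 x k matrix of break points (one column per pattern).
#' @export
weight_bins <- function(memberships) {
  memberships <- as.matrix(memberships)
  apply(memberships, 2L, function(x) {
    if (length(unique(x)) < 8L)
      stop("uninformative pattern: membership column nearly constant")
    quantile(x, probs = seq(0.125, 0.875, by = 0.125), names = FALSE,
             type = 7L)
  })
}

#' Discretize membership weights into meta-state vectors
#'
#' Maps each window's pattern weights to the signed bins
#' \{-4, -3, -2, -1, +1, +2, +3, +4\} using cohort-wide break points, so a
#' scan's windows trace a trajectory through a discrete meta-state space.
#' The mapping is monotone: a larger raw weight never maps to a smaller
#' bin.
#'
#' @param weights W x k membership matrix for one scan (or the pooled
#'   cohort).
#' @param bins Break points from [weight_bins()] (computed from `weights`
#'   itself if omitted — only appropriate when `weights` is the pooled
#'   cohort matrix).
#' @return Integer W x k meta-state matrix (class `meta_state_sequence`).
#' @export
discretize_weights <- function(weights, bins = NULL) {
  weights <- as.matrix(weights)
  if (is.null(bins)) bins <- weight_bins(weights)
  if (ncol(weights) != ncol(bins))
    stop("bins do not match the number of patterns")
  levels <- c(-4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L)
  out <- matrix(NA_integer_, nrow(weights), ncol(weights))
  for (j in seq_len(ncol(weights))) {
    b <- findInterval(weights[, j], bins[, j], left.open = TRUE)
    out[, j] <- levels[b + 1L]
  }
  structure(out, class = c("meta_state_sequence", "matrix"))
}

#' Global dynamism measures of a meta-state trajectory
#'
#' Four scalars summarizing how widely and how restlessly a scan travels
#' through meta-state space:
#' \describe{
#'   \item{n_states}{number of distinct meta-states passed through;}
#'   \item{n_switches}{number of transitions between different consecutive
#'     meta-states;}
#'   \item{state_span}{largest L1 distance between any two occupied
#'     meta-states;}
#'   \item{total_distance}{summed L1 length of all consecutive steps.}
#' }
#' A constant trajectory of any length yields (1, 0, 0, 0).
#'
#' @param states Integer W x k meta-state matrix (rows are meta-states).
#' @return Named numeric vector with the four measures.
#' @export
dynamism_measures <- function(states) {
  states <- as.matrix(unclass(states))
  W <- nrow(states)
  if (W < 1L) stop("empty meta-state sequence")
  uniq <- unique(states)
  n_states <- nrow(uniq)
  if (W == 1L) {
    return(c(n_states = 1, n_switches = 0, state_span = 0,
             total_distance = 0))
  }
  step <- abs(states[-1L, , drop = FALSE] - states[-W, , drop = FALSE])
  step_l1 <- rowSums(step)
  n_switches <- sum(step_l1 > 0)
  total_distance <- sum(step_l1)
  state_span <- 0
  if (n_states > 1L) {
    d <- as.matrix(stats::dist(uniq, method = "manhattan"))
    state_span <- max(d)
  }
  c(n_states = n_states, n_switches = n_switches,
    state_span = state_span, total_distance = total_distance)
}

#' Meta-state dynamism for a cohort of dynamic FNC arrays
#'
#' Pools vectorized windows across all scans, fits the group-level pattern
#' model, discretizes every scan's windows with cohort-wide bins, and
#' returns the four dynamism measures per scan.
#'
#' @param wfnc_list Named list of `windowed_fnc` objects (one per scan).
#' @param k,fuzziness,seed Passed to [fit_patterns()].
#' @return A list with `dynamism` (data frame: `scan_id` plus the four
#'   measures), `model` (the [fit_patterns()] result), `bins`, and
#'   `sequences` (per-scan meta-state matrices).
#' @export
global_dynamism <- function(wfnc_list, k = 5L, fuzziness = 2, seed = 1L) {
  if (is.null(names(wfnc_list)))
    names(wfnc_list) <- sprintf("scan%03d", seq_along(wfnc_list))
  vecs <- lapply(wfnc_list, vectorize_windows)
  pooled <- do.call(rbind, vecs)
  scan_of <- rep(names(wfnc_list), vapply(vecs, nrow, 1L))
  model <- fit_patterns(pooled, k = k, fuzziness = fuzziness, seed = seed)
  bins <- weight_bins(model$memberships)
  seqs <- lapply(names(wfnc_list), function(id)
    discretize_weights(model$memberships[scan_of == id, , drop = FALSE],
                       bins))
  names(seqs) <- names(wfnc_list)
  meas <- t(vapply(seqs, dynamism_measures, numeric(4L)))
  dynamism <- data.frame(scan_id = names(wfnc_list), meas,
                         row.names = NULL, stringsAsFactors = FALSE)
  list(dynamism = dynamism, model = model, bins = bins, sequences = seqs)
}

#' Session-difference dynamism features
#'
#' Builds the per-subject v1 - v3 differences of the four dynamism
#' measures from a per-scan dynamism table, mirroring the static
#' change-feature convention.
#'
#' @param dynamism Data frame from [global_dynamism()] whose `scan_id`
#'   follows the `"<subject>_<session>"` naming of [generate_cohort()].
#' @param subjects Optional subject ordering (default: order of first
#'   appearance).
#' @return Numeric N x 4 matrix of v1 - v3 differences, rownames =
#'   subjects.
#' @export
delta_dynamism <- function(dynamism, subjects = NULL) {
  parts <- strsplit(dynamism$scan_id, "_(?=[^_]+$)", perl = TRUE)
  subj <- vapply(parts, `[`, "", 1L)
  sess <- vapply(parts, `[`, "", 2L)
  if (!all(sess %in% c("v1", "v3")))
    stop("scan_id must end in _v1 or _v3")
  if (is.null(subjects)) subjects <- unique(subj)
  m <- as.matrix(dynamism[, dynamism_names()])
  out <- matrix(NA_real_, length(subjects), 4L,
                dimnames = list(subjects, dynamism_names()))
  for (s in subjects) {
    r1 <- which(subj == s & sess == "v1")
    r3 <- which(subj == s & sess == "v3")
    if (length(r1) != 1L || length(r3) != 1L)
      stop(sprintf("subject %s does not have exactly one v1 and one v3 scan", s))
    out[s, ] <- m[r1, ] - m[r3, ]
  }
  out
}
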