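# Independent oracles used to cross-check the package's own algorithms.
# Each one is deliberately coded via a different route than the
# implementation it checks.

# Brute-force dynamism oracle: plain loops straight from the definitions.
oracle_dynamism <- function(states) {
  states <- as.matrix(unclass(states))
  W <- nrow(states)
  seen <- list()
  for (t in seq_len(W)) {
    key <- paste(states[t, ], collapse = ",")
    seen[[key]] <- states[t, ]
  }
  n_states <- length(seen)
  n_switches <- 0
  total <- 0
  if (W > 1) for (t in 2:W) {
    d <- sum(abs(states[t, ] - states[t - 1, ]))
    if (d > 0) n_switches <- n_switches + 1
    total <- total + d
  }
  span <- 0
  occ <- do.call(rbind, seen)
  if (n_states > 1) for (a in 1:(n_states - 1)) for (b in (a + 1):n_states)
    span <- max(span, sum(abs(occ[a, ] - occ[b, ])))
  c(n_states = n_states, n_switches = n_switches, state_span = span,
    total_distance = total)
}

# Proximal-gradient (G-ISTA style) oracle for the graphical lasso:
# minimise -logdet(Theta) + tr(S Theta) + lambda * sum(abs(Theta))
oracle_glasso_precision <- function(S, lambda, iters = 20000, tol = 1e-10) {
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  obj <- function(Th) {
    ch <- tryCatch(chol(Th), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    -2 * sum(log(diag(ch))) + sum(S * Th) + lambda * sum(abs(Th))
  }
  Theta <- diag(1 / (diag(S) + lambda), nrow(S))
  eta <- 0.1
  f_old <- obj(Theta)
  for (it in seq_len(iters)) {
    G <- S - solve(Theta)
    repeat {
      Thn <- soft(Theta - eta * G, eta * lambda)
      Thn <- (Thn + t(Thn)) / 2
      ok <- min(eigen(Thn, symmetric = TRUE, only.values = TRUE)$values) > 1e-10
      if (ok && obj(Thn) <= f_old + 1e-12) break
      eta <- eta / 2
      if (eta < 1e-14) break
    }
    d <- max(abs(Thn - Theta))
    Theta <- Thn
    f_new <- obj(Theta)
    if (d < tol && abs(f_old - f_new) < tol) break
    f_old <- f_new
    eta <- min(eta * 1.5, 1)
  }
  Theta
}

# SIMPLS oracle for PLS1 coefficients (identical solution path to NIPALS
# for a univariate response, but computed via the orthogonalised
# cross-covariance recursion).
oracle_simpls <- function(X, y, a) {
  X <- as.matrix(X)
  mx <- colMeans(X)
  my <- mean(y)
  Xc <- sweep(X, 2, mx)
  yc <- y - my
  s <- crossprod(Xc, yc)
  p_dim <- ncol(X)
  R <- matrix(0, p_dim, a)
  V <- matrix(0, p_dim, a)
  q <- numeric(a)
  for (i in seq_len(a)) {
    r <- s
    t_sc <- Xc %*% r
    t_sc <- t_sc - mean(t_sc)
    nt <- sqrt(sum(t_sc^2))
    t_sc <- t_sc / nt
    r <- r / nt
    p_load <- crossprod(Xc, t_sc)
    q[i] <- sum(yc * t_sc)
    v <- p_load
    if (i > 1) {
      Vi <- V[, seq_len(i - 1), drop = FALSE]
      v <- v - Vi %*% crossprod(Vi, p_load)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v * sum(v * s)
    R[, i] <- r
    V[, i] <- v
  }
  as.numeric(R %*% q)
}

# textbook Welch two-sample t statistic
oracle_welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# small quick cohorts for unit tests
tiny_cohort <- function(n_subjects = 4, n_icns = 8, n_timepoints = 120,
                        seed = 1, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects, n_icns = n_icns,
                                n_timepoints = n_timepoints, seed = seed,
                                n_latent_states = 2, state_dwell = 25, ...))
}

random_metastate_matrix <- function(W, k) {
  matrix(sample(c(-4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L), W * k, TRUE), W, k)
}
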