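#' Upper-triangle pair index
#'
#' The frozen feature ordering used throughout the package: row-major over
#' the strict upper triangle, i.e. (1,2), (1,3), ..., (1,C), (2,3), ...,
#' (C-1,C). With C = 53 this yields the 1378 connectivity features.
#'
#' @param n_icns Number of ICNs C.
#' @param labels Optional ICN labels (length C) used to name the pairs.
#' @return A data frame with columns `i`, `j` (i < j) and `pair` labels.
#' @export
upper_pair_index <- function(n_icns, labels = NULL) {
  if (n_icns < 2L) stop("need at least 2 ICNs")
  i <- rep(seq_len(n_icns - 1L), times = (n_icns - 1L):1L)
  j <- unlist(lapply(seq_len(n_icns - 1L), function(a) (a + 1L):n_icns))
  if (is.null(labels)) labels <- sprintf("ICN%02d", seq_len(n_icns))
  data.frame(i = i, j = j, pair = paste(labels[i], labels[j], sep = "--"),
             stringsAsFactors = FALSE)
}

#' Static functional network connectivity matrix
#'
#' Pearson correlation between all pairs of post-processed ICN time
#' courses: the whole-scan C x C connectivity matrix with unit diagonal.
#'
#' @param tc An [icn_timecourses()] object (post-processed).
#' @return A C x C correlation matrix of class `fnc_matrix` with attribute
#'   `kind = "pearson"`.
#' @export
compute_sfnc <- function(tc) {
  stopifnot_tc(tc)
  v <- apply(tc$data, 2L, var)
  if (any(v == 0))
    stop(sprintf("zero-variance ICN column(s): %s",
                 paste(colnames(tc$data)[v == 0], collapse = ", ")))
  m <- cor(tc$data)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  structure(m, class = c("fnc_matrix", "matrix"), kind = "pearson")
}

#' Z-score a connectivity matrix within scan
#'
#' Standardizes the off-diagonal entries to mean 0 and SD 1 over the scan's
#' own upper triangle, re-symmetrizes, and zeroes the diagonal. This is the
#' only z-scoring scope computable per scan without sharing statistics
#' across subjects; a cohort-wide alternative is applied at the feature
#' level by [zscore_features()].
#'
#' @param m An `fnc_matrix` (or plain symmetric matrix).
#' @return The standardized `fnc_matrix` with `kind = "zscored"`.
#' @export
zscore_fnc <- function(m) {
  m <- as_sym_matrix(m)
  ut <- m[upper.tri(m)]
  if (length(unique(ut)) < 2L)
    stop("constant off-diagonal: cannot z-score")
  z <- (m - mean(ut)) / sd(ut)
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  diag(z) <- 0
  structure(z, class = c("fnc_matrix", "matrix"), kind = "zscored")
}

#' Standardize each connectivity feature across the cohort
#'
#' Alternative z-scoring scope: column-wise standardization of an N x P
#' feature matrix (each connectivity feature centred and scaled across
#' subjects).
#'
#' @param features Numeric N x P matrix.
#' @return The standardized matrix.
#' @export
zscore_features <- function(features) {
  s <- apply(features, 2L, sd)
  if (any(s == 0)) stop("constant feature column: cannot z-score")
  scale(features)[, , drop = FALSE]
}

as_sym_matrix <- function(m, tol = 1e-8) {
  m <- unclass(as.matrix(m))
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m))))
    stop("matrix is not symmetric within tolerance")
  (m + t(m)) / 2
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Extracts the strict upper triangle in the frozen row-major pair order of
#' [upper_pair_index()]; with C = 53 the result has 1378 entries.
#'
#' @param m A symmetric C x C matrix.
#' @return Numeric vector of length C(C-1)/2, named by ICN pair, with the
#'   pair index attached as attribute `pair_index`.
#' @export
vectorize_upper <- function(m) {
  m <- as_sym_matrix(m)
  pairs <- upper_pair_index(nrow(m), colnames(m))
  v <- m[cbind(pairs$i, pairs$j)]
  names(v) <- pairs$pair
  attr(v, "pair_index") <- pairs
  v
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper()] up to the diagonal, which is set to
#' `diag_value` (0 by default, matching z-scored matrices).
#'
#' @param v Length-C(C-1)/2 vector in the frozen pair order.
#' @param diag_value Value placed on the diagonal.
#' @return A C x C symmetric matrix.
#' @export
devectorize_upper <- function(v, diag_value = 0) {
  p <- length(v)
  C <- (1 + sqrt(1 + 8 * p)) / 2
  if (C != round(C)) stop("length is not C(C-1)/2 for any integer C")
  C <- as.integer(C)
  pairs <- upper_pair_index(C)
  m <- matrix(0, C, C)
  m[cbind(pairs$i, pairs$j)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Session-difference connectivity features
#'
#' Element-wise v1 - v3 difference of two feature vectors in matching pair
#' order (baseline minus post-series, the convention used for outcome
#' change features).
#'
#' @param v1,v3 Feature vectors from [vectorize_upper()] (or any aligned
#'   numeric vectors).
#' @return The difference vector, keeping names and pair index.
#' @export
delta_features <- function(v1, v3) {
  if (length(v1) != length(v3)) stop("feature vectors differ in length")
  if (!is.null(names(v1)) && !is.null(names(v3)) &&
      !identical(names(v1), names(v3)))
    stop("feature labels do not match between sessions")
  out <- v1 - v3
  attr(out, "pair_index") <- attr(v1, "pair_index")
  out
}
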