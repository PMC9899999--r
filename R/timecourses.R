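#' ICN time-course container
#'
#' Bundles one scan's network time courses with its motion parameters and
#' sampling interval. `data` holds one column per intrinsic connectivity
#' network (ICN) and one row per acquired volume; `motion` holds the six
#' rigid-body realignment parameters for the same volumes.
#'
#' @param data Numeric T x C matrix of network time courses (columns may be
#'   named with ICN labels; unnamed columns are labelled `ICN01`, ...).
#' @param motion Numeric T x 6 matrix of realignment parameters, or `NULL`
#'   for a scan without motion estimates (treated as all-zero).
#' @param tr_seconds Positive sampling interval in seconds.
#' @param subject_id,session_id Identifiers; sessions are conventionally
#'   `"v1"` (baseline) and `"v3"` (post-series).
#' @return An object of class `icn_timecourses`.
#' @export
icn_timecourses <- function(data, motion = NULL, tr_seconds = 0.745,
                            subject_id = "S01", session_id = "v1") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("time-course matrix contains missing values")
  if (ncol(data) < 2L) stop("need at least 2 ICN columns")
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("ICN%02d", seq_len(ncol(data)))
  if (is.null(motion)) {
    motion <- matrix(0, nrow(data), 6L)
  } else {
    motion <- as.matrix(motion)
    storage.mode(motion) <- "double"
  }
  if (nrow(motion) != nrow(data) || ncol(motion) != 6L)
    stop("motion must be a T x 6 matrix aligned with the time courses")
  if (anyNA(motion)) stop("motion matrix contains missing values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar")
  structure(
    list(data = data, motion = motion, tr_seconds = tr_seconds,
         subject_id = as.character(subject_id),
         session_id = as.character(session_id)),
    class = "icn_timecourses")
}

#' @export
print.icn_timecourses <- function(x, ...) {
  cat(sprintf("<icn_timecourses> %s/%s: %d timepoints x %d ICNs, TR = %.3f s\n",
              x$subject_id, x$session_id, nrow(x$data), ncol(x$data),
              x$tr_seconds))
  invisible(x)
}

#' @export
dim.icn_timecourses <- function(x) dim(x$data)

stopifnot_tc <- function(tc) {
  if (!inherits(tc, "icn_timecourses"))
    stop("expected an 'icn_timecourses' object")
  tc
}
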