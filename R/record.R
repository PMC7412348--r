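#' Construct a gait record
#'
#' A `gait_record` holds one subject's two-channel vertical ground reaction
#' force trace (left foot, right foot) on a uniform time grid, together with
#' the class label and optional severity metadata.
#'
#' @param subject_id character scalar.
#' @param label class label; `"HC"`, `"ALS"`, `"PD"`, `"HD"` or `"unknown"`.
#' @param fs sampling rate in Hz.
#' @param time numeric vector of sample times in seconds, strictly increasing
#'   and uniform to a tolerance of `1e-6 / fs`.
#' @param left,right numeric force vectors, same length as `time`, all finite.
#' @param severity optional numeric severity/duration measure (disease
#'   duration in months, Hoehn--Yahr stage, or functional-capacity score,
#'   depending on the group).
#' @return an object of class `gait_record`.
#' @export
gait_record <- function(subject_id, label, fs, time, left, right,
                        severity = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1)
    stop_invalid("subject_id must be a single string")
  label <- match.arg(label, c(ndd_labels(), "unknown"))
  if (!is_number(fs) || fs <= 0) stop_invalid("fs must be a positive number")
  n <- length(time)
  if (n < 2) stop_invalid("a gait record needs at least 2 samples")
  if (length(left) != n || length(right) != n)
    stop_invalid("time, left and right must have equal length (got %d, %d, %d)",
                 n, length(left), length(right))
  if (!all(is.finite(time)) || !all(is.finite(left)) || !all(is.finite(right)))
    stop_invalid("time and force values must all be finite")
  dt <- diff(time)
  if (any(dt <= 0)) stop_invalid("time must be strictly increasing")
  if (max(abs(dt - 1 / fs)) > 1e-6 / fs)
    stop_invalid("time grid is not uniform at fs = %g Hz (max deviation %.3g s)",
                 fs, max(abs(dt - 1 / fs)))
  if (!is.null(severity) && !is_number(severity))
    stop_invalid("severity must be a single finite number or NULL")
  structure(
    list(subject_id = subject_id, label = label, fs = fs,
         time = as.numeric(time), left = as.numeric(left),
         right = as.numeric(right), severity = severity),
    class = "gait_record"
  )
}

#' @export
print.gait_record <- function(x, ...) {
  cat(sprintf("<gait_record %s [%s]> %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$label, length(x$time), x$fs,
              length(x$time) / x$fs))
  invisible(x)
}

#' Select a force channel from a gait record
#'
#' `LF` and `RF` return the left and right foot channels verbatim; `CF`
#' (compound foot) is the elementwise sum of the two.
#'
#' @param record a [gait_record()].
#' @param channel `"LF"`, `"RF"` or `"CF"`.
#' @return numeric force vector.
#' @export
select_channel <- function(record, channel = c("LF", "RF", "CF")) {
  stopifnot(inherits(record, "gait_record"))
  channel <- match.arg(channel)
  switch(channel,
         LF = record$left,
         RF = record$right,
         CF = record$left + record$right)
}
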