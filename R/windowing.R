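#' Windowing parameters
#'
#' Parameters of the overlapping rectangular windowing stage: window length
#' `tw`, start-to-start distance `d` and the leading `trim` removed before
#' segmentation. At the defaults (`tw = 10`, `d = tw/3`, `trim = 20`)
#' consecutive windows overlap by `tw - d` = 6.66 s and a 300-s record yields
#' 82 windows per channel. `d` defaults to exactly `tw/3` (10/3 s), not a
#' decimal approximation: only the exact ratio reproduces the integer window
#' counts of the reference cohort.
#'
#' @param tw window length in seconds.
#' @param d distance between consecutive window starts, `0 < d <= tw`.
#' @param trim leading seconds removed before windowing (>= 0).
#' @return object of class `windowing_params`.
#' @export
windowing_params <- function(tw = 10, d = tw / 3, trim = 20) {
  if (!is_number(tw) || tw <= 0) stop_invalid("tw must be positive")
  if (!is_number(d) || d <= 0 || d > tw)
    stop_invalid("d must satisfy 0 < d <= tw")
  if (!is_number(trim) || trim < 0) stop_invalid("trim must be >= 0")
  structure(list(tw = tw, d = d, trim = trim), class = "windowing_params")
}

#' Expected number of windows
#'
#' Number of overlapping windows obtained from a post-trim signal of length
#' `len` seconds: `floor((len - tw)/d + eps) + 1` per subject, times the
#' number of subjects. The epsilon (1e-9) absorbs decimal representations of
#' `d` (3.33 for 10/3) so boundary-exact layouts count the final window.
#'
#' @param len post-trim signal length in seconds.
#' @param tw window length in seconds.
#' @param d start-to-start distance in seconds.
#' @param n_subjects number of subjects sharing this layout.
#' @return integer window count.
#' @export
expected_window_count <- function(len, tw, d, n_subjects = 1) {
  if (!is_number(len) || !is_number(tw) || !is_number(d))
    stop_invalid("len, tw and d must be single finite numbers")
  if (len < tw) stop_invalid("len (%g s) must be >= tw (%g s)", len, tw)
  if (d <= 0) stop_invalid("d must be positive")
  if (!is_count(n_subjects)) stop_invalid("n_subjects must be a positive integer")
  per <- floor((len - tw) / d + 1e-9) + 1
  as.integer(per * n_subjects)
}

#' Remove the initial walking period
#'
#' Drops the first `round(trim * fs)` samples of every channel and of the
#' time axis, discarding the gait-initiation transient.
#'
#' @param record a [gait_record()].
#' @param trim seconds to remove; must be shorter than the record.
#' @return the trimmed [gait_record()].
#' @export
trim_initial <- function(record, trim = 20) {
  stopifnot(inherits(record, "gait_record"))
  if (!is_number(trim) || trim < 0) stop_invalid("trim must be >= 0")
  if (trim == 0) return(record)
  n <- length(record$time)
  k <- round(trim * record$fs)
  if (k >= n - 1)
    stop_invalid("trim (%g s) leaves fewer than 2 of %d samples", trim, n)
  idx <- (k + 1):n
  gait_record(record$subject_id, record$label, record$fs,
              record$time[idx], record$left[idx], record$right[idx],
              record$severity)
}

#' Segment a force channel into overlapping rectangular windows
#'
#' Window `k` (0-based) starts at `k * d` seconds; start indices are
#' quantized to whole samples by rounding `k * d * fs`. Each window is a
#' verbatim copy of the signal (rectangular window, no taper).
#'
#' @param x numeric force vector (one channel, already trimmed).
#' @param fs sampling rate in Hz.
#' @param params a [windowing_params()]; its `trim` is *not* applied here.
#' @param subject_id,label,channel provenance recorded in the window set.
#' @return object of class `window_set`: list with `samples` (matrix, one
#'   window per row), `meta` (data frame: subject_id, label, channel, start
#'   seconds), `params`, `fs`.
#' @export
window_signal <- function(x, fs, params = windowing_params(),
                          subject_id = "s1", label = "unknown",
                          channel = "LF") {
  stopifnot(inherits(params, "windowing_params"), is.numeric(x))
  if (!is_number(fs) || fs <= 0) stop_invalid("fs must be positive")
  n <- length(x)
  wlen <- round(params$tw * fs)
  if (n < wlen)
    stop_invalid("signal too short: %d samples < one %g-s window (%d samples)",
                 n, params$tw, wlen)
  len_s <- n / fs
  K <- expected_window_count(len_s, params$tw, params$d, 1)
  starts <- round((seq_len(K) - 1) * params$d * fs)
  starts <- pmin(starts, n - wlen)  # guard against rounding past the end
  samples <- matrix(0, K, wlen)
  for (k in seq_len(K)) samples[k, ] <- x[(starts[k] + 1):(starts[k] + wlen)]
  meta <- data.frame(subject_id = subject_id, label = label,
                     channel = channel, start = starts / fs,
                     stringsAsFactors = FALSE)
  structure(list(samples = samples, meta = meta, params = params, fs = fs),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows x %d samples (tw %g s, d %g s, fs %g Hz)\n",
              nrow(x$samples), ncol(x$samples), x$params$tw, x$params$d, x$fs))
  invisible(x)
}

#' Trim and window one channel of a record
#'
#' Convenience wrapper: applies `params$trim` with [trim_initial()], selects
#' `channel` and calls [window_signal()].
#'
#' @param record a [gait_record()].
#' @param channel `"LF"`, `"RF"` or `"CF"`.
#' @param params a [windowing_params()].
#' @return a `window_set`.
#' @export
window_record <- function(record, channel = "LF",
                          params = windowing_params()) {
  trimmed <- if (params$trim > 0) trim_initial(record, params$trim) else record
  window_signal(select_channel(trimmed, channel), trimmed$fs, params,
                subject_id = record$subject_id, label = record$label,
                channel = channel)
}

#' Combine window sets
#'
#' Row-binds the sample matrices and metadata of several `window_set`s that
#' share windowing parameters and sampling rate.
#'
#' @param sets list of `window_set` objects.
#' @return one `window_set`.
#' @export
bind_window_sets <- function(sets) {
  stopifnot(length(sets) >= 1,
            all(vapply(sets, inherits, logical(1), "window_set")))
  wl <- vapply(sets, function(s) ncol(s$samples), numeric(1))
  if (length(unique(wl)) != 1)
    stop_invalid("window sets have differing window lengths")
  structure(list(samples = do.call(rbind, lapply(sets, `[[`, "samples")),
                 meta = do.call(rbind, lapply(sets, `[[`, "meta")),
                 params = sets[[1]]$params, fs = sets[[1]]$fs),
            class = "window_set")
}
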