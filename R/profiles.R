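#' Gait class profile
#'
#' A parametric description of one diagnostic group's gait-force statistics,
#' used by [simulate_subject()] to draw vertical ground reaction force (vGRF)
#' traces. Stride-to-stride variability is controlled by coefficients of
#' variation (CV), stance geometry by the stance fraction and the depth of the
#' valley between the loading-response and push-off force peaks.
#'
#' @param label class label, one of `"HC"`, `"ALS"`, `"PD"`, `"HD"`.
#' @param stride_mean mean stride interval in seconds (> 0).
#' @param stride_cv coefficient of variation of the stride interval (>= 0).
#' @param stance_fraction_mean mean fraction of the stride spent in stance,
#'   strictly between 0 and 1.
#' @param stance_fraction_cv CV of the stance fraction (>= 0).
#' @param peak_amplitude stance peak force in arbitrary (body-weight
#'   normalized) units.
#' @param double_peak_depth depth in `[0, 1]` of the mid-stance valley
#'   relative to the peaks; 0 merges the two peaks, values near 1 separate
#'   them sharply.
#' @param swing_noise_sd standard deviation of the additive sensor noise, in
#'   force units.
#' @return an object of class `gait_profile`.
#' @seealso [ndd_profiles()] for the built-in defaults.
#' @export
gait_profile <- function(label,
                         stride_mean,
                         stride_cv,
                         stance_fraction_mean,
                         stance_fraction_cv,
                         peak_amplitude = 1,
                         double_peak_depth = 0.3,
                         swing_noise_sd = 0.01) {
  label <- match.arg(label, ndd_labels())
  if (!is_number(stride_mean) || stride_mean <= 0)
    stop_invalid("stride_mean must be a positive number")
  if (!is_number(stride_cv) || stride_cv < 0)
    stop_invalid("stride_cv must be >= 0")
  if (!is_number(stance_fraction_mean) ||
      stance_fraction_mean <= 0 || stance_fraction_mean >= 1)
    stop_invalid("stance_fraction_mean must lie strictly in (0, 1)")
  if (!is_number(stance_fraction_cv) || stance_fraction_cv < 0)
    stop_invalid("stance_fraction_cv must be >= 0")
  if (!is_number(peak_amplitude) || peak_amplitude <= 0)
    stop_invalid("peak_amplitude must be positive")
  if (!is_number(double_peak_depth) ||
      double_peak_depth < 0 || double_peak_depth > 1)
    stop_invalid("double_peak_depth must lie in [0, 1]")
  if (!is_number(swing_noise_sd) || swing_noise_sd < 0)
    stop_invalid("swing_noise_sd must be >= 0")
  structure(
    list(
      label = label,
      stride_mean = stride_mean,
      stride_cv = stride_cv,
      stance_fraction_mean = stance_fraction_mean,
      stance_fraction_cv = stance_fraction_cv,
      peak_amplitude = peak_amplitude,
      double_peak_depth = double_peak_depth,
      swing_noise_sd = swing_noise_sd
    ),
    class = "gait_profile"
  )
}

#' Default class profiles for the four diagnostic groups
#'
#' The defaults encode the qualitative gait phenomenology of each group:
#' healthy controls walk with regular, consistent stance and swing intervals;
#' ALS gait has a prolonged stance phase with a pronounced double force peak;
#' Parkinsonian gait has irregular stride and swing timing; Huntington gait is
#' the most irregular, with stance and swing of roughly equal duration.
#' Stride-interval irregularity is strictly ordered
#' `HC < ALS < PD < HD` by `stride_cv`. Stride durations are consistent with a
#' self-selected walking speed of roughly 1.0--1.4 m/s.
#'
#' @return named list of [gait_profile()] objects, ordered `HC, ALS, PD, HD`.
#' @export
ndd_profiles <- function() {
  list(
    HC = gait_profile("HC",
      stride_mean = 1.10, stride_cv = 0.02,
      stance_fraction_mean = 0.62, stance_fraction_cv = 0.02,
      peak_amplitude = 1.0, double_peak_depth = 0.25,
      swing_noise_sd = 0.010),
    ALS = gait_profile("ALS",
      stride_mean = 1.40, stride_cv = 0.05,
      stance_fraction_mean = 0.72, stance_fraction_cv = 0.04,
      peak_amplitude = 1.0, double_peak_depth = 0.45,
      swing_noise_sd = 0.010),
    PD = gait_profile("PD",
      stride_mean = 1.20, stride_cv = 0.09,
      stance_fraction_mean = 0.65, stance_fraction_cv = 0.08,
      peak_amplitude = 0.9, double_peak_depth = 0.15,
      swing_noise_sd = 0.015),
    HD = gait_profile("HD",
      stride_mean = 1.25, stride_cv = 0.14,
      stance_fraction_mean = 0.50, stance_fraction_cv = 0.12,
      peak_amplitude = 0.9, double_peak_depth = 0.40,
      swing_noise_sd = 0.015)
  )
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(
    "<gait_profile %s> stride %.2f s (cv %.2f), stance %.0f%% (cv %.2f), peak %.2f, valley depth %.2f\n",
    x$label, x$stride_mean, x$stride_cv, 100 * x$stance_fraction_mean,
    x$stance_fraction_cv, x$peak_amplitude, x$double_peak_depth))
  invisible(x)
}
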