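#' Simulate one subject's vGRF trace
#'
#' Draws a two-channel vertical ground reaction force trace with gait-cycle
#' structure: each stride consists of a stance burst -- a double-peaked force
#' pulse with peaks at 25% and 75% of stance -- followed by a near-zero swing
#' interval. Per-stride durations are i.i.d. lognormal with the profile's
#' mean and coefficient of variation; the stance fraction of each stride is
#' drawn the same way. The right foot runs in antiphase with the left (its
#' first stance begins near mid-left-stride, jittered by the stride CV).
#' Additive Gaussian sensor noise is applied and the trace clipped at zero,
#' so forces are always nonnegative.
#'
#' @param profile a [gait_profile()].
#' @param duration trace duration in seconds (>= one mean stride).
#' @param fs sampling rate in Hz; the record has `round(duration * fs)`
#'   samples per channel.
#' @param seed integer seed; identical arguments give bit-identical records.
#' @param subject_id optional id; defaults to the lowercased label plus seed.
#' @return a [gait_record()].
#' @export
simulate_subject <- function(profile, duration = 300, fs = 300, seed = 1L,
                             subject_id = NULL) {
  stopifnot(inherits(profile, "gait_profile"))
  if (!is_number(duration) || duration <= 0)
    stop_invalid("duration must be a positive number of seconds")
  if (!is_number(fs) || fs <= 0)
    stop_invalid("fs must be a positive sampling rate in Hz")
  if (duration < profile$stride_mean)
    stop_invalid("duration (%g s) must cover at least one mean stride (%g s)",
                 duration, profile$stride_mean)
  subject_id <- subject_id %||% sprintf("%s_s%d", tolower(profile$label),
                                        as.integer(seed))
  n <- round(duration * fs)
  time <- (seq_len(n) - 1) / fs

  local_seed_eval(seed, {
    left <- sim_channel(profile, duration, fs, n, offset = 0)
    off <- 0.5 * profile$stride_mean *
      (1 + profile$stride_cv * stats::rnorm(1))
    off <- max(off, 0.05 * profile$stride_mean)
    right <- sim_channel(profile, duration, fs, n, offset = off)
    if (profile$swing_noise_sd > 0) {
      left <- left + stats::rnorm(n, 0, profile$swing_noise_sd)
      right <- right + stats::rnorm(n, 0, profile$swing_noise_sd)
    }
    gait_record(subject_id, profile$label, fs, time,
                pmax(left, 0), pmax(right, 0))
  })
}

# One foot's noiseless stance-pulse train. Consumes RNG sequentially so the
# whole subject is reproducible from a single seed.
sim_channel <- function(profile, duration, fs, n, offset) {
  lm <- lognormal_pars(profile$stride_mean, profile$stride_cv)
  fm <- lognormal_pars(profile$stance_fraction_mean,
                       profile$stance_fraction_cv)
  sig <- numeric(n)
  t0 <- offset
  while (t0 < duration) {
    stride <- stats::rlnorm(1, lm$meanlog, lm$sdlog)
    frac <- min(max(stats::rlnorm(1, fm$meanlog, fm$sdlog), 0.15), 0.9)
    stance <- frac * stride
    sig <- add_stance_pulse(sig, fs, t0, stance,
                            profile$peak_amplitude,
                            profile$double_peak_depth)
    t0 <- t0 + stride
  }
  sig
}

lognormal_pars <- function(m, cv) {
  s2 <- log(1 + cv^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# Double-bump stance pulse: Gaussian bumps at 25% and 75% of stance, with the
# bump width set so the mid-stance valley sits at (1 - depth) of the peaks.
add_stance_pulse <- function(sig, fs, t0, stance, amplitude, depth) {
  n <- length(sig)
  i0 <- max(1L, floor(t0 * fs) + 1L)
  i1 <- min(n, ceiling((t0 + stance) * fs) + 1L)
  if (i1 <= i0) return(sig)
  d <- min(depth, 0.97)
  sigma <- 0.25 / sqrt(2 * log(2 / (1 - d)))
  u <- (((i0:i1) - 1) / fs - t0) / stance
  bump <- exp(-(u - 0.25)^2 / (2 * sigma^2)) +
    exp(-(u - 0.75)^2 / (2 * sigma^2))
  peak <- 1 + exp(-0.25 / (2 * sigma^2))  # both bumps contribute at u = 0.25
  sig[i0:i1] <- sig[i0:i1] + amplitude * bump / peak
  sig
}

#' Simulate a labeled cohort
#'
#' Generates `subjects_per_class` records for every profile, with per-subject
#' seeds derived deterministically from `seed` so the whole cohort is
#' reproducible bit-for-bit.
#'
#' @param subjects_per_class number of subjects per label (>= 1).
#' @param duration,fs passed to [simulate_subject()].
#' @param seed cohort seed.
#' @param profiles named list of [gait_profile()] objects; defaults to the
#'   four-group [ndd_profiles()].
#' @return object of class `gait_cohort`: a list with `records` (list of
#'   [gait_record()]) and `manifest` (data frame of subject id, label, seed
#'   and profile parameters).
#' @export
simulate_cohort <- function(subjects_per_class = 4, duration = 300, fs = 300,
                            seed = 1L, profiles = ndd_profiles()) {
  if (!is_count(subjects_per_class))
    stop_invalid("subjects_per_class must be a positive integer")
  stopifnot(length(profiles) >= 1, !is.null(names(profiles)))
  records <- list()
  rows <- list()
  idx <- 0L
  for (lab in names(profiles)) {
    prof <- profiles[[lab]]
    for (i in seq_len(subjects_per_class)) {
      idx <- idx + 1L
      sseed <- derive_seed(seed, idx)
      id <- sprintf("%s%02d", tolower(lab), i)
      records[[id]] <- simulate_subject(prof, duration, fs, sseed,
                                        subject_id = id)
      rows[[idx]] <- data.frame(
        subject_id = id, label = prof$label, seed = sseed,
        stride_mean = prof$stride_mean, stride_cv = prof$stride_cv,
        stance_fraction_mean = prof$stance_fraction_mean,
        stance_fraction_cv = prof$stance_fraction_cv,
        peak_amplitude = prof$peak_amplitude,
        double_peak_depth = prof$double_peak_depth,
        swing_noise_sd = prof$swing_noise_sd,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(records = records,
                 manifest = do.call(rbind, rows),
                 duration = duration, fs = fs, seed = seed),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d records (%s) @ %g Hz, %.0f s each\n",
              length(x$records),
              paste(sprintf("%s: %d", names(table(x$manifest$label)),
                            as.integer(table(x$manifest$label))),
                    collapse = ", "),
              x$fs, x$duration))
  invisible(x)
}

#' Drop subjects from a cohort by id
#'
#' Explicit, auditable exclusion of subjects (e.g. records deemed corrupt in
#' an external dataset). Unknown ids are an error so silent typos cannot
#' change the cohort.
#'
#' @param cohort a `gait_cohort`.
#' @param exclude character vector of subject ids to remove.
#' @return the cohort without the excluded subjects.
#' @export
apply_exclusions <- function(cohort, exclude) {
  stopifnot(inherits(cohort, "gait_cohort"))
  if (length(exclude) == 0) return(cohort)
  missing <- setdiff(exclude, names(cohort$records))
  if (length(missing) > 0)
    stop_invalid("exclusion list names unknown subject(s): %s",
                 paste(missing, collapse = ", "))
  cohort$records <- cohort$records[setdiff(names(cohort$records), exclude)]
  cohort$manifest <- cohort$manifest[
    !(cohort$manifest$subject_id %in% exclude), , drop = FALSE]
  cohort
}

#' Write a cohort to delimited text files
#'
#' One three-column file per subject (time, left force, right force) plus a
#' `manifest.csv` with labels, seeds and profile parameters.
#'
#' @param cohort a `gait_cohort`.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths of the written record files.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(cohort$records)) {
    p <- file.path(dir, paste0(id, ".txt"))
    write_gait_record(cohort$records[[id]], p)
    paths <- c(paths, p)
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(paths)
}
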