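# Independent oracles and shared fixtures for the test suite.
# These deliberately avoid the package's own signal path: burst detection is
# plain thresholding + run-length bookkeeping, resampling oracles are brute
# force block means, eigen oracles call eigen() on the explicitly formed
# scatter matrix.

# Segment stance bursts by thresholding at a fraction of the peak, merging
# gaps shorter than 0.2 s (debounce against single-sample flicker at the
# pulse edges) and dropping segments shorter than 0.1 s.
burst_segments <- function(x, fs, th_frac = 0.5) {
  ab <- x > th_frac * max(x)
  r <- rle(ab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  stopifnot(nrow(seg) >= 2)
  merged <- seg[1, , drop = FALSE]
  for (i in seq_len(nrow(seg))[-1]) {
    if ((seg$start[i] - merged$end[nrow(merged)]) / fs < 0.2) {
      merged$end[nrow(merged)] <- seg$end[i]
    } else {
      merged <- rbind(merged, seg[i, ])
    }
  }
  merged[(merged$end - merged$start) / fs >= 0.1, ]
}

# Empirical stride-interval CV and stance fraction from a force trace.
burst_stats <- function(x, fs) {
  b <- burst_segments(x, fs)
  iv <- diff(b$start) / fs
  list(cv = stats::sd(iv) / mean(iv),
       stride = mean(iv),
       stance_fraction = mean((b$end - b$start) / fs) / mean(iv))
}

# Brute-force k x k block mean of a matrix (area-average downsampling).
block_mean <- function(m, k) {
  g <- nrow(m) / k
  out <- matrix(0, g, g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    out[i, j] <- mean(m[((i - 1) * k + 1):(i * k), ((j - 1) * k + 1):(j * k)])
  }
  out
}

# Small, quick cohort used by several test files.
tiny_cohort <- function(subjects_per_class = 2, duration = 45, fs = 30,
                        seed = 11) {
  simulate_cohort(subjects_per_class, duration, fs, seed)
}

# Table of the published two-class 10-s-window results (LF/RF/CF columns of
# sensitivity %, specificity %, printed AUC), transcribed once and reused by
# the metric regression tests.
published_binary_table <- function() {
  rows <- list(
    list(task = "ALS vs. HC", sens = c(100, 100, 100),
         spec = c(100, 100, 100), auc = c(1, 1, 1)),
    list(task = "HD vs. HC", sens = c(98.54, 97.59, 98.51),
         spec = c(98.25, 98.60, 96.41), auc = c(0.9839, 0.9810, 0.9746)),
    list(task = "PD vs. HC", sens = c(100, 100, 100),
         spec = c(100, 100, 100), auc = c(1, 1, 1)),
    list(task = "ALS vs. HD", sens = c(100, 100, 100),
         spec = c(100, 100, 100), auc = c(1, 1, 1)),
    list(task = "PD vs. ALS", sens = c(94.07, 94.59, 92.95),
         spec = c(97.63, 97.65, 95.78), auc = c(0.9585, 0.9612, 0.9437)),
    list(task = "HD vs. PD", sens = c(96.81, 96.54, 93.54),
         spec = c(97.51, 98.24, 97.14), auc = c(0.9711, 0.9739, 0.9534)),
    list(task = "NDD vs. HC", sens = c(99.01, 99.04, 99.44),
         spec = c(98.38, 98.53, 97.43), auc = c(0.9870, 0.9878, 0.9844))
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(task = r$task, channel = c("LF", "RF", "CF"),
               sens = r$sens / 100, spec = r$spec / 100, auc = r$auc,
               stringsAsFactors = FALSE)
  }))
}
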