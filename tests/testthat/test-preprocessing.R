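test_that("expected_window_count reproduces the reference arithmetic", {
  # 280 s post-trim, 10-s windows every 10/3 s: 82 per subject, 1312 for 16
  expect_identical(expected_window_count(280, 10, 10 / 3, 16), 1312L)
  expect_identical(expected_window_count(280, 10, 10 / 3, 1), 82L)
  # a window that exactly fits yields one window regardless of d
  expect_identical(expected_window_count(10, 10, 3, 1), 1L)
  # enumerated starts 0, 5, 10, 15, 20 -> 5 windows x 2 subjects
  expect_identical(expected_window_count(30, 10, 5, 2), 10L)
  # the epsilon absorbs the decimal rendering of d = 10/3 as 3.33
  expect_identical(expected_window_count(280, 10, 3.33, 1), 82L)
  expect_error(expected_window_count(5, 10, 3, 1), ">= tw")
  expect_error(expected_window_count(30, 10, 0, 1), "positive")
})

test_that("full-cohort bookkeeping reproduces the published class totals", {
  sizes <- c(HC = 16L, ALS = 13L, PD = 15L, HD = 20L)
  counts <- vapply(sizes, function(T)
    expected_window_count(280, 10, 10 / 3, T), integer(1))
  expect_identical(counts,
                   c(HC = 1312L, ALS = 1066L, PD = 1230L, HD = 1640L))
  expect_identical(sum(counts), 5248L)
})

test_that("trim_initial drops exactly the leading samples", {
  r <- simulate_subject(ndd_profiles()$HC, 300, 10, seed = 4)
  tr <- trim_initial(r, 20)
  expect_length(tr$left, (300 - 20) * 10)
  expect_identical(tr$left, r$left[-(1:200)])
  expect_identical(trim_initial(r, 0), r)
  # 299.5 s trimmed from a 300-s record at 100 Hz leaves 50 samples
  r2 <- simulate_subject(ndd_profiles()$HC, 300, 100, seed = 4)
  expect_length(trim_initial(r2, 299.5)$left, 50)
  expect_error(trim_initial(r, 300), "trim")
})

test_that("window_signal enumerates rectangular windows verbatim", {
  fs <- 30
  x <- seq_len(280 * fs) / fs
  ws <- window_signal(x, fs, windowing_params(tw = 10, d = 10 / 3))
  expect_identical(nrow(ws$samples), 82L)
  expect_identical(ncol(ws$samples), 300L)
  # verbatim copy, no taper
  expect_identical(ws$samples[1, ], x[1:300])
  expect_identical(ws$samples[5, ], x[(round(4 * 10 / 3 * fs) + 1):(round(4 * 10 / 3 * fs) + 300)])
  # single exact window
  one <- window_signal(x[1:300], fs, windowing_params(tw = 10, d = 10 / 3))
  expect_identical(nrow(one$samples), 1L)
  expect_identical(one$samples[1, ], x[1:300])
  # 16.6ȳ-s signal -> 3 windows at starts 0, 10/3, 20/3
  x3 <- seq_len(1000)  # 50/3 s at 60 Hz
  ws3 <- window_signal(x3, 60, windowing_params(tw = 10, d = 10 / 3))
  expect_identical(nrow(ws3$samples), 3L)
  expect_equal(ws3$meta$start, c(0, 200, 400) / 60)
  expect_error(window_signal(x3[1:100], 60, windowing_params(tw = 10)),
               "too short")
})

test_that("consecutive windows overlap by exactly tw - d", {
  fs <- 30
  params <- windowing_params(tw = 10, d = 10 / 3)
  r <- simulate_subject(ndd_profiles()$PD, 60, fs, seed = 6)
  ws <- window_record(r, "LF", windowing_params(tw = 10, d = 10 / 3,
                                                trim = 20))
  ov <- round((params$tw - params$d) * fs)  # 200 samples = 6.66 s
  for (k in seq_len(nrow(ws$samples) - 1)) {
    tail_k <- ws$samples[k, (ncol(ws$samples) - ov + 1):ncol(ws$samples)]
    head_k1 <- ws$samples[k + 1, 1:ov]
    expect_identical(tail_k, head_k1)
  }
  # starts form an arithmetic sequence with step d (to sample quantization)
  expect_equal(diff(ws$meta$start), rep(params$d, nrow(ws$samples) - 1),
               tolerance = 1 / fs)
})

test_that("5-min mode: one window spanning the whole post-trim record", {
  fs <- 20
  r <- simulate_subject(ndd_profiles()$HC, 120, fs, seed = 2)
  params <- windowing_params(tw = 100, d = 100, trim = 20)
  ws <- window_record(r, "LF", params)
  expect_identical(nrow(ws$samples), 1L)
  expect_equal(ncol(ws$samples), 100 * fs)
})
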