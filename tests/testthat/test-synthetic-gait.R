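test_that("profile invariants hold for the default class profiles", {
  p <- ndd_profiles()
  expect_named(p, c("HC", "ALS", "PD", "HD"))
  cvs <- vapply(p, `[[`, numeric(1), "stride_cv")
  expect_true(all(diff(cvs[c("HC", "ALS", "PD", "HD")]) > 0))
  expect_gt(p$ALS$stance_fraction_mean, p$HC$stance_fraction_mean)
  expect_equal(p$HD$stance_fraction_mean, 0.5, tolerance = 0.05)
  for (prof in p) {
    expect_gt(prof$stride_mean, 0)
    expect_true(prof$stance_fraction_mean > 0 &&
                prof$stance_fraction_mean < 1)
    expect_true(prof$double_peak_depth >= 0 && prof$double_peak_depth <= 1)
  }
})

test_that("profile constructor rejects invalid parameters", {
  expect_error(gait_profile("HC", stride_mean = -1, stride_cv = 0.1,
                            stance_fraction_mean = 0.6,
                            stance_fraction_cv = 0.1), "stride_mean")
  expect_error(gait_profile("HC", stride_mean = 1, stride_cv = 0.1,
                            stance_fraction_mean = 1.2,
                            stance_fraction_cv = 0.1), "stance_fraction")
  expect_error(gait_profile("HC", stride_mean = 1, stride_cv = 0.1,
                            stance_fraction_mean = 0.6,
                            stance_fraction_cv = 0.1,
                            double_peak_depth = 1.5), "double_peak_depth")
})

test_that("simulate_subject honors the length and determinism contracts", {
  p <- ndd_profiles()$HC
  r <- simulate_subject(p, duration = 300, fs = 100, seed = 7)
  expect_identical(length(r$left), 30000L)
  expect_identical(length(r$right), 30000L)
  r2 <- simulate_subject(p, duration = 300, fs = 100, seed = 7)
  expect_identical(r$left, r2$left)
  expect_identical(r$right, r2$right)
  expect_identical(r$time, r2$time)
  r3 <- simulate_subject(p, duration = 300, fs = 100, seed = 8)
  expect_false(identical(r$left, r3$left))
  expect_error(simulate_subject(p, duration = -5, fs = 100, seed = 1),
               "duration")
  expect_error(simulate_subject(p, duration = 10, fs = -1, seed = 1), "fs")
})

test_that("generated forces are nonnegative with near-zero swing intervals", {
  for (lab in c("HC", "HD")) {
    r <- simulate_subject(ndd_profiles()[[lab]], 60, 50, seed = 3)
    for (x in list(r$left, r$right)) {
      expect_true(all(x >= 0))
      swing <- x[x < 0.2 * max(x)]
      expect_lt(mean(swing), 0.05 * max(x))
    }
  }
})

test_that("empirical stride irregularity separates HC from HD", {
  cohort_cv <- function(label, n = 6) {
    vapply(seq_len(n), function(s) {
      r <- simulate_subject(ndd_profiles()[[label]], 120, 50,
                            seed = 100 + s)
      burst_stats(r$left, r$fs)$cv
    }, numeric(1))
  }
  cv_hc <- cohort_cv("HC")
  cv_hd <- cohort_cv("HD")
  expect_lt(mean(cv_hc), mean(cv_hd))
  expect_lt(max(cv_hc), min(cv_hd))  # strict separation at defaults
})

test_that("cohort generation is deterministic with correct class counts", {
  co <- simulate_cohort(4, duration = 30, fs = 25, seed = 5)
  expect_length(co$records, 16)
  expect_equal(unname(table(co$manifest$label)[c("HC", "ALS", "PD", "HD")]),
               rep(4L, 4), ignore_attr = TRUE)
  co2 <- simulate_cohort(4, duration = 30, fs = 25, seed = 5)
  expect_identical(lapply(co$records, `[[`, "left"),
                   lapply(co2$records, `[[`, "left"))
  expect_identical(co$manifest, co2$manifest)
})

test_that("cohort-level stance fraction is larger for ALS than HC", {
  co <- simulate_cohort(4, duration = 90, fs = 50, seed = 21)
  frac <- function(lab) {
    ids <- co$manifest$subject_id[co$manifest$label == lab]
    mean(vapply(ids, function(id)
      burst_stats(co$records[[id]]$left, co$fs)$stance_fraction,
      numeric(1)))
  }
  expect_gt(frac("ALS"), frac("HC"))
})

test_that("exclusion list removes exactly the named subjects", {
  co <- tiny_cohort()
  out <- apply_exclusions(co, c("hc01", "pd02"))
  expect_length(out$records, length(co$records) - 2)
  expect_false(any(c("hc01", "pd02") %in% out$manifest$subject_id))
  expect_error(apply_exclusions(co, "nosuch01"), "unknown subject")
  expect_identical(apply_exclusions(co, character()), co)
})
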