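test_that("band-pass frequency response matches the design", {
  rec <- sine_recording(10, 40)                     # mid-band 10 Hz
  out <- bandpass_filter(rec)
  mid <- seq(2000, 8000)                            # avoid edges
  gain <- stats::sd(out$data[1, mid]) / stats::sd(rec$data[1, mid])
  expect_lt(abs(gain - 1), 0.05)

  rec40 <- sine_recording(40, 40)                   # one octave above 20 Hz
  out40 <- bandpass_filter(rec40)
  att_db <- -20 * log10(stats::sd(out40$data[1, mid]) /
                          stats::sd(rec40$data[1, mid]))
  expect_gt(att_db, 12)

  recdc <- sine_recording(10, 5, dc = 50)           # 50 uV offset
  outdc <- bandpass_filter(recdc)
  expect_lt(abs(mean(outdc$data[1, mid])), 1)

  expect_identical(out$events, rec$events)          # markers untouched
  expect_error(bandpass_filter(sine_recording(10, 1), high = 260),
               "invalid band")
  expect_error(bandpass_filter(sine_recording(10, 1), low = 30, high = 20),
               "invalid band")
})

test_that("resampling preserves in-band content and remaps events", {
  rec <- sine_recording(5, 20, rate = 500, dur_s = 10)
  out <- resample_recording(rec, 256)
  t_new <- (seq_len(ncol(out$data)) - 1) / 256
  analytic <- 20 * sin(2 * pi * 5 * t_new)
  mid <- seq(200, length(t_new) - 200)
  expect_lt(max(abs(out$data[1, mid] - analytic[mid])), 0.05)
  expect_gt(stats::cor(out$data[1, mid], analytic[mid]), 0.999)
  # duration preserved within one sample
  expect_lt(abs(recording_duration(out) - recording_duration(rec)), 1 / 256)

  # event at 500-Hz sample 500 lands at 256-Hz sample 256
  rec$events$onset_sample[1] <- 500L
  out <- resample_recording(rec, 256)
  expect_identical(out$events$onset_sample[1], 256L)

  expect_identical(resample_recording(rec, 500), rec)  # same rate: identity
  expect_error(resample_recording(rec, 1000), "upsampling")
})

test_that("the three rejection criteria fire on their boundary cases", {
  rate <- 256
  ns <- 300
  base <- 10 * sin(2 * pi * 10 * (seq_len(ns) / rate))
  mk <- function(mod) {
    arr <- array(rep(base, 4 * 3), dim = c(4, ns, 3))
    mod(arr)
  }

  # one 250 uV sample -> amplitude rejection
  ep <- mk(function(a) { a[2, 150, 2] <- 250; a })
  res <- reject_artifact_epochs(toy_epochs(ep), rejection_criteria())
  log <- attr(res, "rejection_log")
  expect_identical(res$trial_meta$kept, c(TRUE, FALSE, TRUE))
  expect_identical(log$criterion[2], "amplitude")

  # all-zero epoch -> low activity
  ep <- mk(function(a) { a[, , 1] <- 0; a })
  res <- reject_artifact_epochs(toy_epochs(ep))
  expect_identical(res$trial_meta$kept, c(FALSE, TRUE, TRUE))
  expect_identical(attr(res, "rejection_log")$criterion[1], "low_activity")

  # +-150 uV step inside 200 ms -> max-diff (amplitude bound not crossed)
  ep <- mk(function(a) {
    a[3, 100:130, 3] <- a[3, 100:130, 3] - 140
    a[3, 131:160, 3] <- a[3, 131:160, 3] + 140
    a
  })
  res <- reject_artifact_epochs(toy_epochs(ep))
  expect_identical(res$trial_meta$kept, c(TRUE, TRUE, FALSE))
  expect_identical(attr(res, "rejection_log")$criterion[3], "max_diff")

  # clean 10 uV sinusoid -> kept everywhere
  res <- reject_artifact_epochs(toy_epochs(mk(identity)))
  expect_true(all(res$trial_meta$kept))
})

test_that("rejection is monotone: adding a transient never rescues a trial", {
  rate <- 256
  set.seed(9)
  arr <- array(stats::rnorm(6 * 400 * 8, sd = 15), dim = c(6, 400, 8))
  clean <- reject_artifact_epochs(toy_epochs(arr))
  kept0 <- clean$trial_meta$kept
  arr2 <- arr
  for (tr in which(kept0)) arr2[4, 200, tr] <- 300  # violating pulse
  dirty <- reject_artifact_epochs(toy_epochs(arr2))
  expect_true(all(!dirty$trial_meta$kept[kept0]))
})

test_that("rejection refuses CSD-stage epochs", {
  arr <- array(stats::rnorm(4 * 300 * 2, sd = 5), dim = c(4, 300, 2))
  ep <- toy_epochs(arr)
  ep <- apply_csd(ep, identity_spatial_mode())
  expect_error(reject_artifact_epochs(ep), "wrong stage")
})
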