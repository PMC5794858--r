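test_that("trial classification follows the task boundaries", {
  expect_identical(classify_trial(1200), "correct")
  expect_identical(classify_trial(399), "miss")
  expect_identical(classify_trial(2001), "miss")
  expect_identical(classify_trial(NA), "miss")
  # shared endpoints resolve to the correct window
  expect_identical(classify_trial(c(1000, 1400)), c("correct", "correct"))
  expect_identical(classify_trial(c(400, 999.9)), c("early", "early"))
  expect_identical(classify_trial(c(1400.1, 2000)), c("late", "late"))
  expect_error(classify_trial(-5), "invalid rt")
})

test_that("classification conserves trial counts on generated behavior", {
  prof <- group_profile("ADHD-C")
  for (s in 1:5) {
    set.seed(s)
    beh <- draw_subject_behavior(prof, quick_cfg(n_trials = 120),
                                 u = stats::rnorm(1))
    cats <- classify_trial(beh$rt_ms)
    expect_identical(length(cats), 120L)
    expect_identical(sum(table(cats)), 120L)
    # the drawn latencies classify back into their sampled categories
    expect_identical(cats, beh$category)
  }
})

test_that("segmentation windows have the documented lengths", {
  cfg <- quick_cfg(n_trials = 12)
  subj <- generate_subject(group_profile("control"), cfg, seed = 2)
  rec <- resample_recording(subj$recording, 256)
  stim <- segment_stimulus(rec)
  expect_identical(dim(stim$data)[2], 1281L)   # [-2000, 3000] ms at 256 Hz
  expect_identical(range(stim$times_ms), c(-2000, 3000))
  fb <- segment_feedback(rec)
  expect_identical(dim(fb$data)[2], 436L)      # [-200, 1500] ms at 256 Hz
  relock <- relock_to_response(stim)
  expect_identical(dim(relock$data)[2], 769L)  # [-2000, 1000] ms at 256 Hz
  # lock sample sits at time zero in every scheme
  for (ep in list(stim, fb, relock)) {
    expect_identical(ep$times_ms[which.min(abs(ep$times_ms))], 0)
  }
})

test_that("baseline correction zeroes a constant channel", {
  cfg <- noisefree_cfg(n_trials = 10)
  subj <- generate_subject(group_profile("control"), cfg, seed = 4)
  rec <- resample_recording(subj$recording, 256)
  rec$data[5, ] <- 7  # constant channel
  stim <- segment_stimulus(rec)
  expect_lt(max(abs(stim$data[5, , ])), 1e-9)
  fb <- segment_feedback(rec)
  expect_lt(max(abs(fb$data[5, , ])), 1e-9)
})

test_that("relocking preserves sample identity and excludes misses", {
  cfg <- quick_cfg(n_trials = 30)
  subj <- generate_subject(group_profile("ADD"), cfg, seed = 6)
  rec <- resample_recording(subj$recording, 256)
  stim <- segment_stimulus(rec)
  relock <- relock_to_response(stim)
  expect_false(any(relock$trial_meta$category == "miss"))
  # value at stimulus-time t equals value at response-relative t - RT
  i0_s <- which.min(abs(stim$times_ms))
  i0_r <- which.min(abs(relock$times_ms))
  for (j in seq_len(min(5, n_trials(relock)))) {
    tr <- match(relock$trial_meta$trial_index[j], stim$trial_meta$trial_index)
    rt <- relock$trial_meta$rt_samples[j]
    # response-relative sample -100 .. 100 maps to stimulus sample rt - 100 ..
    expect_identical(relock$data[, (i0_r - 100):(i0_r + 100), j],
                     stim$data[, (i0_s + rt - 100):(i0_s + rt + 100), tr])
  }
  expect_identical(relock$baseline_applied, TRUE)

  raw <- stim
  raw$baseline_applied <- FALSE
  expect_error(relock_to_response(raw), "baselined")
})

test_that("feedback condition pools early and late responses", {
  cfg <- quick_cfg(n_trials = 40)
  subj <- generate_subject(group_profile("ADD"), cfg, seed = 8)
  rec <- resample_recording(subj$recording, 256)
  fb <- segment_feedback(rec)
  tm <- fb$trial_meta
  expect_true(all(tm$condition[tm$category %in% c("early", "late")] == "error"))
  expect_true(all(tm$condition[tm$category == "correct"] == "correct"))
  expect_false(any(tm$category == "miss"))
})

test_that("epochs exceeding recording bounds are dropped with a warning", {
  cfg <- quick_cfg(n_trials = 6)
  subj <- generate_subject(group_profile("control"), cfg, seed = 12)
  rec <- resample_recording(subj$recording, 256)
  short <- new_recording(rec$data[, seq_len(rec$events$onset_sample[
    rec$events$kind == "stimulus"][6] + 100), drop = FALSE],
    rec$rate, rec$events[rec$events$onset_sample <=
                           rec$events$onset_sample[rec$events$kind == "stimulus"][6] + 100, ],
    rec$montage)
  expect_warning(stim <- segment_stimulus(short), "dropped")
  expect_lt(n_trials(stim), 6)
})
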