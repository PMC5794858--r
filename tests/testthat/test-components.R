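test_that("window_mean averages trials, samples and electrodes", {
  arr <- array(0, dim = c(4, 100, 3))
  arr[1, , ] <- 10
  ep <- toy_epochs(arr)
  ep <- apply_csd(ep, identity_spatial_mode())
  lbl <- ep$montage$labels
  expect_equal(window_mean(ep, lbl[1], c(0, 100)), 10)
  arr[2, , ] <- -10
  ep2 <- apply_csd(toy_epochs(arr), identity_spatial_mode())
  expect_equal(window_mean(ep2, lbl[1:2], c(0, 100)), 0)
})

test_that("component quantification is linear in the signal", {
  set.seed(3)
  arr <- array(stats::rnorm(6 * 200 * 4), dim = c(6, 200, 4))
  ep <- apply_csd(toy_epochs(arr), identity_spatial_mode())
  ep5 <- apply_csd(toy_epochs(5 * arr), identity_spatial_mode())
  lbl <- ep$montage$labels
  w1 <- window_mean(ep, lbl[2:3], c(-100, 50))
  w5 <- window_mean(ep5, lbl[2:3], c(-100, 50))
  expect_equal(w5, 5 * w1, tolerance = 1e-12)
})

test_that("FRN peak-to-peak difference ignores shared constant offsets", {
  cfg <- noisefree_cfg(n_trials = 40)
  subj <- generate_subject(group_profile("control"), cfg, seed = 5)
  rec <- resample_recording(subj$recording, 256)
  fb <- segment_feedback(rec)
  fb_t <- apply_csd(fb, identity_spatial_mode())
  base <- extract_frn(fb_t, component_windows("control"))
  shifted <- fb_t
  shifted$data <- shifted$data + 42
  out <- extract_frn(shifted, component_windows("control"))
  expect_equal(out$frn_difference, base$frn_difference, tolerance = 1e-9)
  expect_equal(out$frn_p2p_correct, base$frn_p2p_correct, tolerance = 1e-9)
})

test_that("group-specific component windows match the analysis definitions", {
  w_ctrl <- component_windows("control")
  w_pat <- component_windows("ADHD-C")
  expect_identical(w_ctrl$p1$window_ms, c(115, 140))
  expect_identical(w_pat$p1$window_ms, c(125, 150))
  expect_identical(w_ctrl$frn$peak1_ms, c(200, 210))
  expect_identical(w_pat$frn$peak1_ms, c(225, 235))
  expect_identical(component_windows("ADD")$frn$peak2_ms, c(300, 310))
  expect_identical(w_ctrl$cnv$windows_ms$w1, c(-825, -775))
  expect_identical(w_ctrl$cnv$electrode, "Cz")
  expect_identical(w_ctrl$frn$electrode, "FCz")
})

test_that("electrode validation selects a strongly injected site", {
  set.seed(11)
  n_sub <- 16; nch <- 60
  mon <- make_equidistant_montage(nch)
  target <- channel_index(mon, "Cz")
  amp <- matrix(stats::rnorm(n_sub * nch, sd = 1), n_sub, nch)
  amp[, target] <- amp[, target] - 10          # strong negative effect
  res <- validate_selection(amp, mon, "negative")
  expect_true(res$selected[target])
  expect_identical(sum(res$selected), 1L)

  # wrong expected polarity blocks selection
  res_pos <- validate_selection(amp, mon, "positive")
  expect_false(res_pos$selected[target])
})

test_that("electrode validation rarely selects under pure noise", {
  mon <- make_equidistant_montage(60)
  false_hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    amp <- matrix(stats::rnorm(16 * 60), 16, 60)
    false_hits <- false_hits +
      sum(validate_selection(amp, mon, "negative")$selected)
  }
  expect_lte(false_hits, 1)
})

test_that("validation needs at least two subjects", {
  mon <- make_equidistant_montage(16)
  expect_error(validate_selection(matrix(0, 1, 16), mon), "insufficient")
})

test_that("validation picks the analysis electrodes on synthetic data", {
  # cohort of identity-mode subjects; CNV window 4 should single out Cz
  cfg <- quick_cfg(n_trials = 50, n_channels = 60)
  amps <- t(vapply(1:8, function(i) {
    subj <- generate_subject(group_profile("control"), cfg, seed = 400 + i)
    an <- analyze_subject(subj$recording, "control", recovery_config(cfg),
                          destructive = TRUE)
    ep <- an$epochs$cnv
    sel <- which(ep$trial_meta$category == "correct")
    channel_window_means(ep, c(-50, 0), sel)
  }, numeric(60)))
  mon <- make_equidistant_montage(60)
  res <- validate_selection(amps, mon, "negative")
  expect_true(res$selected[channel_index(mon, "Cz")])
  expect_identical(res$electrode[which.min(res$mean_diff)], "Cz")
})

test_that("missing conditions yield NA with a warning, not an error", {
  arr <- array(stats::rnorm(4 * 300 * 2, sd = 5), dim = c(4, 300, 2))
  ep <- toy_epochs(arr, categories = c("correct", "correct"))
  ep <- apply_csd(ep, identity_spatial_mode())
  expect_warning(out <- extract_frn(ep, component_windows("control")),
                 "no kept")
  expect_true(is.na(out$frn_p2p_error))
  expect_true(is.na(out$frn_difference))
})
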