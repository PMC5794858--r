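test_that("event counts are conserved per subject", {
  cfg <- quick_cfg(n_trials = 60)
  subj <- generate_subject(group_profile("ADD"), cfg, seed = 11)
  ev <- subj$recording$events
  n_miss <- sum(subj$behavior$category == "miss")
  expect_identical(sum(ev$kind == "stimulus"), 60L)
  expect_identical(sum(ev$kind == "response"), 60L - n_miss)
  expect_identical(sum(ev$kind == "feedback"), 60L - n_miss)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- quick_cfg(n_trials = 20)
  a <- generate_subject(group_profile("control"), cfg, seed = 7)
  b <- generate_subject(group_profile("control"), cfg, seed = 7)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$behavior, b$behavior)
  c <- generate_subject(group_profile("control"), cfg, seed = 8)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("noise-free pipeline recovers the injected component amplitudes", {
  cfg <- noisefree_cfg()
  for (grp in c("control", "ADD", "ADHD-C")) {
    prof <- group_profile(grp)
    subj <- generate_subject(prof, cfg, seed = 3)
    an <- analyze_subject(subj$recording, grp, noisefree_pipeline(cfg))
    comp <- an$components
    cnv <- comp$value[grepl("^cnv", comp$component) &
                        comp$condition == "correct"]
    expect_equal(cnv, unname(prof$cnv_window_targets), tolerance = 0.015,
                 ignore_attr = TRUE)
    frn <- comp$value[comp$component == "frn_difference"]
    expect_equal(frn, prof$frn$difference, tolerance = 0.02)
    p2p_c <- comp$value[comp$component == "frn_p2p" &
                          comp$condition == "correct"]
    expect_equal(p2p_c, prof$frn$correct_p2p, tolerance = 0.1)
  }
})

test_that("cohort generation has the right shape and valid symptom scores", {
  cfg <- quick_cfg(n_trials = 10)
  cohort <- generate_cohort(cfg, eeg = FALSE)
  expect_identical(nrow(cohort$subjects), 48L)
  expect_identical(as.integer(table(cohort$subjects$group)), rep(16L, 3))
  sc <- cohort$subjects[, c("inattention", "hyperactivity", "impulsivity")]
  expect_true(all(sc >= 0 & sc <= 3))
  # per-subject seeds all distinct
  expect_false(any(duplicated(cohort$subjects$seed)))
})

test_that("symptom-performance coupling hits its target correlation", {
  cfg <- sim_config(n_subjects_per_group = 200, master_seed = 5)
  add <- generate_cohort(cfg, groups = "ADD", eeg = FALSE)$subjects
  r_add <- stats::cor(add$correct_count, add$inattention)
  expect_lt(abs(r_add - (-0.54)), 0.1)

  ctrl <- generate_cohort(cfg, groups = "control", eeg = FALSE)$subjects
  r_ctrl <- stats::cor(ctrl$correct_count, ctrl$inattention)
  expect_lt(abs(r_ctrl), 0.15)
})

test_that("injected artifacts trip the rejection stage at plausible rates", {
  cfg <- quick_cfg(n_trials = 80, n_channels = 30)
  subj <- generate_subject(group_profile("control"), cfg, seed = 21)
  an <- analyze_subject(subj$recording, "control", recovery_config(cfg))
  prop <- an$rejection$prop_rejected[an$rejection$scheme == "stimulus"]
  expect_gte(prop, 0)
  expect_lt(prop, 0.35)  # loose: small cohort, one subject
})
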