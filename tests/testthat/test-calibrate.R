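test_that("calibrated RT model reproduces the control category rates", {
  targets <- c(correct = 0.64, early = 0.17, late = 0.18, miss = 0.01)
  m <- calibrate_rt_model(targets)
  expect_lt(m$max_err, 0.005)
  # independent check by numeric quadrature of the fitted density
  mass <- function(a, b) {
    stats::integrate(function(x) rt_density(x, m), a, b,
                     rel.tol = 1e-9)$value
  }
  expect_equal(mass(1000, 1400), 0.64, tolerance = 0.006)
  expect_equal(mass(400, 1000), 0.17, tolerance = 0.006)
  expect_equal(mass(1400, 2000), 0.18, tolerance = 0.006)
})

test_that("calibration handles symmetric and degenerate targets", {
  # a perfectly symmetric, tail-free target is representable only up to the
  # family's tail mass (even the Gaussian limit leaves ~0.7% outside the
  # 400-2000 ms span), so a slightly relaxed tolerance is used here
  m <- calibrate_rt_model(c(correct = 0.5, early = 0.25, late = 0.25,
                            miss = 0), tol = 0.02)
  # equal mass on either side of the correct window
  expect_equal(m$achieved[["early"]], m$achieved[["late"]], tolerance = 0.01)

  # all-correct targets are representable only in the near-delta limit;
  # either outcome (tight fit or calibration failure) is acceptable, and a
  # returned model must place essentially all mass inside the window
  res <- tryCatch(calibrate_rt_model(c(1, 0, 0, 0)), error = identity)
  if (!inherits(res, "error")) {
    expect_gt(res$achieved[["correct"]], 0.995)
  } else {
    expect_match(conditionMessage(res), "calibration failure")
  }
})

test_that("calibration is deterministic and validates input", {
  t1 <- c(correct = 0.44, early = 0.30, late = 0.23, miss = 0.03)
  expect_identical(calibrate_rt_model(t1), calibrate_rt_model(t1))
  expect_error(calibrate_rt_model(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("category-conditional RT sampling lands in the right windows", {
  m <- calibrate_rt_model(c(correct = 0.49, early = 0.30, late = 0.18,
                            miss = 0.03))
  set.seed(42)
  cats <- sample(c("correct", "early", "late", "miss"), 500, replace = TRUE)
  rt <- timingerp:::sample_rt_given_category(cats, m)
  expect_true(all(is.na(rt[cats == "miss"])))
  expect_identical(classify_trial(rt[cats != "miss"]), cats[cats != "miss"])
})
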