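test_that("equidistant montage satisfies its geometric contract", {
  mon <- make_equidistant_montage(60)
  expect_length(mon$labels, 60)
  expect_false(any(duplicated(mon$labels)))
  expect_true(all(c("Cz", "FCz", "P7", "P8", "P9", "P10") %in% mon$labels))
  expect_lt(max(abs(sqrt(rowSums(mon$positions^2)) - 1)), 1e-9)

  # near-equidistance: nearest-neighbour spacing is tight
  d <- as.matrix(stats::dist(mon$positions))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(stats::sd(nn) / mean(nn), 0.2)
  expect_gt(min(nn) / max(nn), 0.6)

  # named sites sit where they should: Cz on top, FCz anterior midline,
  # parietal sites posterior-lateral
  pos <- mon$positions
  expect_gt(pos[channel_index(mon, "Cz"), 3], 0.95)
  fcz <- pos[channel_index(mon, "FCz"), ]
  expect_gt(fcz[2], 0.2)
  for (lbl in c("P7", "P9")) expect_lt(pos[channel_index(mon, lbl), 1], -0.4)
  for (lbl in c("P8", "P10")) expect_gt(pos[channel_index(mon, lbl), 1], 0.4)
  for (lbl in c("P7", "P8", "P9", "P10")) {
    expect_lt(pos[channel_index(mon, lbl), 2], -0.2)
  }
})

test_that("montage construction is deterministic and size-checked", {
  expect_identical(make_equidistant_montage(60), make_equidistant_montage(60))
  expect_error(make_equidistant_montage(8), "invalid montage")
  small <- make_equidistant_montage(16)
  expect_length(small$labels, 16)
})

test_that("montage serialization round-trips exactly", {
  mon <- make_equidistant_montage(24)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_montage(mon, path)
  back <- read_montage(path)
  expect_identical(back$labels, mon$labels)
  expect_equal(back$positions, mon$positions, tolerance = 1e-15)
})

test_that("ms_to_samples rounds half away from zero and inverts within one sample", {
  expect_identical(ms_to_samples(1000, 256), 256L)
  expect_identical(ms_to_samples(-200, 256), -51L)
  expect_identical(ms_to_samples(0, 500), 0L)
  expect_identical(ms_to_samples(3, 500), 2L)     # 1.5 -> away from zero
  expect_identical(ms_to_samples(-3, 500), -2L)
  # round trip: sample -> ms -> sample is the identity on the grid
  for (rate in c(256, 500)) {
    k <- -50:50
    expect_identical(ms_to_samples(k * 1000 / rate, rate), as.integer(k))
  }
})
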