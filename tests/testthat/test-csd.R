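test_that("CSD of a constant potential is numerically zero", {
  mon <- make_equidistant_montage(60)
  csd <- build_csd_matrix(mon)
  out <- csd$operator %*% rep(5, 60)
  expect_lt(max(abs(out)), 1e-6 * norm(csd$operator, "F"))
  # row sums vanish relative to the operator scale (reference invariance)
  expect_lt(max(abs(rowSums(csd$operator))), 1e-6 * norm(csd$operator, "F"))
})

test_that("CSD is linear and reference-invariant", {
  mon <- make_equidistant_montage(24)
  csd <- build_csd_matrix(mon)
  set.seed(1)
  x <- stats::rnorm(24); y <- stats::rnorm(24)
  a <- 2.3; b <- -0.7
  lhs <- csd$operator %*% (a * x + b * y)
  rhs <- a * csd$operator %*% x + b * csd$operator %*% y
  expect_lt(max(abs(lhs - rhs)), 1e-9 * max(abs(rhs)))

  shifted <- csd$operator %*% (x + 1000)
  expect_lt(max(abs(shifted - csd$operator %*% x)), 1e-6 * 1000)
})

test_that("a single-electrode impulse produces a centre-surround pattern", {
  mon <- make_equidistant_montage(60)
  csd <- build_csd_matrix(mon)
  cz <- channel_index(mon, "Cz")
  v <- rep(0, 60); v[cz] <- 1
  out <- as.numeric(csd$operator %*% v)
  expect_gt(out[cz], 0)
  expect_identical(which.max(out), cz)
  # the negative annulus sits at the spline smoothing scale, beyond the
  # immediate neighbours (which still sit on the positive centre lobe)
  d <- acos(pmin(1, mon$positions %*% mon$positions[cz, ]))
  annulus <- which(d > 0.5 & d < 1.0)
  expect_gt(length(annulus), 5)
  expect_lt(mean(out[annulus]), 0)
  expect_lt(min(out[annulus]), -0.1 * out[cz])
})

test_that("matrix solution matches an independent constrained least-squares fit", {
  mon <- make_equidistant_montage(16)
  par <- csd_params()
  csd <- build_csd_matrix(mon, par)
  set.seed(4)
  v <- stats::rnorm(16, sd = 10)

  # brute force: solve the full KKT system of the regularized spline fit
  G <- csd$G
  n <- nrow(G)
  kkt <- rbind(cbind(G + diag(par$lambda, n), rep(1, n)),
               c(rep(1, n), 0))
  sol <- solve(kkt, c(v, 0))
  c_bf <- sol[seq_len(n)]
  csd_bf <- as.numeric(csd$H %*% c_bf) / par$head_radius_m^2

  got <- as.numeric(csd$operator %*% v)
  expect_lt(max(abs(got - csd_bf)), 1e-6 * max(abs(csd_bf)))
})

test_that("operator output equals the numerical surface Laplacian of the spline", {
  mon <- make_equidistant_montage(16)
  par <- csd_params()
  csd <- build_csd_matrix(mon, par)
  set.seed(5)
  v <- stats::rnorm(16, sd = 10)
  got <- as.numeric(csd$operator %*% v)

  # Laplace-Beltrami via circle means with Richardson extrapolation:
  # lap V(x) ~ 4 (mean over geodesic circle of radius h - V(x)) / h^2
  circle_mean <- function(x0, h, k = 96) {
    e1 <- if (abs(x0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- e1 - sum(e1 * x0) * x0
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(x0[2] * e1[3] - x0[3] * e1[2],
            x0[3] * e1[1] - x0[1] * e1[3],
            x0[1] * e1[2] - x0[2] * e1[1])
    th <- 2 * pi * (seq_len(k) - 1) / k
    pts <- cos(h) * matrix(x0, k, 3, byrow = TRUE) +
      sin(h) * (outer(cos(th), e1) + outer(sin(th), e2))
    mean(csd_spline_potential(csd, mon, v, pts))
  }
  num_lap <- vapply(seq_len(16), function(i) {
    x0 <- mon$positions[i, ]
    v0 <- csd_spline_potential(csd, mon, v, matrix(x0, 1))
    L <- function(h) 4 * (circle_mean(x0, h) - v0) / h^2
    (4 * L(0.02) - L(0.04)) / 3
  }, numeric(1))
  expect_lt(max(abs(got - (-num_lap) / par$head_radius_m^2)),
            1e-3 * max(abs(got)))
})

test_that("CSD is equivariant under a symmetry rotation of the montage", {
  mon <- ring_montage()
  csd <- build_csd_matrix(mon)
  # rotating by 60 degrees permutes each 6-electrode ring cyclically
  perm <- c(2:6, 1, 8:12, 7)
  set.seed(6)
  v <- stats::rnorm(12)
  lhs <- (csd$operator %*% v)[perm]
  rhs <- csd$operator %*% v[perm]
  expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-9)
})

test_that("stronger regularization smooths: output power decreases in lambda", {
  mon <- make_equidistant_montage(32)
  set.seed(7)
  v <- stats::rnorm(32, sd = 10)
  pw <- vapply(c(1e-6, 1e-4, 1e-2), function(l) {
    op <- build_csd_matrix(mon, csd_params(lambda = l))$operator
    sum((op %*% v)^2)
  }, numeric(1))
  expect_true(all(diff(pw) < 0))
})

test_that("apply_csd transforms per sample and guards its contract", {
  mon <- make_equidistant_montage(16)
  csd <- build_csd_matrix(mon)
  arr <- array(stats::rnorm(16 * 50 * 3), dim = c(16, 50, 3))
  ep <- toy_epochs(arr, rate = 256)
  ep$montage <- mon
  out <- apply_csd(ep, csd)
  expect_identical(out$units, "uV/m^2")
  # definitional check against direct per-sample multiplication
  expect_equal(out$data[, 7, 2],
               as.numeric(csd$operator %*% arr[, 7, 2]), tolerance = 1e-12)
  expect_identical(out$trial_meta, ep$trial_meta)
  expect_error(apply_csd(out, csd), "microvolt")

  big <- toy_epochs(array(0, dim = c(20, 10, 1)))
  expect_error(apply_csd(big, csd), "mismatch")
})

test_that("identity spatial mode relabels without touching the data", {
  arr <- array(stats::rnorm(4 * 30 * 2), dim = c(4, 30, 2))
  ep <- toy_epochs(arr)
  out <- apply_csd(ep, identity_spatial_mode())
  expect_identical(out$data, ep$data)
  expect_identical(out$units, "uV/m^2")
  expect_identical(attr(out, "spatial_mode"), "identity")
})

test_that("degenerate montages are rejected", {
  mon <- make_equidistant_montage(16)
  mon$positions[2, ] <- mon$positions[1, ]
  expect_error(build_csd_matrix(mon), "singular geometry")
})

test_that("CSD matrix export writes a labelled plain-text table", {
  mon <- make_equidistant_montage(16)
  csd <- build_csd_matrix(mon)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_csd_matrix(csd, path)
  back <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                      check.names = FALSE))
  expect_equal(unname(back), unname(csd$operator), tolerance = 1e-12)
})
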