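#' Spherical-spline CSD parameters
#'
#' Parameters of the spherical-spline surface Laplacian used to convert
#' scalp potentials (uV) into reference-free current source density
#' (uV/m^2): spline stiffness order m, Tikhonov regularization lambda, the
#' number of Legendre terms in the series, and the head radius used for the
#' physical scaling (output is divided by radius^2 so results are per m^2).
#' The defaults (m = 4, lambda = 1e-5, 50 terms, radius 8.75 cm) are the
#' conventional choices of the spherical-spline CSD literature; recovered
#' amplitudes rather than absolute physical units are what the downstream
#' analysis compares, so the scaling convention is surfaced here explicitly.
#'
#' @param m Spline order (>= 2, default 4).
#' @param lambda Regularization (>= 0, default 1e-5).
#' @param legendre_terms Series terms (>= 20, default 50).
#' @param head_radius_m Head radius in meters (default 0.0875).
#' @return A `csd_params` list.
#' @export
csd_params <- function(m = 4, lambda = 1e-5, legendre_terms = 50,
                       head_radius_m = 0.0875) {
  stopifnot(m >= 2, lambda >= 0, legendre_terms >= 20, head_radius_m > 0)
  structure(list(m = m, lambda = lambda, legendre_terms = legendre_terms,
                 head_radius_m = head_radius_m),
            class = "csd_params")
}

# Legendre polynomials P_1..P_n evaluated at x (vector); rows = order.
legendre_table <- function(x, n) {
  out <- matrix(0, n, length(x))
  pkm1 <- rep(1, length(x))  # P_0
  pk <- x                    # P_1
  out[1, ] <- pk
  for (k in 2:n) {
    pkp <- ((2 * k - 1) * x * pk - (k - 1) * pkm1) / k
    out[k, ] <- pkp
    pkm1 <- pk
    pk <- pkp
  }
  out
}

# g and h kernels of the spherical spline: g interpolates the potential,
# h carries the (negated) surface Laplacian of g on the unit sphere.
csd_kernels <- function(x, m, nterms) {
  k <- seq_len(nterms)
  P <- legendre_table(pmin(pmax(x, -1), 1), nterms)
  wg <- (2 * k + 1) / (k * (k + 1))^m
  wh <- (2 * k + 1) / (k * (k + 1))^(m - 1)
  list(g = as.numeric(wg %*% P) / (4 * pi),
       h = as.numeric(wh %*% P) / (4 * pi))
}

#' Build the spherical-spline CSD transform for a montage
#'
#' Assembles the spline interpolation matrix G and its surface-Laplacian
#' counterpart H from a Legendre series over inter-electrode angles, and
#' returns the linear operator mapping a vector of scalp potentials to
#' current source density at the electrodes. The spline model is
#' V(x) = c0 + sum_j c_j g(cos gamma(x, x_j)) with sum_j c_j = 0, fitted
#' with ridge regularization (G + lambda I); the CSD is the negated surface
#' Laplacian of the fitted spline, scaled by 1/radius^2 to yield uV/m^2.
#' Because the Laplacian annihilates the constant c0, rows of the operator
#' sum to (numerically) zero: the transform is insensitive to the reference.
#'
#' @param montage An `erp_montage` (unit-norm positions, no duplicates).
#' @param params A [csd_params()] list.
#' @return An `erp_csd` list: `operator` (channels x channels), `G`, `H`,
#'   `labels`, `params`.
#' @export
build_csd_matrix <- function(montage, params = csd_params()) {
  pos <- montage$positions
  nrm <- sqrt(rowSums(pos^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("montage positions must be unit-norm", call. = FALSE)
  cosang <- pos %*% t(pos)
  if (any(cosang[upper.tri(cosang)] > 1 - 1e-10)) {
    stop("singular geometry: duplicate electrode positions", call. = FALSE)
  }
  nch <- nrow(pos)
  kern <- csd_kernels(as.numeric(cosang), params$m, params$legendre_terms)
  G <- matrix(kern$g, nch, nch)
  H <- matrix(kern$h, nch, nch)
  Greg <- G + diag(params$lambda, nch)
  Gi <- solve(Greg)
  ones <- rep(1, nch)
  denom <- as.numeric(t(ones) %*% Gi %*% ones)
  # coefficient map S: v -> c with the zero-sum constraint folded in
  S <- Gi - (Gi %*% ones %*% t(ones) %*% Gi) / denom
  operator <- (H %*% S) / params$head_radius_m^2
  structure(list(operator = operator, G = G, H = H, S = S,
                 labels = montage$labels, params = params),
            class = "erp_csd")
}

#' @export
print.erp_csd <- function(x, ...) {
  cat(sprintf("<erp_csd> %d channels, m = %d, lambda = %g\n",
              length(x$labels), x$params$m, x$params$lambda))
  invisible(x)
}

#' Identity spatial mode
#'
#' A pass-through spatial transform used for parameter recovery: epochs are
#' numerically unchanged and only relabelled to the nominal uV/m^2
#' measurement scale in which the generator's amplitude targets are defined.
#' The mode is recorded in the `spatial_mode` attribute so provenance logs
#' can distinguish it from a real CSD run.
#'
#' @return An object of class `erp_identity_spatial`.
#' @export
identity_spatial_mode <- function() {
  structure(list(), class = "erp_identity_spatial")
}

#' Apply a spatial transform (CSD or identity) to epochs
#'
#' For an `erp_csd` transform the operator is applied to every time sample
#' of every trial (a plain matrix product per sample); metadata is
#' preserved and units become uV/m^2. The identity mode relabels only.
#'
#' @param epochs An `erp_epochs` in microvolts.
#' @param transform An `erp_csd` or [identity_spatial_mode()].
#' @return Transformed `erp_epochs` (units uV/m^2).
#' @export
apply_csd <- function(epochs, transform) {
  if (inherits(transform, "erp_identity_spatial")) {
    epochs$units <- "uV/m^2"
    attr(epochs, "spatial_mode") <- "identity"
    return(epochs)
  }
  stopifnot(inherits(transform, "erp_csd"))
  if (epochs$units != "uV") {
    stop("CSD must be applied to microvolt epochs", call. = FALSE)
  }
  d <- dim(epochs$data)
  if (d[1] != nrow(transform$operator)) {
    stop("channel count mismatch between epochs and CSD operator", call. = FALSE)
  }
  flat <- matrix(epochs$data, nrow = d[1])
  epochs$data <- array(transform$operator %*% flat, dim = d)
  epochs$units <- "uV/m^2"
  attr(epochs, "spatial_mode") <- "csd"
  epochs
}

#' Export a CSD operator as a plain-text table
#' @param csd An `erp_csd`.
#' @param path Output path (tab-separated, labelled rows/columns).
#' @return `path`, invisibly.
#' @export
write_csd_matrix <- function(csd, path) {
  m <- csd$operator
  dimnames(m) <- list(csd$labels, csd$labels)
  utils::write.table(format(as.data.frame(m), digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Evaluate the fitted spline potential at arbitrary scalp points
#'
#' Interpolates a potential vector through the spherical spline underlying
#' a CSD transform and evaluates it at unit-sphere points. Exposed because
#' independent verification of the Laplacian (e.g. by numerical
#' differentiation on the sphere) needs the raw interpolant.
#'
#' @param csd An `erp_csd`.
#' @param montage The montage the transform was built from.
#' @param v Potential vector (one value per channel).
#' @param points Matrix of unit-norm 3D points (rows).
#' @return Interpolated potentials at `points`.
#' @export
csd_spline_potential <- function(csd, montage, v, points) {
  coef <- as.numeric(csd$S %*% v)
  c0 <- mean(v - as.numeric(csd$G %*% coef))
  x <- points %*% t(montage$positions)
  kern <- csd_kernels(as.numeric(x), csd$params$m, csd$params$legendre_terms)
  gmat <- matrix(kern$g, nrow(points), nrow(montage$positions))
  c0 + as.numeric(gmat %*% coef)
}
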