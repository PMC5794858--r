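#' Deterministic equidistant scalp montage on the unit sphere
#'
#' Builds an approximately equidistant electrode layout by placing points on a
#' Fibonacci (golden-angle) spiral restricted to the upper portion of the unit
#' sphere (z > -0.2, i.e. the scalp), then relabelling the sites closest to
#' the canonical 10-20 directions of the six electrodes the analysis depends
#' on (Cz at the vertex, FCz anterior-midline, P7/P8/P9/P10
#' posterior-lateral). The construction is fully deterministic: calling it
#' twice with the same `n_channels` yields bit-identical coordinates.
#'
#' The coordinate frame is right-handed with x pointing right, y anterior and
#' z up; the head radius is treated as 1 (physical scaling happens in the CSD
#' stage). The layout is a stand-in: the recording system this emulates uses
#' an equidistant cap whose coordinate table is not published, so only the
#' qualitative geometry (equidistance, named landmark sites) is reproduced.
#'
#' @param n_channels Number of scalp electrodes (>= 16; default 60).
#' @param reference_label Name of the (non-scalp) reference site, kept as
#'   metadata only.
#' @return An object of class `erp_montage`: a list with `labels` (character),
#'   `positions` (`n_channels` x 3 matrix of unit vectors) and
#'   `reference_label`.
#' @examples
#' mon <- make_equidistant_montage(60)
#' head(mon$labels)
#' @export
make_equidistant_montage <- function(n_channels = 60, reference_label = "Fpz") {
  if (!is.numeric(n_channels) || length(n_channels) != 1 || n_channels < 16) {
    stop("invalid montage: n_channels must be a single integer >= 16",
         call. = FALSE)
  }
  n <- as.integer(n_channels)
  # golden-angle spiral on the spherical cap z in (-0.2, 1]
  i <- seq_len(n)
  z <- 1 - (i - 0.5) / n * 1.2
  golden <- pi * (3 - sqrt(5))
  az <- golden * (i - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(az), y = r * sin(az), z = z)
  pos <- pos / sqrt(rowSums(pos^2))

  labels <- sprintf("E%02d", i)
  named <- named_site_directions()
  taken <- rep(FALSE, n)
  for (nm in rownames(named)) {
    d <- pos %*% named[nm, ]
    d[taken] <- -Inf
    k <- which.max(d)
    labels[k] <- nm
    taken[k] <- TRUE
  }
  structure(
    list(labels = labels, positions = pos, reference_label = reference_label),
    class = "erp_montage"
  )
}

# Unit directions of the named sites (10-20 geometry, x right / y anterior).
named_site_directions <- function() {
  sph <- function(incl_deg, az_deg) {
    incl <- incl_deg * pi / 180
    az <- az_deg * pi / 180
    c(sin(incl) * cos(az), sin(incl) * sin(az), cos(incl))
  }
  out <- rbind(
    Cz  = sph(0, 0),
    FCz = sph(23, 90),
    P7  = sph(72, 216),
    P8  = sph(72, 324),
    P9  = sph(95, 216),
    P10 = sph(95, 324)
  )
  out / sqrt(rowSums(out^2))
}

#' @export
print.erp_montage <- function(x, ...) {
  cat(sprintf("<erp_montage> %d channels, reference %s\n",
              length(x$labels), x$reference_label))
  invisible(x)
}

#' Number of channels of a montage
#' @param montage An `erp_montage`.
#' @return Integer channel count.
#' @export
n_channels <- function(montage) length(montage$labels)

#' Index of named channels in a montage
#' @param montage An `erp_montage`.
#' @param labels Character vector of channel names.
#' @return Integer positions; errors if any label is absent.
#' @export
channel_index <- function(montage, labels) {
  idx <- match(labels, montage$labels)
  if (anyNA(idx)) {
    stop("channel(s) not in montage: ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Serialize a montage to a plain-text table
#'
#' Writes one row per channel: label, x, y, z (tab-separated, full double
#' precision so a round trip is exact).
#' @param montage An `erp_montage`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(label = montage$labels,
                   x = montage$positions[, 1],
                   y = montage$positions[, 2],
                   z = montage$positions[, 3])
  utils::write.table(format(df, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a montage written by [write_montage()]
#' @param path File path.
#' @param reference_label Reference-site name to attach.
#' @return An `erp_montage`.
#' @export
read_montage <- function(path, reference_label = "Fpz") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  colnames(pos) <- c("x", "y", "z")
  structure(list(labels = df$label, positions = pos,
                 reference_label = reference_label),
            class = "erp_montage")
}

#' Convert a latency in milliseconds to a sample offset
#'
#' Uses round-half-away-from-zero so that positive and negative latencies are
#' treated symmetrically around the lock event.
#'
#' @param t_ms Latency (ms), vectorized.
#' @param rate Sampling rate (Hz), > 0.
#' @return Integer sample offsets.
#' @examples
#' ms_to_samples(1000, 256)  # 256
#' ms_to_samples(-200, 256)  # -51
#' @export
ms_to_samples <- function(t_ms, rate) {
  stopifnot(is.numeric(rate), length(rate) == 1, rate > 0)
  x <- t_ms * rate / 1000
  as.integer(sign(x) * floor(abs(x) + 0.5))
}
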