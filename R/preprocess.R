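#' Butterworth second-order sections
#'
#' Designs an order-`n` Butterworth low- or high-pass as a cascade of
#' biquads (second-order sections). Biquads are used instead of a single
#' transfer function because high-order IIR filters with cutoffs far below
#' Nyquist (0.5 Hz at 500 Hz) are numerically unstable in direct form.
#'
#' @param n Filter order (poles).
#' @param wc_hz Cutoff frequency, Hz.
#' @param rate Sampling rate, Hz.
#' @param type "low" or "high".
#' @return Matrix with one row per section, columns b0 b1 b2 a0 a1 a2.
#' @keywords internal
butter_sos <- function(n, wc_hz, rate, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(wc_hz > 0, wc_hz < rate / 2)
  k <- seq_len(n)
  pa <- complex(modulus = 1, argument = pi * (2 * k - 1) / (2 * n) + pi / 2)
  warped <- 2 * rate * tan(pi * wc_hz / rate)
  pa <- if (type == "low") warped * pa else warped / pa
  sos <- NULL
  used <- rep(FALSE, n)
  for (j in seq_len(n)) {
    if (used[j]) next
    conj_j <- which(!used & seq_len(n) != j &
                      abs(Conj(pa[j]) - pa) < 1e-8 * Mod(pa[j]))
    if (abs(Im(pa[j])) < 1e-12 * Mod(pa[j]) || length(conj_j) == 0) {
      z <- (2 * rate + pa[j]) / (2 * rate - pa[j])
      b <- if (type == "low") c(1, 1, 0) else c(1, -1, 0)
      a <- c(1, -Re(z), 0)
      used[j] <- TRUE
    } else {
      z1 <- (2 * rate + pa[j]) / (2 * rate - pa[j])
      a <- c(1, -2 * Re(z1), Mod(z1)^2)
      b <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
      used[c(j, conj_j[1])] <- TRUE
    }
    w0 <- if (type == "low") 1 + 0i else -1 + 0i
    g <- abs(sum(b * c(1, w0, w0^2)) / sum(a * c(1, w0, w0^2)))
    sos <- rbind(sos, c(b / g, a))
  }
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

# Zero-phase application of an SOS cascade to a channels x samples matrix.
sos_filter_channels <- function(data, sos, pad) {
  iir_filtfilt_rows(data, sos, as.integer(pad))
}

#' Zero-phase band-pass filter of a continuous recording
#'
#' Applies an order-8 (by default) Butterworth high-pass and low-pass
#' cascade forward and backward (zero phase). An order-8 design has a 48
#' dB/oct asymptotic slope per edge; the forward-backward application
#' doubles the attenuation but leaves the -6 dB points at the requested
#' cutoffs. Event markers are unchanged.
#'
#' @param rec An `erp_recording`.
#' @param low,high Band edges, Hz (0 < low < high < rate/2).
#' @param slope_db_per_oct Asymptotic slope of the one-pass design; the
#'   filter order is `ceiling(slope / 6)` (default 48 -> order 8).
#' @return The filtered `erp_recording`.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 20, slope_db_per_oct = 48) {
  if (!(low > 0 && low < high)) stop("invalid band: need 0 < low < high", call. = FALSE)
  if (high >= rec$rate / 2) {
    stop("invalid band: high edge at or above Nyquist", call. = FALSE)
  }
  ord <- ceiling(slope_db_per_oct / 6)
  sos <- rbind(butter_sos(ord, low, rec$rate, "high"),
               butter_sos(ord, high, rec$rate, "low"))
  pad <- min(ncol(rec$data) - 1, ceiling(3 * rec$rate / low))
  rec$data <- sos_filter_channels(rec$data, sos, pad)
  rec
}

#' Anti-aliased resampling of a continuous recording
#'
#' Low-passes at 0.45 of the target rate (order-4 Butterworth, zero phase,
#' so 48 dB/oct of magnitude roll-off after the forward-backward pass) and
#' linearly interpolates onto the target grid; with EEG content far below
#' the new Nyquist frequency both the pass-band error and the aliased
#' residual are negligible. Event onsets are remapped to the nearest new
#' sample; the duration is preserved within one sample. Only downsampling
#' is supported.
#'
#' @param rec An `erp_recording`.
#' @param target_rate New rate, Hz (<= current rate).
#' @param destructive Allow the filter to work in the input's own memory
#'   (the input recording is invalidated). Only safe when the caller owns
#'   the recording and discards it afterwards, as the cohort pipeline
#'   does; the default keeps the input intact.
#' @return The resampled `erp_recording`.
#' @export
resample_recording <- function(rec, target_rate = 256, destructive = FALSE) {
  if (target_rate > rec$rate) {
    stop("upsampling not supported (target rate above recording rate)",
         call. = FALSE)
  }
  if (target_rate == rec$rate) return(rec)
  n <- ncol(rec$data)
  sos <- butter_sos(4, 0.45 * target_rate, rec$rate, "low")
  n_new <- floor((n - 1) * target_rate / rec$rate) + 1
  newdata <- if (destructive) {
    resample_rows_destructive(rec$data, sos, 300L, rec$rate / target_rate,
                              as.integer(n_new))
  } else {
    resample_rows(rec$data, sos, 300L, rec$rate / target_rate,
                  as.integer(n_new))
  }
  ev <- rec$events
  ev$onset_sample <- as.integer(pmin(n_new, pmax(
    1, round((ev$onset_sample - 1) * target_rate / rec$rate) + 1)))
  new_recording(newdata, target_rate, ev, rec$montage)
}

#' Automated artifact rejection criteria
#'
#' The three criteria of the automated rejection stage: an absolute
#' amplitude bound of +-200 uV, a maximal value difference of 200 uV within
#' any sliding 200 ms window, and a low-activity bound flagging epochs in
#' which any channel stays within a 0.5 uV range for 100 ms (dead channel).
#'
#' @param abs_amplitude_uV Absolute amplitude bound (default 200).
#' @param max_diff_uV Maximal difference bound (default 200).
#' @param max_diff_window_ms Window for the difference criterion (200 ms).
#' @param low_activity_uV Low-activity bound (default 0.5); 0 disables the
#'   criterion, which matters for strictly noise-free synthetic data where
#'   silent channels are by construction, not dead electrodes.
#' @param low_activity_window_ms Window for low activity (100 ms).
#' @return A `rejection_criteria` list.
#' @export
rejection_criteria <- function(abs_amplitude_uV = 200,
                               max_diff_uV = 200,
                               max_diff_window_ms = 200,
                               low_activity_uV = 0.5,
                               low_activity_window_ms = 100) {
  stopifnot(abs_amplitude_uV > 0, max_diff_uV > 0, max_diff_window_ms > 0,
            low_activity_uV >= 0, low_activity_window_ms > 0)
  structure(list(abs_amplitude_uV = abs_amplitude_uV,
                 max_diff_uV = max_diff_uV,
                 max_diff_window_ms = max_diff_window_ms,
                 low_activity_uV = low_activity_uV,
                 low_activity_window_ms = low_activity_window_ms),
            class = "rejection_criteria")
}

#' Reject artifact-contaminated epochs
#'
#' Marks a trial as rejected if ANY channel violates ANY of the three
#' criteria (one bad channel rejects the whole trial; no interpolation is
#' attempted). Sliding windows advance one sample at a time; window lengths
#' in samples are `round(window_ms * rate / 1000)`. Must be applied at the
#' microvolt stage, before any CSD transform.
#'
#' @param epochs An `erp_epochs` with units "uV".
#' @param criteria A [rejection_criteria()] list.
#' @return The epochs with updated `kept` flags and a `rejection_log`
#'   attribute: a tibble (trial_index, kept, criterion, channel) where
#'   `criterion` is the first violated rule ("amplitude", "max_diff",
#'   "low_activity" or NA).
#' @export
reject_artifact_epochs <- function(epochs, criteria = rejection_criteria()) {
  if (epochs$units != "uV") {
    stop("wrong stage: artifact rejection must run on microvolt epochs ",
         "(got ", epochs$units, ")", call. = FALSE)
  }
  w_diff <- max(2L, ms_to_samples(criteria$max_diff_window_ms, epochs$rate))
  w_low <- max(2L, ms_to_samples(criteria$low_activity_window_ms, epochs$rate))
  res <- scan_artifacts(epochs$data, dim(epochs$data),
                        criteria$abs_amplitude_uV, criteria$max_diff_uV,
                        w_diff, criteria$low_activity_uV, w_low)
  crit <- c(NA, "amplitude", "max_diff", "low_activity")[res[, 1] + 1]
  clean <- res[, 1] == 0
  epochs$trial_meta$kept <- epochs$trial_meta$kept & clean
  log <- tibble::tibble(
    trial_index = epochs$trial_meta$trial_index,
    kept = epochs$trial_meta$kept,
    criterion = crit,
    channel = ifelse(res[, 2] > 0, epochs$montage$labels[pmax(res[, 2], 1)],
                     NA_character_)
  )
  attr(epochs, "rejection_log") <- log
  epochs
}

#' Rejection summary of an epochs object
#' @param epochs Epochs processed by [reject_artifact_epochs()].
#' @return Tibble with n_trials, n_rejected, prop_rejected.
#' @export
rejection_summary <- function(epochs) {
  log <- attr(epochs, "rejection_log")
  if (is.null(log)) stop("no rejection log: run reject_artifact_epochs first",
                         call. = FALSE)
  tibble::tibble(n_trials = nrow(log),
                 n_rejected = sum(!log$kept),
                 prop_rejected = mean(!log$kept))
}
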