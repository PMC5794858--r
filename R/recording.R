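#' Continuous multichannel EEG recording
#'
#' Thin container coupling a channels x samples signal matrix (microvolts)
#' with its sampling rate, event table and montage. Events live on the sample
#' grid of the recording and are remapped whenever the recording is
#' resampled.
#'
#' @param data Numeric matrix, channels x samples, all finite, in microvolts.
#' @param rate Sampling rate in Hz (> 0).
#' @param events Tibble/data frame with columns `onset_sample` (1-based
#'   integer sample index), `kind` (one of "stimulus", "response",
#'   "feedback") and `trial_index` (integer >= 1).
#' @param montage An `erp_montage` whose size matches `nrow(data)`.
#' @return An object of class `erp_recording`.
#' @export
new_recording <- function(data, rate, events, montage) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.finite(sum(data))) {
    stop("recording contains non-finite values", call. = FALSE)
  }
  stopifnot(is.numeric(rate), length(rate) == 1, rate > 0)
  if (nrow(data) != n_channels(montage)) {
    stop("channel count (", nrow(data), ") does not match montage (",
         n_channels(montage), ")", call. = FALSE)
  }
  events <- tibble::as_tibble(events)
  req <- c("onset_sample", "kind", "trial_index")
  if (!all(req %in% names(events))) {
    stop("events must have columns onset_sample, kind, trial_index", call. = FALSE)
  }
  if (nrow(events) > 0) {
    if (!all(events$kind %in% c("stimulus", "response", "feedback"))) {
      stop("unknown event kind", call. = FALSE)
    }
    if (any(events$onset_sample < 1 | events$onset_sample > ncol(data))) {
      stop("event onset outside recording", call. = FALSE)
    }
    if (any(events$trial_index < 1)) stop("trial_index must be >= 1", call. = FALSE)
  }
  structure(list(data = data, rate = rate, events = events, montage = montage),
            class = "erp_recording")
}

#' @export
print.erp_recording <- function(x, ...) {
  cat(sprintf("<erp_recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$rate, nrow(x$events)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `erp_recording`.
#' @return Seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$rate

#' Epoched EEG data
#'
#' Container for trials x channels x samples data, stored internally as a
#' channels x samples x trials array (`data[ch, sample, trial]`) for fast
#' trial averaging. The time axis `times_ms` is uniform with step 1000/rate
#' and `times_ms == 0` is the lock-event sample of every trial.
#'
#' @param data Numeric array channels x samples x trials.
#' @param times_ms Per-sample latency (ms) relative to the lock event.
#' @param rate Sampling rate (Hz).
#' @param lock One of "stimulus", "response".
#' @param baseline_applied Logical: has a baseline been subtracted?
#' @param trial_meta Tibble with one row per trial; must contain `trial_index`,
#'   `rt_ms`, `category`, `kept`; feedback-locked epochs also carry
#'   `condition` ("correct"/"error").
#' @param units One of "uV", "uV/m^2", "a.u.".
#' @param montage The montage the channels refer to.
#' @return An object of class `erp_epochs`.
#' @export
new_epochs <- function(data, times_ms, rate, lock, baseline_applied,
                       trial_meta, units, montage) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  stopifnot(dim(data)[2] == length(times_ms))
  if (length(times_ms) > 1) {
    steps <- diff(times_ms)
    stopifnot(all(steps > 0), max(abs(steps - 1000 / rate)) < 1e-6)
  }
  lock <- match.arg(lock, c("stimulus", "response"))
  units <- match.arg(units, c("uV", "uV/m^2", "a.u."))
  trial_meta <- tibble::as_tibble(trial_meta)
  stopifnot(nrow(trial_meta) == dim(data)[3])
  structure(list(data = data, times_ms = times_ms, rate = rate, lock = lock,
                 baseline_applied = baseline_applied, trial_meta = trial_meta,
                 units = units, montage = montage),
            class = "erp_epochs")
}

#' @export
print.erp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<erp_epochs> %d trials x %d ch x %d samples, %s-locked [%g, %g] ms, %s%s\n",
    d[3], d[1], d[2], x$lock, min(x$times_ms), max(x$times_ms), x$units,
    if (x$baseline_applied) ", baselined" else ""))
  invisible(x)
}

#' Number of trials in an epochs object
#' @param epochs An `erp_epochs`.
#' @return Integer.
#' @export
n_trials <- function(epochs) dim(epochs$data)[3]

#' Subset epochs by trial
#' @param epochs An `erp_epochs`.
#' @param idx Logical or integer trial selector.
#' @return An `erp_epochs` with the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  epochs$trial_meta <- epochs$trial_meta[idx, , drop = FALSE]
  epochs
}

# Sample indices (into times_ms) of the closed window [a, b] ms.
window_sample_idx <- function(epochs, window_ms) {
  i0 <- which.min(abs(epochs$times_ms))  # lock sample
  a <- ms_to_samples(window_ms[1], epochs$rate)
  b <- ms_to_samples(window_ms[2], epochs$rate)
  idx <- (i0 + a):(i0 + b)
  if (min(idx) < 1 || max(idx) > length(epochs$times_ms)) {
    stop("window [", window_ms[1], ", ", window_ms[2],
         "] ms exceeds epoch extent", call. = FALSE)
  }
  idx
}

#' Trial-average ERP waveform
#'
#' Averages the kept trials (optionally restricted to a condition or
#' category set) into a channels x samples matrix.
#'
#' @param epochs An `erp_epochs`.
#' @param trials Optional logical/integer trial selector applied on top of
#'   the `kept` flag.
#' @param channels Optional channel labels (or indices) restricting the
#'   output; all channels by default.
#' @return Matrix channels x samples; errors if no trial survives.
#' @export
erp_average <- function(epochs, trials = NULL, channels = NULL) {
  sel <- epochs$trial_meta$kept
  if (!is.null(trials)) {
    pick <- rep(FALSE, n_trials(epochs))
    pick[trials] <- TRUE
    sel <- sel & pick
  }
  if (!any(sel)) stop("no kept trials to average", call. = FALSE)
  ch <- if (is.null(channels)) {
    seq_len(dim(epochs$data)[1])
  } else if (is.character(channels)) {
    channel_index(epochs$montage, channels)
  } else {
    as.integer(channels)
  }
  average_trials(epochs$data, dim(epochs$data), which(sel), ch)
}
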