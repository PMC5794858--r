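#' Response classification boundaries of the time-production task
#'
#' Responses are classified by their latency after the visual cue: early in
#' \[400, 1000) ms, correct in \[1000, 1400\] ms, late in (1400, 2000\] ms,
#' and miss otherwise (before 400 ms, after 2000 ms, or no response within
#' the 3000 ms response deadline). The published windows share their
#' endpoints; the half-open convention adopted here (1000 ms counts as
#' correct, 1400 ms counts as correct) makes the mapping a partition so every
#' latency belongs to exactly one category.
#'
#' @return A list with `early`, `correct`, `late` (2-vectors, ms) and
#'   `response_deadline_ms`.
#' @export
classification_boundaries <- function() {
  list(early = c(400, 1000), correct = c(1000, 1400), late = c(1400, 2000),
       response_deadline_ms = 3000)
}

#' Classify response latencies into trial categories
#'
#' @param rt_ms Numeric vector of response latencies (ms); `NA` means no
#'   response was given.
#' @param boundaries A [classification_boundaries()] list.
#' @return Character vector: "correct", "early", "late" or "miss".
#' @examples
#' classify_trial(c(1200, 399, 1000, 1400, NA))
#' @export
classify_trial <- function(rt_ms, boundaries = classification_boundaries()) {
  if (any(rt_ms < 0, na.rm = TRUE)) stop("invalid rt: negative latency", call. = FALSE)
  out <- rep("miss", length(rt_ms))
  out[!is.na(rt_ms) & rt_ms >= boundaries$early[1] & rt_ms < boundaries$correct[1]] <- "early"
  out[!is.na(rt_ms) & rt_ms >= boundaries$correct[1] & rt_ms <= boundaries$correct[2]] <- "correct"
  out[!is.na(rt_ms) & rt_ms > boundaries$late[1] & rt_ms <= boundaries$late[2]] <- "late"
  out
}

#' Segmentation schemes used by the analysis
#'
#' Three schemes are used downstream: stimulus-locked segments from 2000 ms
#' before to 3000 ms after the cue with a \[-200, 0\] ms pre-stimulus
#' baseline; response-relocked segments of \[-2000, 1000\] ms that keep the
#' pre-stimulus baseline (see [relock_to_response()]); and feedback segments
#' of \[-200, 1500\] ms around the response, baselined to the \[-200, 0\] ms
#' pre-response interval.
#'
#' @param which One of "stimulus", "cnv", "feedback".
#' @return List with `lock`, `window_ms`, `baseline_ms` (NULL means inherit).
#' @export
segmentation_scheme <- function(which = c("stimulus", "cnv", "feedback")) {
  which <- match.arg(which)
  switch(which,
    stimulus = list(lock = "stimulus", window_ms = c(-2000, 3000),
                    baseline_ms = c(-200, 0)),
    cnv = list(lock = "response", window_ms = c(-2000, 1000),
               baseline_ms = NULL),
    feedback = list(lock = "response", window_ms = c(-200, 1500),
                    baseline_ms = c(-200, 0))
  )
}

# Build the per-trial table for a recording: stimulus sample, response
# sample (NA for miss), RT on the sample grid, category.
trial_table_from_events <- function(rec) {
  ev <- rec$events
  stim <- ev[ev$kind == "stimulus", ]
  resp <- ev[ev$kind == "response", ]
  resp_at <- resp$onset_sample[match(stim$trial_index, resp$trial_index)]
  rt_ms <- (resp_at - stim$onset_sample) / rec$rate * 1000
  tibble::tibble(
    trial_index = stim$trial_index,
    stim_sample = stim$onset_sample,
    resp_sample = resp_at,
    rt_ms = rt_ms,
    category = classify_trial(rt_ms)
  )
}

# Gather fixed-length windows around lock samples into a ch x samples x
# trials array, subtracting the per-channel baseline mean when a baseline
# window (in ms relative to the lock) is given. Lock samples must be such
# that all windows are in bounds.
gather_epoch_array <- function(data, lock_samples, a, b, rate,
                               baseline_ms = NULL) {
  if (is.null(baseline_ms)) {
    bl_a <- 1L; bl_b <- 0L  # disables baselining in the kernel
  } else {
    bl_a <- ms_to_samples(baseline_ms[1], rate)
    bl_b <- ms_to_samples(baseline_ms[2], rate)
  }
  gather_baseline(data, as.integer(lock_samples), as.integer(a),
                  as.integer(b), bl_a, bl_b)
}

#' Stimulus-locked segmentation with pre-stimulus baseline
#'
#' Cuts one epoch per stimulus event that fits fully inside the recording
#' (epochs that would exceed the recording bounds are dropped with a
#' warning), then subtracts the mean of the \[-200, 0\] ms pre-stimulus
#' interval per channel and trial. Trial metadata carries the response
#' latency measured on the current sample grid and its category.
#'
#' @param rec A filtered/resampled `erp_recording` (microvolts).
#' @param scheme A [segmentation_scheme()] ("stimulus" by default).
#' @return An `erp_epochs`, stimulus-locked, baselined.
#' @export
segment_stimulus <- function(rec, scheme = segmentation_scheme("stimulus")) {
  tt <- trial_table_from_events(rec)
  a <- ms_to_samples(scheme$window_ms[1], rec$rate)
  b <- ms_to_samples(scheme$window_ms[2], rec$rate)
  ok <- tt$stim_sample + a >= 1 & tt$stim_sample + b <= ncol(rec$data)
  if (any(!ok)) {
    warning(sum(!ok), " stimulus epoch(s) exceeded recording bounds and were dropped")
    tt <- tt[ok, ]
  }
  arr <- gather_epoch_array(rec$data, tt$stim_sample, a, b, rec$rate,
                            scheme$baseline_ms)
  times <- (a:b) * 1000 / rec$rate
  meta <- tibble::tibble(trial_index = tt$trial_index, rt_ms = tt$rt_ms,
                         rt_samples = tt$resp_sample - tt$stim_sample,
                         category = tt$category, kept = TRUE)
  new_epochs(arr, times, rec$rate, "stimulus", TRUE, meta, "uV", rec$montage)
}

#' Re-lock stimulus epochs to the response (CNV segmentation)
#'
#' Re-windows each baselined stimulus epoch to \[-2000, 1000\] ms around that
#' trial's response sample, keeping the fixed pre-stimulus baseline (no
#' re-baselining), so that pre-response preparatory activity can be averaged
#' across trials with different response latencies. Miss trials (no
#' response) are excluded; trials whose response lies so early or late that
#' the window exceeds the stimulus epoch are dropped with a warning.
#'
#' @param stim_epochs Baselined stimulus-locked `erp_epochs`.
#' @param window_ms Relock window (default c(-2000, 1000) ms).
#' @return A response-locked `erp_epochs` in the same units, with sample
#'   identity preserved: the value at stimulus-time t equals the value at
#'   response-relative time t - RT.
#' @export
relock_to_response <- function(stim_epochs, window_ms = c(-2000, 1000)) {
  if (!isTRUE(stim_epochs$baseline_applied)) {
    stop("relock_to_response requires baselined stimulus epochs", call. = FALSE)
  }
  if (stim_epochs$lock != "stimulus") {
    stop("input must be stimulus-locked", call. = FALSE)
  }
  meta <- stim_epochs$trial_meta
  has_resp <- !is.na(meta$rt_samples)
  a <- ms_to_samples(window_ms[1], stim_epochs$rate)
  b <- ms_to_samples(window_ms[2], stim_epochs$rate)
  i0 <- which.min(abs(stim_epochs$times_ms))
  ns <- length(stim_epochs$times_ms)
  lo <- i0 + meta$rt_samples + a
  hi <- i0 + meta$rt_samples + b
  ok <- has_resp & !is.na(lo) & lo >= 1 & hi <= ns
  if (any(has_resp & !ok)) {
    warning(sum(has_resp & !ok),
            " trial(s) dropped: relock window exceeds the stimulus epoch")
  }
  keep <- which(ok)
  arr <- relock_gather(stim_epochs$data, dim(stim_epochs$data),
                       as.integer(keep), as.integer(meta$rt_samples[keep]),
                       as.integer(i0), as.integer(a), as.integer(b))
  times <- (a:b) * 1000 / stim_epochs$rate
  new_epochs(arr, times, stim_epochs$rate, "response", TRUE,
             meta[keep, , drop = FALSE], stim_epochs$units,
             stim_epochs$montage)
}

#' Feedback-locked segmentation from the continuous record
#'
#' Cuts one epoch per response event directly from the (unsegmented)
#' recording, windowed to \[-200, 1500\] ms around the response and
#' baseline-corrected to the \[-200, 0\] ms pre-response interval. Each
#' trial is labelled by feedback condition: "correct" for in-time responses
#' and "error" for early and late responses pooled. Misses have no response
#' event and therefore no feedback epoch.
#'
#' @param rec A filtered/resampled `erp_recording`.
#' @param scheme A [segmentation_scheme()] ("feedback" by default).
#' @return A response-locked `erp_epochs` with a `condition` column in
#'   `trial_meta`.
#' @export
segment_feedback <- function(rec, scheme = segmentation_scheme("feedback")) {
  tt <- trial_table_from_events(rec)
  tt <- tt[!is.na(tt$resp_sample) & tt$category != "miss", ]
  a <- ms_to_samples(scheme$window_ms[1], rec$rate)
  b <- ms_to_samples(scheme$window_ms[2], rec$rate)
  ok <- tt$resp_sample + a >= 1 & tt$resp_sample + b <= ncol(rec$data)
  if (any(!ok)) {
    warning(sum(!ok), " feedback epoch(s) exceeded recording bounds and were dropped")
    tt <- tt[ok, ]
  }
  arr <- gather_epoch_array(rec$data, tt$resp_sample, a, b, rec$rate,
                            scheme$baseline_ms)
  times <- (a:b) * 1000 / rec$rate
  meta <- tibble::tibble(
    trial_index = tt$trial_index, rt_ms = tt$rt_ms,
    rt_samples = tt$resp_sample - tt$stim_sample,
    category = tt$category,
    condition = ifelse(tt$category == "correct", "correct", "error"),
    kept = TRUE
  )
  new_epochs(arr, times, rec$rate, "response", TRUE, meta, "uV", rec$montage)
}
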