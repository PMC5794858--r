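#' ERP component windows and electrodes
#'
#' The quantification windows of the analysis: P1 and N1 over the parietal
#' electrodes P7/P8/P9/P10 (latency windows are group-specific: controls
#' 115-140 / 185-205 ms, patients 125-150 / 195-215 ms), the four
#' pre-response CNV windows at Cz (-825..-775, -625..-525, -225..-175,
#' -50..0 ms), and the two FRN peak windows at FCz (controls & ADD 200-210
#' and 300-310 ms, ADHD-C 225-235 and 320-330 ms post response).
#'
#' @param group Group label; "control" selects the control windows, any
#'   other label the patient windows.
#' @return A `component_windows` list.
#' @export
component_windows <- function(group = "control") {
  ctrl <- identical(group, "control")
  structure(list(
    p1 = list(window_ms = if (ctrl) c(115, 140) else c(125, 150),
              electrodes = c("P7", "P8", "P9", "P10")),
    n1 = list(window_ms = if (ctrl) c(185, 205) else c(195, 215),
              electrodes = c("P7", "P8", "P9", "P10")),
    cnv = list(windows_ms = list(w1 = c(-825, -775), w2 = c(-625, -525),
                                 w3 = c(-225, -175), w4 = c(-50, 0)),
               electrode = "Cz"),
    frn = list(peak1_ms = if (ctrl || identical(group, "ADD")) c(200, 210) else c(225, 235),
               peak2_ms = if (ctrl || identical(group, "ADD")) c(300, 310) else c(320, 330),
               electrode = "FCz")
  ), class = "component_windows")
}

#' Windowed mean amplitude of a trial-averaged ERP
#'
#' Averages the kept trials passing the condition filter into an ERP,
#' takes the mean over the samples of the closed latency window, and
#' averages over the listed electrodes. This windowed mean of the
#' trial-average waveform is the "mean amplitude" quantification used for
#' every component (the windows are narrow, so a per-trial peak search
#' would only add noise bias).
#'
#' @param epochs An `erp_epochs` (CSD-transformed or identity mode).
#' @param electrodes Character vector of channel names.
#' @param window_ms Closed latency window c(a, b) in ms.
#' @param trials Optional trial filter (logical/integer), combined with the
#'   `kept` flag.
#' @return Scalar amplitude, or `NA` (with a warning) if no trial survives.
#' @export
window_mean <- function(epochs, electrodes, window_ms, trials = NULL) {
  erp <- tryCatch(erp_average(epochs, trials, electrodes),
                  error = function(e) NULL)
  if (is.null(erp)) {
    warning("no kept trials in condition; returning NA")
    return(NA_real_)
  }
  idx <- window_sample_idx(epochs, window_ms)
  mean(erp[, idx, drop = FALSE])
}

#' CNV window means per accuracy condition
#'
#' Extracts the four pre-response CNV window means at Cz from
#' response-relocked epochs, separately for correct trials and for error
#' trials (early and late pooled).
#'
#' @param relocked_epochs Response-locked `erp_epochs` from
#'   [relock_to_response()].
#' @param windows A [component_windows()] list.
#' @return Tibble: condition, cnv_w1..cnv_w4.
#' @export
extract_cnv <- function(relocked_epochs, windows = component_windows()) {
  if (relocked_epochs$lock != "response") {
    stop("CNV extraction needs response-locked epochs", call. = FALSE)
  }
  el <- windows$cnv$electrode
  conds <- list(correct = relocked_epochs$trial_meta$category == "correct",
                error = relocked_epochs$trial_meta$category %in% c("early", "late"))
  purrr::map_dfr(names(conds), function(cn) {
    erp <- tryCatch(erp_average(relocked_epochs, which(conds[[cn]]), el),
                    error = function(e) NULL)
    vals <- vapply(windows$cnv$windows_ms, function(w) {
      if (is.null(erp)) return(NA_real_)
      mean(erp[, window_sample_idx(relocked_epochs, w)])
    }, numeric(1))
    if (is.null(erp)) warning("no kept ", cn, " trials; CNV is NA")
    tibble::tibble(condition = cn, cnv_w1 = vals[[1]], cnv_w2 = vals[[2]],
                   cnv_w3 = vals[[3]], cnv_w4 = vals[[4]])
  })
}

#' FRN peak-to-peak amplitudes and their condition difference
#'
#' On the condition-average waveform at FCz, locates the minimum (most
#' negative value, earliest sample on ties) within each of the two
#' group-specific peak windows; the peak-to-peak value is
#' `value(peak2) - value(peak1)`, and the FRN is the difference of this
#' amplitude between correct- and error-feedback trials
#' (correct - error). Peak-to-peak scoring makes the measure invariant to
#' any constant offset shared by both deflections.
#'
#' @param feedback_epochs Feedback-locked `erp_epochs` from
#'   [segment_feedback()].
#' @param windows A [component_windows()] list (group-specific).
#' @return Tibble: frn_p2p_correct, frn_p2p_error, frn_difference.
#' @export
extract_frn <- function(feedback_epochs, windows = component_windows()) {
  el <- windows$frn$electrode
  p2p <- function(cond) {
    sel <- feedback_epochs$trial_meta$condition == cond &
      feedback_epochs$trial_meta$kept
    if (!any(sel)) {
      warning("no kept ", cond, " trials; FRN is NA")
      return(NA_real_)
    }
    erp <- erp_average(feedback_epochs, which(sel), el)[1, ]
    peak_min <- function(w) {
      idx <- window_sample_idx(feedback_epochs, w)
      min(erp[idx])
    }
    peak_min(windows$frn$peak2_ms) - peak_min(windows$frn$peak1_ms)
  }
  pc <- p2p("correct"); pe <- p2p("error")
  tibble::tibble(frn_p2p_correct = pc, frn_p2p_error = pe,
                 frn_difference = pc - pe)
}

#' Per-subject component table for one analyzed subject
#'
#' Bundles P1/N1 (parietal mean), the four CNV windows at Cz and the FRN
#' measures into one tidy row set (one row per condition where applicable).
#'
#' @param stim_epochs Baselined stimulus-locked epochs (spatially
#'   transformed).
#' @param relocked_epochs Response-relocked epochs (spatially transformed).
#' @param feedback_epochs Feedback-locked epochs (spatially transformed).
#' @param group Group label (selects windows).
#' @return Tibble with columns component, condition, value.
#' @export
subject_component_table <- function(stim_epochs, relocked_epochs,
                                    feedback_epochs, group) {
  win <- component_windows(group)
  conds <- list(correct = "correct", error = c("early", "late"))
  rows <- list()
  for (cn in names(conds)) {
    sel <- which(stim_epochs$trial_meta$category %in% conds[[cn]])
    rows[[paste0("p1_", cn)]] <- tibble::tibble(
      component = "p1", condition = cn,
      value = window_mean(stim_epochs, win$p1$electrodes, win$p1$window_ms, sel))
    rows[[paste0("n1_", cn)]] <- tibble::tibble(
      component = "n1", condition = cn,
      value = window_mean(stim_epochs, win$n1$electrodes, win$n1$window_ms, sel))
  }
  cnv <- extract_cnv(relocked_epochs, win)
  rows$cnv <- tidyr::pivot_longer(cnv, dplyr::starts_with("cnv_"),
                                  names_to = "component", values_to = "value")
  frn <- extract_frn(feedback_epochs, win)
  rows$frn <- tibble::tibble(
    component = c("frn_p2p", "frn_p2p", "frn_difference"),
    condition = c("correct", "error", "difference"),
    value = c(frn$frn_p2p_correct, frn$frn_p2p_error, frn$frn_difference))
  dplyr::bind_rows(rows)
}

#' Validate an electrode/time-window choice against the full montage
#'
#' For a candidate component window, compares each electrode's per-subject
#' window mean against the per-subject average of all other electrodes with
#' a paired two-tailed t-test, and selects the electrodes that are both
#' significant at the Bonferroni-corrected threshold (p < 0.0007 by
#' default, the published critical value) and larger in the expected
#' polarity (more negative for N-type, more positive for P-type
#' components).
#'
#' @param subject_amplitudes Subjects x channels matrix of per-subject
#'   window-mean amplitudes over the full montage.
#' @param montage The montage (supplies channel labels).
#' @param expected_polarity "negative" or "positive".
#' @param alpha Critical threshold (default 0.0007).
#' @return Tibble: electrode, t, p, mean_diff, selected.
#' @export
validate_selection <- function(subject_amplitudes, montage,
                               expected_polarity = c("negative", "positive"),
                               alpha = 0.0007) {
  expected_polarity <- match.arg(expected_polarity)
  if (nrow(subject_amplitudes) < 2) {
    stop("insufficient data: need at least 2 subjects", call. = FALSE)
  }
  nch <- ncol(subject_amplitudes)
  stopifnot(nch == n_channels(montage))
  res <- purrr::map_dfr(seq_len(nch), function(e) {
    x <- subject_amplitudes[, e]
    y <- rowMeans(subject_amplitudes[, -e, drop = FALSE])
    tt <- stats::t.test(x, y, paired = TRUE)
    tibble::tibble(electrode = montage$labels[e],
                   t = unname(tt$statistic), p = tt$p.value,
                   mean_diff = mean(x - y))
  })
  sign_ok <- if (expected_polarity == "negative") res$mean_diff < 0 else res$mean_diff > 0
  res$selected <- res$p < alpha & sign_ok
  res
}

#' Per-subject window means over the full montage
#'
#' Helper feeding [validate_selection()]: the trial-average window mean of
#' every channel for one subject's epochs.
#'
#' @param epochs An `erp_epochs`.
#' @param window_ms Latency window.
#' @param trials Optional trial filter.
#' @return Numeric vector, one value per channel.
#' @export
channel_window_means <- function(epochs, window_ms, trials = NULL) {
  erp <- erp_average(epochs, trials)
  idx <- window_sample_idx(epochs, window_ms)
  rowMeans(erp[, idx, drop = FALSE])
}
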