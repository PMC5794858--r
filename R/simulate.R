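#' Draw one subject's task behavior
#'
#' Samples the per-trial response categories and latencies of one subject.
#' Subjects differ in timing precision through a latent standard-normal
#' factor `u` that shifts the subject's correct-response probability by
#' `correct_rate_sd * u` (the published between-subject spread of the
#' correct rate); the remaining category probabilities are rescaled
#' proportionally. Latencies are then drawn from the group's calibrated
#' shifted-lognormal model truncated to the sampled category's window, so
#' classification of the drawn latency always reproduces the category.
#'
#' Assumes the RNG state has been seeded by the caller; all draws come from
#' R's RNG so a fixed seed gives bit-identical behavior.
#'
#' @param profile A [group_profile()].
#' @param config A [sim_config()].
#' @param u Latent timing-precision factor (standard normal scale).
#' @return Tibble with `trial_index`, `category`, `rt_ms` (NA for misses).
#' @export
draw_subject_behavior <- function(profile, config, u = 0) {
  t <- profile$category_targets
  p_c <- min(max(t[["correct"]] + profile$correct_rate_sd * u, 0.02), 0.95)
  rest <- t[c("early", "late", "miss")] * (1 - p_c) / (1 - t[["correct"]])
  probs <- c(correct = p_c, rest)
  cats <- sample(names(probs), config$n_trials, replace = TRUE, prob = probs)
  rt <- sample_rt_given_category(cats, profile$rt_model)
  tibble::tibble(trial_index = seq_len(config$n_trials),
                 category = cats, rt_ms = rt)
}

# Latent correlation needed so that the realized correct COUNT (which adds
# multinomial sampling noise to the latent rate) correlates with the
# inattention score at the profile's target. Analytic attenuation:
# corr(count, u) = T*sd / sqrt(T^2 sd^2 + T p(1-p)).
latent_symptom_rho <- function(profile, config) {
  T <- config$n_trials
  sd_c <- profile$correct_rate_sd
  p <- profile$category_targets[["correct"]]
  r_cu <- (T * sd_c) / sqrt(T^2 * sd_c^2 + T * p * (1 - p))
  max(-1, min(1, profile$symptom_performance_r / r_cu))
}

draw_symptoms <- function(profile, v) {
  sm <- profile$symptom_moments
  clamp01 <- function(x) pmin(3, pmax(0, x))
  # inattention is coupled to performance via v; the other scales are
  # independent subject traits
  c(inattention = clamp01(sm$inattention[["mean"]] + sm$inattention[["sd"]] * v),
    hyperactivity = clamp01(stats::rnorm(1, sm$hyperactivity[["mean"]],
                                         sm$hyperactivity[["sd"]])),
    impulsivity = clamp01(stats::rnorm(1, sm$impulsivity[["mean"]],
                                       sm$impulsivity[["sd"]])))
}

#' Generate one synthetic subject
#'
#' Draws the subject's behavior and symptom scores and (optionally)
#' synthesizes the continuous 60-channel recording: background noise plus a
#' posterior P1/N1 complex after each stimulus, a vertex-focused
#' pre-response CNV ramp whose mean in each of the four analysis windows
#' equals the profile targets (in the identity-spatial measurement space,
#' in expectation over noise), and a fronto-central feedback complex whose
#' two negative deflections differ between correct- and error-feedback
#' trials per the profile. Artifacts are injected at the configured rates.
#' The same seed yields bit-identical output.
#'
#' @param profile A [group_profile()].
#' @param config A [sim_config()].
#' @param seed Integer seed for this subject.
#' @param latent Optional named vector `c(u = ..., v = ...)` of the
#'   performance and symptom latents (drawn internally, with the profile's
#'   coupling, when omitted; cohort generation passes them in).
#' @param eeg Generate the EEG signal (set FALSE for behavior-only studies).
#' @return An `erp_subject` list: `group`, `seed`, `behavior` (trial
#'   tibble), `symptom_scores`, `correct_count`, and `recording` (NULL when
#'   `eeg = FALSE`).
#' @export
generate_subject <- function(profile, config, seed, latent = NULL, eeg = TRUE) {
  set.seed(as.integer(seed))
  if (is.null(latent)) {
    rho <- latent_symptom_rho(profile, config)
    u <- stats::rnorm(1)
    v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(1)
    latent <- c(u = u, v = v)
  }
  behavior <- draw_subject_behavior(profile, config, latent[["u"]])
  symptoms <- draw_symptoms(profile, latent[["v"]])
  rec <- if (eeg) synthesize_recording(behavior, profile, config) else NULL
  structure(list(group = profile$group, seed = as.integer(seed),
                 behavior = behavior, symptom_scores = symptoms,
                 correct_count = sum(behavior$category == "correct"),
                 recording = rec),
            class = "erp_subject")
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects_per_group` subjects for each requested group.
#' Per-subject seeds are fanned out deterministically from the master seed.
#' Within each group the subject latents (timing precision, inattention)
#' are drawn jointly from a Gaussian copula whose correlation is calibrated
#' analytically so the realized correct count and the inattention score
#' correlate at the profile's `symptom_performance_r`.
#'
#' Recordings are large (hundreds of MB per subject), so by default only
#' behavior and metadata are materialized and EEG is synthesized on demand
#' by the pipeline; set `eeg = TRUE` to attach recordings directly.
#'
#' @param config A [sim_config()].
#' @param groups Character vector of group names (default all three).
#' @param eeg Attach synthesized recordings to each subject.
#' @return An `erp_cohort`: list with `subjects` (tibble: subject_id, group,
#'   seed, latents, symptom scores, correct_count) and `records` (list of
#'   `erp_subject`).
#' @export
generate_cohort <- function(config = sim_config(),
                            groups = c("control", "ADD", "ADHD-C"),
                            eeg = FALSE) {
  records <- list()
  rows <- list()
  for (g in groups) {
    profile <- group_profile(g)
    rho <- latent_symptom_rho(profile, config)
    set.seed(seed_hash(config$master_seed, g, 0L))
    n <- config$n_subjects_per_group
    u <- stats::rnorm(n)
    v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n)
    for (i in seq_len(n)) {
      sid <- sprintf("%s_%02d", gsub("-", "", g), i)
      sseed <- seed_hash(config$master_seed, g, i)
      rec <- generate_subject(profile, config, sseed,
                              latent = c(u = u[i], v = v[i]), eeg = eeg)
      records[[sid]] <- rec
      rows[[sid]] <- tibble::tibble(
        subject_id = sid, group = g, seed = sseed,
        u = u[i], v = v[i],
        inattention = rec$symptom_scores[["inattention"]],
        hyperactivity = rec$symptom_scores[["hyperactivity"]],
        impulsivity = rec$symptom_scores[["impulsivity"]],
        correct_count = rec$correct_count
      )
    }
  }
  structure(list(subjects = dplyr::bind_rows(rows), records = records,
                 config = config),
            class = "erp_cohort")
}

#' @export
print.erp_cohort <- function(x, ...) {
  cat(sprintf("<erp_cohort> %d subjects (%s)\n", nrow(x$subjects),
              paste(unique(x$subjects$group), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# EEG synthesis

# CNV ramp value as a function of response-relative time (ms): zero before
# stimulus onset (-rt), piecewise linear through the four window plateaus
# (constant within each analysis window so window means equal the targets
# exactly), released back to zero within 100 ms after the response.
cnv_knots <- function(rt_ms, targets) {
  kt <- c(-825, -775, -625, -525, -225, -175, -50, 0, 100)
  kv <- c(targets[1], targets[1], targets[2], targets[2],
          targets[3], targets[3], targets[4], targets[4], 0)
  keep <- kt > -rt_ms
  list(t = c(-rt_ms, kt[keep]), v = c(0, kv[keep]))
}

# Synthesize the continuous recording for one subject's behavior. Uses the
# caller's RNG stream (generate_subject seeds it).
synthesize_recording <- function(behavior, profile, config) {
  rate <- config$rate
  nch <- config$n_channels
  montage <- make_equidistant_montage(nch)
  smp <- function(ms) round(ms * rate / 1000)

  # --- trial timeline -----------------------------------------------------
  ntr <- nrow(behavior)
  iti <- stats::runif(ntr, config$iti_range_ms[1], config$iti_range_ms[2])
  pad0 <- smp(2500)
  stim <- integer(ntr); resp <- rep(NA_integer_, ntr)
  cur <- pad0 + 1L
  for (k in seq_len(ntr)) {
    stim[k] <- cur
    if (!is.na(behavior$rt_ms[k])) {
      resp[k] <- stim[k] + smp(behavior$rt_ms[k])
      tail_s <- resp[k]
    } else {
      tail_s <- stim[k] + smp(3000)
    }
    cur <- tail_s + smp(config$feedback_duration_ms) + smp(iti[k])
  }
  n <- stim[ntr] + smp(3500)

  # --- per-subject amplitude factors (symmetric truncation keeps mean 1) --
  amp_sd <- config$subject_amp_sd
  tr_norm <- function() min(max(stats::rnorm(1, 1, amp_sd), 1 - 3 * amp_sd),
                            1 + 3 * amp_sd)
  f_cnv <- tr_norm(); f_frn <- tr_norm()

  # --- component time series ----------------------------------------------
  cnv <- numeric(n); frn <- numeric(n); p1n1 <- numeric(n)
  frn_par <- profile$frn
  c1 <- mean(frn_par$peak1_window); c2 <- mean(frn_par$peak2_window)
  sdp <- frn_par$peak_sd_ms
  a1 <- frn_par$first_peak_amp
  p1c <- mean(profile$p1_n1$p1_window); n1c <- mean(profile$p1_n1$n1_window)
  for (k in seq_len(ntr)) {
    # P1/N1 follow every stimulus
    idx <- stim[k] + (smp(40):smp(320))
    tms <- (idx - stim[k]) * 1000 / rate
    p1n1[idx] <- p1n1[idx] +
      profile$p1_n1$p1_amp * exp(-(tms - p1c)^2 / (2 * 10^2)) +
      profile$p1_n1$n1_amp * exp(-(tms - n1c)^2 / (2 * 12^2))
    if (is.na(resp[k])) next
    # CNV ramp from stimulus onset to 100 ms past the response
    idx <- stim[k]:(resp[k] + smp(100))
    tms <- (idx - resp[k]) * 1000 / rate
    kn <- cnv_knots(behavior$rt_ms[k], profile$cnv_window_targets)
    cnv[idx] <- cnv[idx] +
      f_cnv * stats::approx(kn$t, kn$v, xout = tms, yleft = 0, yright = 0,
                            ties = "ordered")$y
    # feedback complex: two negative deflections after the response
    a2 <- a1 + if (behavior$category[k] == "correct") frn_par$correct_p2p else
      frn_par$error_p2p
    idx <- resp[k] + (smp(80):smp(480))
    tms <- (idx - resp[k]) * 1000 / rate
    frn[idx] <- frn[idx] + f_frn * (a1 * exp(-(tms - c1)^2 / (2 * sdp^2)) +
                                      a2 * exp(-(tms - c2)^2 / (2 * sdp^2)))
  }

  # --- spatial projection of the components -------------------------------
  pos <- montage$positions
  gauss_about <- function(center, sigma = 0.25) {
    d <- acos(pmin(pmax(as.numeric(pos %*% center), -1), 1))
    exp(-d^2 / (2 * sigma^2))
  }
  w_cnv <- gauss_about(pos[channel_index(montage, "Cz"), ])
  w_frn <- gauss_about(pos[channel_index(montage, "FCz"), ])
  w_p1n1 <- pmin(1, Reduce(`+`, lapply(c("P7", "P8", "P9", "P10"),
                                       function(l) gauss_about(pos[channel_index(montage, l), ]))))

  # --- background noise ----------------------------------------------------
  # spatial mixing patterns and modulation parameters come from the R RNG;
  # the bulk sample stream is produced in compiled code from a substream
  # seed drawn here, so subject-level determinism is preserved
  nz <- config$noise
  if (nz$pink_sd > 0 && nz$pink_rank > 0) {
    K <- nz$pink_rank
    centers <- random_upper_sphere_points(K)
    M <- vapply(seq_len(K), function(k) gauss_about(centers[k, ], 0.8),
                numeric(nch))
    M <- M * nz$pink_sd / sqrt(rowSums(M^2))
  } else {
    M <- matrix(0, nch, 0)
  }
  if (nz$alpha_sd > 0) {
    Ka <- 4
    centers <- random_upper_sphere_points(Ka, posterior = TRUE)
    Wa <- vapply(seq_len(Ka), function(k) gauss_about(centers[k, ], 0.6),
                 numeric(nch))
    Wa <- Wa * nz$alpha_sd / pmax(sqrt(rowSums(Wa^2)), 1e-6)
    alpha_par <- cbind(stats::runif(Ka, 0, 2 * pi),
                       stats::runif(Ka, 0.1, 0.3),
                       stats::runif(Ka, 0, 2 * pi))
  } else {
    Wa <- matrix(0, nch, 0)
    alpha_par <- matrix(0, 0, 3)
  }
  noise_seed <- stats::runif(1, 0, 2^31)
  data <- synth_background(nch, n,
                           cbind(w_cnv, w_frn, w_p1n1, M, Wa),
                           rbind(cnv, frn, p1n1),
                           ncol(M), pink_ar_coefs(nz$pink_alpha),
                           ncol(Wa), alpha_par, 10, nz$white_sd, rate,
                           noise_seed)

  # --- artifacts -----------------------------------------------------------
  dur_s <- n / rate
  art <- config$artifacts
  if (art$blink_rate > 0) {
    nb <- stats::rpois(1, art$blink_rate * dur_s)
    if (nb > 0) {
      wf <- pmax(0, pos[, 2])^1.5
      wf <- wf / max(wf)
      width <- smp(1200)
      onsets <- sort(sample.int(max(1, n - width), nb))
      for (o in onsets) {
        amp <- stats::runif(1, 220, 300)
        shape <- amp * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = width)))
        data[, o:(o + width - 1)] <- data[, o:(o + width - 1)] + outer(wf, shape)
      }
    }
  }
  if (art$drift_rate > 0) {
    nd <- stats::rpois(1, art$drift_rate * dur_s)
    if (nd > 0) {
      width <- smp(3000)
      onsets <- sample.int(max(1, n - width), nd)
      for (o in onsets) {
        ch <- sample.int(nch, 1)
        amp <- stats::runif(1, 210, 260) * sample(c(-1, 1), 1)
        data[ch, o:(o + width - 1)] <- data[ch, o:(o + width - 1)] +
          amp * sin(pi * seq(0, 1, length.out = width))
      }
    }
  }
  if (art$flatline_rate > 0) {
    nf <- stats::rpois(1, art$flatline_rate * dur_s)
    if (nf > 0) {
      width <- smp(2000)
      onsets <- sample.int(max(1, n - width), nf)
      for (o in onsets) {
        ch <- sample.int(nch, 1)
        data[ch, o:(o + width - 1)] <- 0
      }
    }
  }

  # --- events --------------------------------------------------------------
  has_resp <- !is.na(resp)
  events <- dplyr::bind_rows(
    tibble::tibble(onset_sample = stim, kind = "stimulus",
                   trial_index = behavior$trial_index),
    tibble::tibble(onset_sample = resp[has_resp], kind = "response",
                   trial_index = behavior$trial_index[has_resp]),
    tibble::tibble(onset_sample = resp[has_resp], kind = "feedback",
                   trial_index = behavior$trial_index[has_resp])
  )
  events <- events[order(events$onset_sample), ]
  new_recording(data, rate, events, montage)
}

# Kasdin AR coefficients for 1/f^alpha shaping.
pink_ar_coefs <- function(alpha, p = 24) {
  a <- numeric(p)
  prev <- 1
  for (k in seq_len(p)) {
    prev <- (k - 1 - alpha / 2) * prev / k
    a[k] <- prev
  }
  a
}

random_upper_sphere_points <- function(k, posterior = FALSE) {
  out <- matrix(0, k, 3)
  got <- 0
  while (got < k) {
    p <- stats::rnorm(3)
    p <- p / sqrt(sum(p^2))
    if (p[3] < -0.1) next
    if (posterior && p[2] > -0.2) next
    got <- got + 1
    out[got, ] <- p
  }
  out
}
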