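# Shared fixtures: everything is built in code at test time.

# Small, fast simulation settings for unit tests (the acceptance tests use
# the full study conditions instead).
quick_cfg <- function(n_trials = 40, n_channels = 20, ...) {
  sim_config(n_trials = n_trials, n_channels = n_channels, ...)
}

# Settings with all stochastic elements silenced: recovered component
# amplitudes must then equal the generative targets up to quantization.
noisefree_cfg <- function(n_trials = 60, n_channels = 20) {
  sim_config(
    n_trials = n_trials, n_channels = n_channels,
    noise = list(pink_sd = 0, pink_rank = 0, alpha_sd = 0, white_sd = 0),
    artifacts = list(blink_rate = 0, drift_rate = 0, flatline_rate = 0),
    subject_amp_sd = 0
  )
}

# Hand-built montage: two rings of six equally spaced azimuths, so that a
# 60 degree rotation about z is a pure channel permutation.
ring_montage <- function() {
  az <- seq(0, 300, by = 60) * pi / 180
  ring <- function(incl_deg) {
    incl <- incl_deg * pi / 180
    cbind(sin(incl) * cos(az), sin(incl) * sin(az), cos(incl))
  }
  pos <- rbind(ring(40), ring(75))
  structure(list(labels = sprintf("R%02d", seq_len(nrow(pos))),
                 positions = pos, reference_label = "ref"),
            class = "erp_montage")
}

# Wrap a channels x samples x trials array as microvolt epochs.
toy_epochs <- function(arr, rate = 256, lock = "stimulus",
                       categories = NULL, baselined = TRUE) {
  d <- dim(arr)
  mon <- make_equidistant_montage(max(16, d[1]))
  mon$labels <- mon$labels[seq_len(d[1])]
  mon$positions <- mon$positions[seq_len(d[1]), , drop = FALSE]
  if (is.null(categories)) categories <- rep("correct", d[3])
  meta <- tibble::tibble(trial_index = seq_len(d[3]), rt_ms = 1200,
                         rt_samples = ms_to_samples(1200, rate),
                         category = categories,
                         condition = ifelse(categories == "correct",
                                            "correct", "error"),
                         kept = TRUE)
  i0 <- max(1, floor(d[2] / 4))  # lock a quarter of the way in
  times <- (seq_len(d[2]) - i0) * 1000 / rate
  new_epochs(arr, times, rate, lock, baselined, meta, "uV", mon)
}

# Single-channel sinusoid recording for filter tests.
sine_recording <- function(freqs, amps, rate = 500, dur_s = 20,
                           n_channels = 16, dc = 0) {
  t <- (seq_len(rate * dur_s) - 1) / rate
  x <- dc + Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * t),
                            freqs, amps))
  data <- matrix(rep(x, each = n_channels), n_channels)
  ev <- tibble::tibble(onset_sample = as.integer(rate * c(2, 5)),
                       kind = "stimulus", trial_index = 1:2)
  new_recording(data, rate, ev, make_equidistant_montage(n_channels))
}

expect_ggplot <- function(x) expect_s3_class(x, "ggplot")

# Recovery pipeline for noise-free data: a silent recording has no
# background activity at all, so the low-activity criterion (meant to catch
# dead channels against a live background) is disabled.
noisefree_pipeline <- function(cfg) {
  p <- recovery_config(cfg)
  p$criteria <- rejection_criteria(low_activity_uV = 0)
  p
}

# Brute-force split-plot sums of squares for one within factor (a levels)
# and one between factor, balanced, computed from cell means only.
bruteforce_split_plot <- function(df) {
  m <- mean(df$value)
  a <- length(unique(df$w)); g <- length(unique(df$grp))
  n <- length(unique(df$subject)) / g
  ms <- tapply(df$value, df$subject, mean)
  mg <- tapply(df$value, df$grp, mean)
  ma <- tapply(df$value, df$w, mean)
  mga <- tapply(df$value, list(df$grp, df$w), mean)
  ss_subj <- a * sum((ms - m)^2)
  ss_g <- n * a * sum((mg - m)^2)
  ss_err_b <- ss_subj - ss_g
  ss_a <- g * n * sum((ma - m)^2)
  ss_ga <- n * sum(sweep(sweep(mga, 1, mg - m), 2, ma - m)^2) -
    0  # cell - row - col + grand
  # explicit double-centering for clarity
  cc <- mga
  for (i in seq_len(g)) for (j in seq_len(a)) {
    cc[i, j] <- mga[i, j] - mg[i] - ma[j] + m
  }
  ss_ga <- n * sum(cc^2)
  ss_tot <- sum((df$value - m)^2)
  ss_err_w <- ss_tot - ss_subj - ss_a - ss_ga
  list(
    F_g = (ss_g / (g - 1)) / (ss_err_b / (g * (n - 1))),
    F_a = (ss_a / (a - 1)) / (ss_err_w / (g * (n - 1) * (a - 1))),
    F_ga = (ss_ga / ((g - 1) * (a - 1))) /
      (ss_err_w / (g * (n - 1) * (a - 1))),
    ss = c(g = ss_g, err_b = ss_err_b, a = ss_a, ga = ss_ga,
           err_w = ss_err_w, tot = ss_tot)
  )
}

toy_table <- function(seed = 1, g = 3, n = 4, a = 3) {
  set.seed(seed)
  grid <- expand.grid(subject = seq_len(g * n), w = paste0("w", seq_len(a)))
  grid$grp <- paste0("g", (grid$subject - 1) %/% n + 1)
  eff <- stats::setNames(seq(0, by = 0.8, length.out = a),
                         paste0("w", seq_len(a)))
  grid$value <- stats::rnorm(nrow(grid), sd = 2) + eff[grid$w] +
    2 * (grid$grp == "g2") + stats::rnorm(g * n)[grid$subject]
  grid
}

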