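#' Pipeline configuration
#'
#' Bundles every stage's parameters: the simulation config, the band-pass
#' settings (or NULL to skip filtering), the analysis sampling rate, the
#' rejection criteria, the spatial mode ("csd" or "identity") with its CSD
#' parameters, and classification boundaries. The whole object serializes
#' to YAML and back without loss (see [save_pipeline_config()]).
#'
#' @param sim A [sim_config()].
#' @param bandpass List(low, high, slope_db_per_oct) or NULL to skip the
#'   band-pass stage.
#' @param analysis_rate Rate the recording is resampled to before
#'   segmentation (default 256 Hz).
#' @param criteria A [rejection_criteria()].
#' @param spatial "csd" or "identity".
#' @param csd A [csd_params()].
#' @param write_edf Also export each synthesized recording as EDF when an
#'   output directory is given (off by default; recordings are large).
#' @return An `erp_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            bandpass = list(low = 0.5, high = 20,
                                            slope_db_per_oct = 48),
                            analysis_rate = 256,
                            criteria = rejection_criteria(),
                            spatial = c("csd", "identity"),
                            csd = csd_params(),
                            write_edf = FALSE) {
  spatial <- match.arg(spatial)
  structure(list(sim = sim, bandpass = bandpass,
                 analysis_rate = analysis_rate, criteria = criteria,
                 spatial = spatial, csd = csd, write_edf = write_edf),
            class = "erp_pipeline_config")
}

#' Recovery configuration for synthetic cohorts
#'
#' The pipeline configuration used for parameter-recovery runs: identity
#' spatial mode (amplitude targets are defined in that measurement space)
#' and no band-pass stage. The generator emits signals already confined to
#' the analysis band -- no DC offset, no drift, no line noise -- so for
#' synthetic data the band-pass is structurally a no-op except for its one
#' real effect, attenuating the slow preparatory ramp itself; it is
#' therefore disabled here and reserved for externally recorded data. See
#' the methods vignette for the numerical analysis behind this choice.
#'
#' @param sim A [sim_config()].
#' @return An `erp_pipeline_config`.
#' @export
recovery_config <- function(sim = sim_config()) {
  pipeline_config(sim = sim, bandpass = NULL, spatial = "identity")
}

#' Analyze one subject's recording
#'
#' Runs the full single-subject chain: optional band-pass, resampling to
#' the analysis rate, the three segmentations (stimulus-locked with
#' pre-stimulus baseline, response-relocked, feedback-locked), artifact
#' rejection separately per segmentation scheme, the spatial transform,
#' and component quantification.
#'
#' Two numerically equivalent execution paths exist. The modular path
#' (`fast = FALSE`) materializes every epochs array through
#' [segment_stimulus()], [relock_to_response()] and [segment_feedback()].
#' The fused path (default) evaluates the rejection criteria and the
#' condition-average waveforms directly against the continuous record --
#' the sliding-window criteria are offset-invariant and every epoch window
#' is a window of the continuous record, so the results are identical
#' (this is asserted by the test suite) -- and only condition averages are
#' ever held in memory, which is what makes large cohort runs cheap.
#'
#' @param rec An `erp_recording` (microvolts, 500 Hz typically).
#' @param group Group label (selects component windows).
#' @param config An `erp_pipeline_config`.
#' @param transform Optional prebuilt spatial transform (an `erp_csd` or
#'   [identity_spatial_mode()]); built from the config when omitted.
#' @param fast Use the fused continuous-domain path (default TRUE).
#' @param destructive Passed to [resample_recording()]; run_pipeline sets
#'   it because it owns and immediately discards each recording.
#' @return List: `components` (tidy per-condition tibble), `trials`
#'   (per-trial table with kept flags per scheme), `rejection` (per-scheme
#'   summary), `epochs` (the three transformed epoch objects; on the fused
#'   path these hold one condition-average pseudo-trial per condition).
#' @export
analyze_subject <- function(rec, group, config = pipeline_config(),
                            transform = NULL, fast = TRUE,
                            destructive = FALSE) {
  rec <- resample_recording(rec, config$analysis_rate, destructive)
  if (!is.null(config$bandpass)) {
    rec <- bandpass_filter(rec, config$bandpass$low, config$bandpass$high,
                           config$bandpass$slope_db_per_oct)
  }
  if (is.null(transform)) {
    transform <- if (config$spatial == "identity") identity_spatial_mode()
    else build_csd_matrix(rec$montage, config$csd)
  }
  if (fast) {
    analyze_subject_fused(rec, group, config, transform)
  } else {
    analyze_subject_modular(rec, group, config, transform)
  }
}

analyze_subject_modular <- function(rec, group, config, transform) {
  stim <- segment_stimulus(rec)
  relock <- relock_to_response(stim)
  feedback <- segment_feedback(rec)
  stim <- reject_artifact_epochs(stim, config$criteria)
  relock <- reject_artifact_epochs(relock, config$criteria)
  feedback <- reject_artifact_epochs(feedback, config$criteria)
  rej <- dplyr::bind_rows(
    dplyr::mutate(rejection_summary(stim), scheme = "stimulus"),
    dplyr::mutate(rejection_summary(relock), scheme = "cnv"),
    dplyr::mutate(rejection_summary(feedback), scheme = "feedback")
  )
  stim_t <- apply_csd(stim, transform)
  relock_t <- apply_csd(relock, transform)
  feedback_t <- apply_csd(feedback, transform)
  comp <- subject_component_table(stim_t, relock_t, feedback_t, group)
  trials <- stim$trial_meta |>
    dplyr::select("trial_index", "rt_ms", "category",
                  kept_stimulus = "kept") |>
    dplyr::left_join(
      dplyr::select(feedback$trial_meta, "trial_index",
                    kept_feedback = "kept"),
      by = "trial_index")
  list(components = comp, trials = trials, rejection = rej,
       epochs = list(stimulus = stim_t, cnv = relock_t,
                     feedback = feedback_t))
}

# Fused path: rejection and condition averages computed straight from the
# continuous record; numerically identical to the modular path.
analyze_subject_fused <- function(rec, group, config, transform) {
  rate <- rec$rate
  n <- ncol(rec$data)
  tt <- trial_table_from_events(rec)
  w <- list(stim = c(ms_to_samples(-2000, rate), ms_to_samples(3000, rate)),
            cnv = c(ms_to_samples(-2000, rate), ms_to_samples(1000, rate)),
            fb = c(ms_to_samples(-200, rate), ms_to_samples(1500, rate)))
  bl <- c(ms_to_samples(-200, rate), 0L)

  ok_s <- tt$stim_sample + w$stim[1] >= 1 & tt$stim_sample + w$stim[2] <= n
  if (any(!ok_s)) {
    warning(sum(!ok_s), " stimulus epoch(s) exceeded recording bounds and were dropped")
  }
  tts <- tt[ok_s, ]
  has_resp <- !is.na(tts$resp_sample)
  rt_smp <- tts$resp_sample - tts$stim_sample
  ok_r <- has_resp & rt_smp + w$cnv[1] >= w$stim[1] & rt_smp + w$cnv[2] <= w$stim[2]
  if (any(has_resp & !ok_r)) {
    warning(sum(has_resp & !ok_r),
            " trial(s) dropped: relock window exceeds the stimulus epoch")
  }
  ok_f <- !is.na(tt$resp_sample) & tt$category != "miss" &
    tt$resp_sample + w$fb[1] >= 1 & tt$resp_sample + w$fb[2] <= n
  ttf <- tt[ok_f, ]

  crit <- config$criteria
  w_diff <- max(2L, ms_to_samples(crit$max_diff_window_ms, rate))
  w_low <- max(2L, ms_to_samples(crit$low_activity_window_ms, rate))
  schemes <- list(
    list(locks = as.integer(tts$stim_sample), bl_locks = as.integer(tts$stim_sample),
         a = w$stim[1], b = w$stim[2], bl_a = bl[1], bl_b = bl[2]),
    list(locks = as.integer(tts$resp_sample[ok_r]),
         bl_locks = as.integer(tts$stim_sample[ok_r]),
         a = w$cnv[1], b = w$cnv[2], bl_a = bl[1], bl_b = bl[2]),
    list(locks = as.integer(ttf$resp_sample), bl_locks = as.integer(ttf$resp_sample),
         a = w$fb[1], b = w$fb[2], bl_a = bl[1], bl_b = bl[2])
  )
  res <- reject_schemes_cont(rec$data, schemes, crit$abs_amplitude_uV,
                             crit$max_diff_uV, w_diff,
                             crit$low_activity_uV, w_low)
  kept_s <- res[[1]][, 1] == 0
  kept_r <- res[[2]][, 1] == 0
  kept_f <- res[[3]][, 1] == 0
  rej <- dplyr::bind_rows(
    tibble::tibble(n_trials = length(kept_s), n_rejected = sum(!kept_s),
                   prop_rejected = mean(!kept_s), scheme = "stimulus"),
    tibble::tibble(n_trials = length(kept_r), n_rejected = sum(!kept_r),
                   prop_rejected = mean(!kept_r), scheme = "cnv"),
    tibble::tibble(n_trials = length(kept_f), n_rejected = sum(!kept_f),
                   prop_rejected = mean(!kept_f), scheme = "feedback")
  )

  # condition-average pseudo-epochs (one averaged trial per condition)
  conds <- list(correct = "correct", error = c("early", "late"))
  build_pseudo <- function(locks, bl_locks, win, sel_cat, lock) {
    arrs <- list(); meta <- list()
    for (cn in names(conds)) {
      sel <- sel_cat %in% conds[[cn]]
      if (!any(sel)) next
      m <- lock_window_average(rec$data, seq_len(nrow(rec$data)),
                               as.integer(locks[sel]),
                               as.integer(bl_locks[sel]),
                               win[1], win[2], bl[1], bl[2])
      arrs[[cn]] <- m
      meta[[cn]] <- tibble::tibble(
        trial_index = length(meta) + 1L, rt_ms = NA_real_,
        rt_samples = NA_integer_,
        category = if (cn == "correct") "correct" else "early",
        condition = cn, kept = TRUE)
    }
    if (length(arrs) == 0) return(NULL)
    arr <- array(unlist(arrs), dim = c(nrow(rec$data), win[2] - win[1] + 1,
                                       length(arrs)))
    new_epochs(arr, (win[1]:win[2]) * 1000 / rate, rate, lock, TRUE,
               dplyr::bind_rows(meta), "uV", rec$montage)
  }
  stim_p <- build_pseudo(tts$stim_sample[kept_s], tts$stim_sample[kept_s],
                         w$stim, tts$category[kept_s], "stimulus")
  cnv_p <- build_pseudo(tts$resp_sample[ok_r][kept_r],
                        tts$stim_sample[ok_r][kept_r], w$cnv,
                        tts$category[ok_r][kept_r], "response")
  fb_p <- build_pseudo(ttf$resp_sample[kept_f], ttf$resp_sample[kept_f],
                       w$fb, ttf$category[kept_f], "response")
  if (is.null(stim_p) || is.null(cnv_p) || is.null(fb_p)) {
    stop("no analyzable trials left in at least one segmentation scheme",
         call. = FALSE)
  }
  stim_t <- apply_csd(stim_p, transform)
  cnv_t <- apply_csd(cnv_p, transform)
  fb_t <- apply_csd(fb_p, transform)
  comp <- subject_component_table(stim_t, cnv_t, fb_t, group)

  trials <- tibble::tibble(trial_index = tts$trial_index, rt_ms = tts$rt_ms,
                           category = tts$category, kept_stimulus = kept_s) |>
    dplyr::left_join(tibble::tibble(trial_index = ttf$trial_index,
                                    kept_feedback = kept_f),
                     by = "trial_index")
  list(components = comp, trials = trials, rejection = rej,
       epochs = list(stimulus = stim_t, cnv = cnv_t, feedback = fb_t))
}

#' Run the full cohort pipeline
#'
#' Simulates a cohort (behavior + symptoms first, EEG streamed one subject
#' at a time to bound memory), runs [analyze_subject()] on every
#' recording, and assembles the run report: the behavioral summary,
#' per-subject component table, group-level ANOVAs (behavioral Response x
#' Group; CNV Time Window x Accuracy x Group; FRN one-way Group),
#' per-group performance-symptom correlations, rejection summaries, and
#' group-average CNV (Cz) and FRN (FCz) waveforms for plotting. When
#' `out_dir` is given every table is written as CSV with the config hash
#' embedded in a header comment.
#'
#' @param config An `erp_pipeline_config`.
#' @param groups Groups to simulate (default all three).
#' @param out_dir Optional output directory for CSV artifacts.
#' @return An `erp_report`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         groups = c("control", "ADD", "ADHD-C"),
                         out_dir = NULL) {
  cohort <- generate_cohort(config$sim, groups, eeg = FALSE)
  montage <- make_equidistant_montage(config$sim$n_channels)
  transform <- if (config$spatial == "identity") identity_spatial_mode()
  else build_csd_matrix(montage, config$csd)

  profiles <- lapply(stats::setNames(groups, groups), group_profile)
  comp_rows <- list(); trial_rows <- list(); rej_rows <- list()
  wave_rows <- list()
  for (i in seq_len(nrow(cohort$subjects))) {
    srow <- cohort$subjects[i, ]
    profile <- profiles[[srow$group]]
    subj <- generate_subject(profile, config$sim, srow$seed,
                             latent = c(u = srow$u, v = srow$v), eeg = TRUE)
    if (isTRUE(config$write_edf) && !is.null(out_dir)) {
      dir.create(file.path(out_dir, "edf"), showWarnings = FALSE,
                 recursive = TRUE)
      write_edf(subj$recording,
                file.path(out_dir, "edf", paste0(srow$subject_id, ".edf")))
    }
    an <- analyze_subject(subj$recording, srow$group, config, transform,
                          destructive = TRUE)
    comp_rows[[i]] <- dplyr::mutate(an$components,
                                    subject = srow$subject_id,
                                    group = srow$group, .before = 1)
    trial_rows[[i]] <- dplyr::mutate(an$trials, subject = srow$subject_id,
                                     group = srow$group, .before = 1)
    rej_rows[[i]] <- dplyr::mutate(an$rejection, subject = srow$subject_id,
                                   group = srow$group, .before = 1)
    wave_rows[[i]] <- subject_waveforms(an$epochs, srow)
    rm(subj, an)
  }
  components <- dplyr::bind_rows(comp_rows)
  trials <- dplyr::bind_rows(trial_rows)
  rejection <- dplyr::bind_rows(rej_rows)
  waveforms <- dplyr::bind_rows(wave_rows) |>
    dplyr::group_by(.data$kind, .data$group, .data$condition,
                    .data$time_ms) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")

  behavior <- summarize_behavior(trials)
  stats <- report_statistics(components, trials, cohort$subjects)
  provenance <- list(config_hash = config_hash(config),
                     master_seed = config$sim$master_seed,
                     spatial_mode = config$spatial,
                     n_subjects = nrow(cohort$subjects),
                     r_version = as.character(getRversion()))
  report <- structure(list(behavior = behavior, components = components,
                           trials = trials, rejection = rejection,
                           stats = stats, subjects = cohort$subjects,
                           waveforms = waveforms, provenance = provenance,
                           config = config),
                      class = "erp_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Group-average waveforms at the analysis electrodes, kept for plotting.
subject_waveforms <- function(epochs, srow) {
  rows <- list()
  for (cond in c("correct", "error")) {
    sel_cnv <- which(if (cond == "correct")
      epochs$cnv$trial_meta$category == "correct"
      else epochs$cnv$trial_meta$category %in% c("early", "late"))
    if (length(sel_cnv) && any(epochs$cnv$trial_meta$kept[sel_cnv])) {
      w <- erp_average(epochs$cnv, sel_cnv, "Cz")[1, ]
      rows[[paste0("cnv_", cond)]] <- tibble::tibble(
        kind = "cnv", group = srow$group, condition = cond,
        time_ms = epochs$cnv$times_ms, value = w)
    }
    sel_fb <- which(epochs$feedback$trial_meta$condition == cond)
    if (length(sel_fb) && any(epochs$feedback$trial_meta$kept[sel_fb])) {
      w <- erp_average(epochs$feedback, sel_fb, "FCz")[1, ]
      rows[[paste0("frn_", cond)]] <- tibble::tibble(
        kind = "frn", group = srow$group, condition = cond,
        time_ms = epochs$feedback$times_ms, value = w)
    }
  }
  dplyr::bind_rows(rows)
}

#' Behavioral summary table
#'
#' Per-subject response-category percentages, then group mean and standard
#' deviation -- the behavioral table of a cohort run.
#'
#' @param trials Per-trial table with `subject`, `group`, `category`.
#' @return Tibble: group, category, mean_pct, sd_pct.
#' @export
summarize_behavior <- function(trials) {
  cats <- c("correct", "early", "late", "miss")
  per_subj <- trials |>
    dplyr::count(.data$group, .data$subject, .data$category) |>
    tidyr::complete(tidyr::nesting(!!rlang::sym("group"),
                                   !!rlang::sym("subject")),
                    category = cats, fill = list(n = 0)) |>
    dplyr::group_by(.data$group, .data$subject) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  per_subj |>
    dplyr::group_by(.data$group, .data$category) |>
    dplyr::summarise(mean_pct = mean(.data$pct),
                     sd_pct = stats::sd(.data$pct), .groups = "drop") |>
    dplyr::mutate(category = factor(.data$category, levels = cats)) |>
    dplyr::arrange(.data$group, .data$category)
}

# Group-level statistics of a cohort run.
report_statistics <- function(components, trials, subjects) {
  out <- list()
  # behavioral: Response (correct/early/late) within x Group between
  beh <- trials |>
    dplyr::filter(.data$category != "miss") |>
    dplyr::count(.data$group, .data$subject, .data$category) |>
    dplyr::group_by(.data$group, .data$subject) |>
    tidyr::complete(category = c("correct", "early", "late"),
                    fill = list(n = 0)) |>
    dplyr::ungroup() |>
    dplyr::rename(subject_id = "subject", value = "n",
                  response = "category")
  if (length(unique(beh$group)) >= 2) {
    out$behavior <- mixed_anova(beh, within = "response", between = "group",
                                subject = "subject_id")
  }
  cnv <- components |>
    dplyr::filter(grepl("^cnv_w", .data$component),
                  .data$condition %in% c("correct", "error"))
  if (nrow(cnv) && length(unique(cnv$group)) >= 2 &&
      !anyNA(cnv$value)) {
    out$cnv <- mixed_anova(
      dplyr::rename(cnv, time_window = "component", accuracy = "condition"),
      within = c("time_window", "accuracy"), between = "group")
  }
  frn <- components |>
    dplyr::filter(.data$component == "frn_difference")
  if (nrow(frn) && length(unique(frn$group)) >= 2 && !anyNA(frn$value)) {
    fit <- stats::aov(value ~ group, data = frn)
    tab <- summary(fit)[[1]]
    out$frn <- tibble::tibble(
      effect = "group", df_effect = tab["group", "Df"],
      df_error = tab["Residuals", "Df"],
      F = tab["group", "F value"], p = tab["group", "Pr(>F)"],
      partial_eta_sq = tab["group", "Sum Sq"] /
        (tab["group", "Sum Sq"] + tab["Residuals", "Sum Sq"]))
  }
  out$correlations <- subjects |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3 || stats::sd(d$correct_count) == 0 ||
          stats::sd(d$inattention) == 0) return(tibble::tibble())
      pearson_r(d$correct_count, d$inattention)
    }) |>
    dplyr::ungroup()
  out
}

config_hash <- function(config) rlang::hash(config)

#' Save / load a pipeline configuration as YAML
#' @param config An `erp_pipeline_config`.
#' @param path YAML file path.
#' @return `path` / the restored config.
#' @export
save_pipeline_config <- function(config, path) {
  x <- rapply(unclass(config), identity, how = "list")
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_pipeline_config
#' @export
load_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    sim = do.call(sim_config, x$sim),
    bandpass = x$bandpass,
    analysis_rate = x$analysis_rate,
    criteria = do.call(rejection_criteria, x$criteria),
    spatial = x$spatial,
    csd = do.call(csd_params, x$csd),
    write_edf = isTRUE(x$write_edf)
  )
  cfg
}

#' @export
print.erp_report <- function(x, ...) {
  cat(sprintf("<erp_report> %d subjects, %d groups (hash %s)\n",
              x$provenance$n_subjects,
              length(unique(x$subjects$group)),
              substr(x$provenance$config_hash, 1, 8)))
  print(x$behavior, n = 12)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- report$provenance$config_hash
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", h, " seed: ",
                      report$provenance$master_seed), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  emit(report$behavior, "behavior")
  emit(report$components, "components")
  emit(report$trials, "trials")
  emit(report$rejection, "rejection")
  emit(report$subjects, "subjects")
  if (!is.null(report$stats$behavior)) {
    emit(tidy(report$stats$behavior), "anova_behavior")
  }
  if (!is.null(report$stats$cnv)) emit(tidy(report$stats$cnv), "anova_cnv")
  if (!is.null(report$stats$frn)) emit(report$stats$frn, "anova_frn")
  if (nrow(report$stats$correlations)) {
    emit(report$stats$correlations, "correlations")
  }
  invisible(out_dir)
}

#' Parameter-recovery study over replicate cohorts
#'
#' Generates `n_seeds` independent cohorts of one group under the recovery
#' configuration (identity spatial mode), runs the pipeline on every
#' subject, and returns the per-subject component table with seed and
#' replicate identifiers. Averaging the component values over subjects and
#' replicates estimates the generative targets.
#'
#' @param group Group name.
#' @param n_seeds Number of replicate cohorts (default 10).
#' @param base_seed Integer from which replicate master seeds are derived.
#' @param sim A [sim_config()]; its `master_seed` is overridden per
#'   replicate.
#' @param groups_config Optional function customizing the config.
#' @return Tibble: replicate, subject, group, condition, component, value.
#' @export
recovery_study <- function(group, n_seeds = 10, base_seed = 1,
                           sim = sim_config()) {
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    sim$master_seed <- seed_hash(base_seed, "replicate", s)
    cfg <- recovery_config(sim)
    rep <- run_pipeline(cfg, groups = group)
    dplyr::mutate(rep$components, replicate = s, .before = 1)
  })
}
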