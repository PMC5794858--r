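#' Write a recording to an EDF file
#'
#' Serializes a continuous recording to the classic European Data Format:
#' one-second data records of little-endian 16-bit integers, one signal per
#' channel, with per-channel physical scaling chosen from the data range
#' (quantization error is below 0.02 uV for typical amplitudes). The final
#' partial second is zero-padded. Event markers are not representable in
#' classic EDF; they are written by [write_events()] as a plain-text
#' sidecar, which together with the EDF forms the on-disk exchange format
#' of the pipeline.
#'
#' @param rec An `erp_recording` with an integer sampling rate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(rec$rate == round(rec$rate))
  rate <- as.integer(rec$rate)
  nch <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- ceiling(n / rate)
  pad <- n_rec * rate - n
  pm <- pmax(apply(abs(rec$data), 1, max), 1)
  pm <- signif(pm * 1.0001, 7)  # keep all samples strictly inside range

  fixed <- function(x, width) {
    x <- as.character(x)
    x <- substr(x, 1, width)
    sprintf(paste0("%-", width, "s"), x)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    fixed("0", 8), fixed("synthetic subject", 80),
    fixed("timingerp synthetic recording", 80),
    fixed("01.01.20", 8), fixed("00.00.00", 8),
    fixed(256 * (1 + nch), 8), fixed("", 44),
    fixed(n_rec, 8), fixed(1, 8), fixed(nch, 4)
  )
  field <- function(vals, width) paste(vapply(vals, fixed, "", width),
                                       collapse = "")
  hdr <- paste0(
    hdr,
    field(rec$montage$labels, 16),
    field(rep("AgAgCl electrode", nch), 80),
    field(rep("uV", nch), 8),
    field(sprintf("%.7g", -pm), 8),
    field(sprintf("%.7g", pm), 8),
    field(rep(-32768, nch), 8),
    field(rep(32767, nch), 8),
    field(rep("", nch), 80),
    field(rep(rate, nch), 8),
    field(rep("", nch), 32)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  data <- cbind(rec$data, matrix(0, nch, pad))
  scale <- 65535 / (2 * pm)
  for (r in seq_len(n_rec)) {
    seg <- data[, ((r - 1) * rate + 1):(r * rate), drop = FALSE]
    dig <- round((seg + pm) * scale) - 32768
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file.
#' @param events Optional events tibble (e.g. from [read_events()]);
#'   defaults to an empty table.
#' @param montage Optional montage; reconstructed as the deterministic
#'   equidistant layout of matching size when omitted (labels are taken
#'   from the file).
#' @return An `erp_recording`.
#' @export
read_edf <- function(path, events = NULL, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  stopifnot(length(unique(spr)) == 1)
  rate <- spr[1] / dur
  data <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = nch * spr[1], size = 2,
                   endian = "little")
    seg <- matrix(raw, nrow = spr[1], ncol = nch)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t((seg - rep(dmin, each = spr[1])) *
                       rep((pmax_ - pmin_) / (dmax - dmin), each = spr[1]) +
                       rep(pmin_, each = spr[1]))
  }
  if (is.null(montage)) {
    montage <- make_equidistant_montage(nch)
    montage$labels <- labels
  }
  if (is.null(events)) {
    events <- tibble::tibble(onset_sample = integer(), kind = character(),
                             trial_index = integer())
  }
  new_recording(data, rate, events, montage)
}

#' Write / read the event sidecar of a recording
#' @param rec An `erp_recording`.
#' @param path CSV path.
#' @return `path` / the events tibble.
#' @export
write_events <- function(rec, path) {
  utils::write.csv(rec$events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Export a cohort to disk (EDF + events per subject, cohort CSV)
#'
#' @param cohort An `erp_cohort` generated with `eeg = TRUE`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$records)) {
    rec <- cohort$records[[sid]]$recording
    if (is.null(rec)) stop("cohort was generated without EEG", call. = FALSE)
    write_edf(rec, file.path(dir, paste0(sid, ".edf")))
    write_events(rec, file.path(dir, paste0(sid, "_events.csv")))
  }
  utils::write.csv(
    cohort$subjects[, c("subject_id", "group", "inattention",
                        "hyperactivity", "impulsivity")],
    file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}
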