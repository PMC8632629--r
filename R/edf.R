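# EDF (European Data Format) 16-bit signal I/O.
# Layout: 256-byte fixed header, 256 bytes per signal of per-signal
# headers, then data records of interleaved little-endian int16 blocks
# (one block of `samples_per_record` values per signal per record).

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 7)
  s <- ifelse(nchar(s) > width, substr(s, 1L, width), s)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Signals are stored as 16-bit integers with per-channel physical
#' scaling (physical unit microvolts), 1-second data records.  The
#' total sample count must be a whole number of records and the rate a
#' whole number of samples per second.  Values are quantized to the
#' channel's physical range over 65535 digital steps; the round-trip
#' error is at most half of one step.
#'
#' @param rec a `szg_recording`.
#' @param path output file path.
#' @param patient_id,recording_id identification strings for the header.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient_id = "X", recording_id = "szgraph") {
  stopifnot(inherits(rec, "szg_recording"))
  rate <- rec$rate
  if (rate != round(rate))
    stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$signals)
  total <- ncol(rec$signals)
  if (total %% rate != 0)
    stop("EDF writer requires a whole number of 1-s records")
  n_rec <- total %/% rate

  # physical range: symmetric per channel, at least +/- 1 uV; integer
  # bounds so the header's ASCII fields carry them exactly
  pmax_ <- ceiling(pmax(apply(abs(rec$signals), 1, max), 1))
  phys_min <- -pmax_
  phys_max <- pmax_
  dig_min <- -32768
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(patient_id, 80),
    edf_pad(recording_id, 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_num(256L * (1L + ns), 8),
    edf_pad("", 44),
    edf_num(n_rec, 8),
    edf_num(1, 8),
    edf_num(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    edf_pad(rec$channel_labels, 16),
    edf_pad(ifelse(rec$channel_kind == "scalp", "AgAgCl electrode",
                   ifelse(rec$channel_kind == "ieeg", "SEEG depth", "none")),
            80),
    edf_pad("uV", 8),
    vapply(phys_min, edf_num, "", width = 8),
    vapply(phys_max, edf_num, "", width = 8),
    edf_pad(dig_min, 8),
    edf_pad(dig_max, 8),
    edf_pad("", 80),
    edf_num(rep(rate, ns), 8),
    edf_pad("", 32))
  for (f in fields) writeChar(paste(rep_len(f, ns), collapse = ""),
                              con, eos = NULL)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round((rec$signals - phys_min) / gain + dig_min)
  dig[dig > dig_max] <- dig_max
  dig[dig < dig_min] <- dig_min
  storage.mode(dig) <- "integer"
  # record-major interleave: record r holds rate samples of each signal
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * rate + 1L):(r * rate)
    block <- t(dig[, cols, drop = FALSE])   # samples x channels
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return A `szg_recording`.  Channel kind is inferred from the roster:
#'   labels in the standard scalp roster are `scalp`, identically-zero
#'   non-scalp channels are `padded`, all others `ieeg`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # physical dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)            # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader requires a common sampling rate across signals")
  rate <- spr[1] / rec_dur
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    sig[, cols] <- t((block - matrix(dig_min, spr[1], ns, byrow = TRUE)) *
                       matrix(gain, spr[1], ns, byrow = TRUE) +
                       matrix(phys_min, spr[1], ns, byrow = TRUE))
  }
  kind <- ifelse(labels %in% scalp_channels(), "scalp", "ieeg")
  zero <- apply(sig == 0, 1, all)
  kind[kind == "ieeg" & zero] <- "padded"
  recording(sig, rate, labels, kind)
}

#' Read a recording with its annotation sidecar
#'
#' Signals are returned unfiltered, in microvolts; annotations are
#' validated against their invariants and the recording duration.
#'
#' @param path EDF file path.
#' @param sidecar JSON annotation sidecar path.
#' @return List with `recording` (`szg_recording`), `annotations` (list
#'   of `szg_annotation`), `patient_id`, `implant_laterality`.
#' @export
read_recording <- function(path, sidecar) {
  rec <- read_edf(path)
  ann <- read_annotations(sidecar)
  anns <- validate_annotations(ann$seizures, duration = duration_s(rec))
  list(recording = rec, annotations = anns,
       patient_id = ann$patient_id,
       implant_laterality = ann$implant_laterality)
}
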