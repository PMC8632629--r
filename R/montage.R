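#' Standard channel rosters
#'
#' The scalp roster is the 19-contact subset of the 10-10 placement
#' system used for long-term monitoring.  The intracranial roster holds
#' 24 depth contacts per hemisphere: 4 contacts in each of six anatomic
#' groups (amygdala, lateral anterior temporal, hippocampus, lateral mid
#' temporal, medial orbitofrontal, lateral frontal).
#'
#' @return Character vector of channel labels.
#' @export
scalp_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8",
    "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

ieeg_groups <- function() c("AM", "ATL", "HIP", "MTL", "OF", "LF")

ieeg_hemisphere_channels <- function(side) {
  prefix <- if (side == "left") "L" else "R"
  unlist(lapply(ieeg_groups(), function(g) paste0(prefix, g, 1:4)))
}

#' Intracranial channel roster
#'
#' 48 slots: 24 per hemisphere.  For unilateral implants the recorded
#' hemisphere occupies slots 1-24 and the non-implanted hemisphere's
#' slots 25-48 are padding placeholders, regardless of side.
#'
#' @param laterality `"bilateral"`, `"unilateral-left"` or
#'   `"unilateral-right"`.
#' @return Character vector of 48 labels, ordered as they appear in the
#'   iEEG view.
#' @export
ieeg_channels <- function(laterality = "bilateral") {
  laterality <- match.arg(laterality,
                          c("bilateral", "unilateral-left", "unilateral-right"))
  switch(laterality,
    "bilateral"        = c(ieeg_hemisphere_channels("left"),
                           ieeg_hemisphere_channels("right")),
    "unilateral-left"  = c(ieeg_hemisphere_channels("left"),
                           ieeg_hemisphere_channels("right")),
    "unilateral-right" = c(ieeg_hemisphere_channels("right"),
                           ieeg_hemisphere_channels("left")))
}

#' Mesial-temporal contact block for one hemisphere
#'
#' The 8 amygdala + hippocampus contacts of a hemisphere; the synthetic
#' generator injects the ictal rhythm there.
#'
#' @param side `"left"` or `"right"`.
#' @return Character vector of 8 labels.
#' @export
mesial_block <- function(side) {
  side <- match.arg(side, c("left", "right"))
  prefix <- if (side == "left") "L" else "R"
  c(paste0(prefix, "AM", 1:4), paste0(prefix, "HIP", 1:4))
}

#' Construct a montage specification
#'
#' A montage view selects and orders channels for analysis: `scalp`
#' (19 contacts), `ieeg` (48 slots), or `combined` (scalp roster then
#' iEEG roster, 67).  For unilateral implants the iEEG view keeps its 48
#' slots; the 24 non-implanted slots are zero-padded.
#'
#' @param view `"scalp"`, `"ieeg"` or `"combined"`.
#' @param laterality implant laterality; one of `"bilateral"`,
#'   `"unilateral-left"`, `"unilateral-right"`.
#' @return A `szg_montage` object with fields `view`, `n_contacts`,
#'   `roster`, `laterality`, and `recorded` (logical per slot).
#' @export
montage_spec <- function(view = c("scalp", "ieeg", "combined"),
                         laterality = "bilateral") {
  view <- match.arg(view)
  laterality <- match.arg(laterality,
                          c("bilateral", "unilateral-left", "unilateral-right"))
  ieeg <- ieeg_channels(laterality)
  ieeg_recorded <- if (laterality == "bilateral") rep(TRUE, 48)
                   else c(rep(TRUE, 24), rep(FALSE, 24))
  roster <- switch(view,
    scalp    = scalp_channels(),
    ieeg     = ieeg,
    combined = c(scalp_channels(), ieeg))
  recorded <- switch(view,
    scalp    = rep(TRUE, 19),
    ieeg     = ieeg_recorded,
    combined = c(rep(TRUE, 19), ieeg_recorded))
  structure(list(view = view,
                 n_contacts = length(roster),
                 roster = roster,
                 laterality = laterality,
                 recorded = recorded),
            class = "szg_montage")
}

#' Construct a Recording
#'
#' @param signals numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz (samples per second per channel).
#' @param channel_labels character vector, one label per row.
#' @param channel_kind `"scalp"`, `"ieeg"` or `"padded"` per channel.
#' @return A `szg_recording` object.
#' @export
recording <- function(signals, rate, channel_labels,
                      channel_kind = rep("scalp", nrow(signals))) {
  signals <- as.matrix(signals)
  stopifnot(is.numeric(signals), length(channel_labels) == nrow(signals),
            length(channel_kind) == nrow(signals), rate > 0)
  if (!all(channel_kind %in% c("scalp", "ieeg", "padded")))
    stop("channel_kind must be scalp, ieeg or padded")
  pad <- channel_kind == "padded"
  if (any(pad) && any(signals[pad, , drop = FALSE] != 0))
    stop("padded channels must be identically zero")
  rownames(signals) <- channel_labels
  structure(list(signals = signals, rate = rate,
                 channel_labels = as.character(channel_labels),
                 channel_kind = channel_kind,
                 recorded = !pad),
            class = "szg_recording")
}

#' @export
print.szg_recording <- function(x, ...) {
  cat(sprintf("<szg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$rate,
              ncol(x$signals) / x$rate))
  kinds <- table(x$channel_kind)
  cat("  channels:", paste(names(kinds), kinds, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `szg_recording`.
#' @export
duration_s <- function(rec) ncol(rec$signals) / rec$rate

#' Restrict / pad a recording to a montage view
#'
#' Selects channels in roster order.  Roster slots flagged unrecorded in
#' the montage (the non-implanted hemisphere of a unilateral study) are
#' filled with zeros and marked `padded`.  Channel order is exactly the
#' roster order, so it is stable across recordings and the operation is
#' idempotent.
#'
#' @param rec a `szg_recording` containing at least the recorded roster
#'   channels.
#' @param spec a `szg_montage`.
#' @return A `szg_recording` with `spec$n_contacts` channels.
#' @export
assemble_montage <- function(rec, spec) {
  stopifnot(inherits(rec, "szg_recording"), inherits(spec, "szg_montage"))
  need <- spec$roster[spec$recorded]
  missing <- setdiff(need, rec$channel_labels)
  if (length(missing) > 0L)
    stop("montage error: required channels absent from recording: ",
         paste(missing, collapse = ", "))
  if (spec$laterality == "bilateral" && spec$view != "scalp") {
    # a bilateral view demands recorded contacts on both sides
    both <- ieeg_channels("bilateral")
    if (!all(both %in% rec$channel_labels) ||
        any(!rec$recorded[match(intersect(both, rec$channel_labels),
                                rec$channel_labels)]))
      stop("montage error: bilateral view requested but iEEG data is not ",
           "bilateral")
  }
  n <- ncol(rec$signals)
  out <- matrix(0, nrow = spec$n_contacts, ncol = n)
  kind <- character(spec$n_contacts)
  for (i in seq_len(spec$n_contacts)) {
    lab <- spec$roster[i]
    if (spec$recorded[i]) {
      j <- match(lab, rec$channel_labels)
      if (!rec$recorded[j])
        stop("montage error: channel ", lab, " present but marked padded")
      out[i, ] <- rec$signals[j, ]
      kind[i] <- if (lab %in% scalp_channels()) "scalp" else "ieeg"
    } else {
      kind[i] <- "padded"
    }
  }
  recording(out, rec$rate, spec$roster, kind)
}
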