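#' Construct a seizure annotation
#'
#' Times are seconds from recording start on the intracranial clock,
#' fractional allowed; intervals are half-open `[onset, offset)`.
#' Seizure onset is defined by the intracranial trace; the scalp
#' expression of the same seizure is described by `scalp_category`:
#' `surface_negative` (no visible scalp correlate), `delayed` (scalp
#' onset lags the intracranial onset by `scalp_onset_s - onset_s`), or
#' `simultaneous`.
#'
#' @param onset_s,offset_s intracranial onset/offset, `offset_s > onset_s`.
#' @param lateralization `"left"` or `"right"` mesial-temporal onset.
#' @param scalp_category `"surface_negative"`, `"delayed"` or
#'   `"simultaneous"`.
#' @param scalp_onset_s scalp onset; required for `delayed`
#'   (`> onset_s`), must equal `onset_s` for `simultaneous`, and must be
#'   absent (`NULL`) for `surface_negative`.
#' @param clinical_type free-text clinical description.
#' @return A `szg_annotation` object.
#' @export
seizure_annotation <- function(onset_s, offset_s, lateralization,
                               scalp_category, scalp_onset_s = NULL,
                               clinical_type = "") {
  lateralization <- match.arg(lateralization, c("left", "right"))
  scalp_category <- match.arg(scalp_category,
                              c("surface_negative", "delayed", "simultaneous"))
  if (!is.numeric(onset_s) || !is.numeric(offset_s) || offset_s <= onset_s)
    stop("validation error: offset_s must be greater than onset_s")
  if (scalp_category == "surface_negative" && !is.null(scalp_onset_s))
    stop("validation error: surface_negative annotations carry no ",
         "scalp_onset_s")
  if (scalp_category == "delayed") {
    if (is.null(scalp_onset_s) || scalp_onset_s <= onset_s)
      stop("validation error: delayed category requires scalp_onset_s > ",
           "onset_s")
  }
  if (scalp_category == "simultaneous") {
    if (is.null(scalp_onset_s)) scalp_onset_s <- onset_s
    if (scalp_onset_s != onset_s)
      stop("validation error: simultaneous category requires scalp_onset_s ",
           "== onset_s")
  }
  structure(list(onset_s = onset_s, offset_s = offset_s,
                 lateralization = lateralization,
                 scalp_category = scalp_category,
                 scalp_onset_s = scalp_onset_s,
                 clinical_type = clinical_type),
            class = "szg_annotation")
}

#' Validate a list of annotations against a recording
#'
#' Checks each annotation's invariants, that all times fall within the
#' recording duration, and that seizure intervals do not overlap.
#'
#' @param annotations list of `szg_annotation`.
#' @param duration recording duration in seconds (optional).
#' @return The (sorted-by-onset) annotation list, invisibly on success.
#' @export
validate_annotations <- function(annotations, duration = NULL) {
  stopifnot(is.list(annotations))
  if (length(annotations) == 0L) return(invisible(annotations))
  if (!all(vapply(annotations, inherits, TRUE, "szg_annotation")))
    stop("validation error: annotations must be szg_annotation objects")
  ons <- vapply(annotations, `[[`, 0, "onset_s")
  offs <- vapply(annotations, `[[`, 0, "offset_s")
  if (!is.null(duration) && (any(ons < 0) || any(offs > duration)))
    stop("validation error: annotation times outside recording duration")
  o <- order(ons)
  annotations <- annotations[o]
  ons <- ons[o]; offs <- offs[o]
  if (length(annotations) > 1L && any(ons[-1] < offs[-length(offs)]))
    stop("validation error: overlapping seizure intervals")
  invisible(annotations)
}

annotation_to_list <- function(a) {
  out <- list(onset_s = a$onset_s, offset_s = a$offset_s,
              lateralization = a$lateralization,
              scalp_category = a$scalp_category,
              clinical_type = a$clinical_type)
  if (!is.null(a$scalp_onset_s)) out$scalp_onset_s <- a$scalp_onset_s
  out
}

#' Write a JSON annotation sidecar
#'
#' One sidecar per EDF file; holds the seizure list plus optional
#' patient metadata (`patient_id`, `implant_laterality`).
#'
#' @param annotations list of `szg_annotation`.
#' @param path output path.
#' @param patient_id optional patient identifier.
#' @param implant_laterality optional implant laterality string.
#' @export
write_annotations <- function(annotations, path, patient_id = NULL,
                              implant_laterality = NULL) {
  validate_annotations(annotations)
  obj <- list(seizures = lapply(annotations, annotation_to_list))
  if (!is.null(patient_id)) obj$patient_id <- patient_id
  if (!is.null(implant_laterality))
    obj$implant_laterality <- implant_laterality
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON annotation sidecar
#'
#' @param path sidecar path.
#' @return List with `seizures` (list of `szg_annotation`),
#'   `patient_id`, `implant_laterality` (either may be `NULL`).
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  anns <- lapply(obj$seizures, function(s) {
    seizure_annotation(onset_s = s$onset_s, offset_s = s$offset_s,
                       lateralization = s$lateralization,
                       scalp_category = s$scalp_category,
                       scalp_onset_s = s$scalp_onset_s,
                       clinical_type = if (is.null(s$clinical_type)) ""
                                       else s$clinical_type)
  })
  anns <- validate_annotations(anns)
  list(seizures = anns,
       patient_id = obj$patient_id,
       implant_laterality = obj$implant_laterality)
}
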