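# Windowing and class extraction.
#
# Recordings are cut into non-overlapping 1-s windows on the integer
# grid (start times 0, 1, 2, ... s).  Windows are labeled non-seizure /
# pre-seizure / seizure from the intracranial onset clock; the
# pre-ictal horizon is the 10 minutes before onset.  Training samples
# are extracted at the fixed class ratio
# non-seizure : pre-seizure : seizure = 4 : 3 : 2.

PREICTAL_HORIZON_S <- 600
POSTICTAL_BUFFER_S <- 600

#' Class level sets
#'
#' The fixed class ordering used everywhere (training targets, reports,
#' argmax tie-breaks): `non_seizure`, `pre_seizure`, then `seizure` for
#' the three-class scheme or `seizure_left`, `seizure_right` for the
#' four-class scheme.
#'
#' @param scheme `"three_class"` or `"four_class"`.
#' @return Character vector of class levels.
#' @export
class_levels <- function(scheme = c("three_class", "four_class")) {
  scheme <- match.arg(scheme)
  if (scheme == "three_class")
    c("non_seizure", "pre_seizure", "seizure")
  else
    c("non_seizure", "pre_seizure", "seizure_left", "seizure_right")
}

#' Label a 1-s window
#'
#' A window `[start, start + 1)` is `seizure` if it intersects any
#' seizure interval `[onset, offset)`; otherwise `pre_seizure` if it
#' intersects any 10-minute pre-ictal horizon `[onset - 600, onset)`;
#' otherwise `non_seizure`.  Under the four-class scheme ictal windows
#' carry the annotation's lateralization (`seizure_left` /
#' `seizure_right`).  The function is pure and vectorized over `starts`.
#'
#' @param starts numeric vector of window start times (s).
#' @param annotations validated list of `szg_annotation`.
#' @param scheme `"three_class"` or `"four_class"`.
#' @param duration recording duration; window ends beyond it raise a
#'   range error (optional).
#' @return Character vector of labels.
#' @export
label_window <- function(starts, annotations,
                         scheme = c("three_class", "four_class"),
                         duration = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(duration) && any(starts + 1 > duration))
    stop("range error: window extends past recording end")
  labs <- rep("non_seizure", length(starts))
  # horizons first, then ictal intervals override
  for (a in annotations) {
    hit <- starts < a$onset_s & (starts + 1) > (a$onset_s - PREICTAL_HORIZON_S)
    labs[hit] <- "pre_seizure"
  }
  for (a in annotations) {
    ict <- starts < a$offset_s & (starts + 1) > a$onset_s
    if (scheme == "three_class") {
      labs[ict] <- "seizure"
    } else {
      labs[ict] <- paste0("seizure_", a$lateralization)
    }
  }
  labs
}

window_grid <- function(duration) seq.int(0L, floor(duration) - 1L)

#' Build a class-extraction plan
#'
#' For each seizure of duration `D` seconds the plan draws
#' `floor(2 D)` non-seizure windows and `floor(1.5 D)` pre-seizure
#' windows (the 4:3:2 ratio against the `D` ictal windows), with the
#' pre-seizure quota capped by the 600-s horizon.  Pre-seizure windows
#' are drawn uniformly at random (seeded) from the seizure's horizon,
#' truncated at an earlier seizure's offset plus the post-ictal buffer;
#' non-seizure windows are drawn uniformly from windows outside all
#' seizures, all horizons, and a 600-s post-ictal buffer after each
#' offset.
#'
#' @param annotations validated list of `szg_annotation`.
#' @param duration recording duration in seconds.
#' @param seed integer seed for the random draws.
#' @param scheme label scheme passed through to the window labels.
#' @param horizon pre-ictal horizon (s).
#' @param postictal_buffer exclusion buffer after each offset (s).
#' @return A `szg_plan`: per-class window start vectors (`non_seizure`,
#'   `pre_seizure`, `seizure`), per-seizure quota table, labels for the
#'   selected windows, and the seed.
#' @export
build_extraction_plan <- function(annotations, duration, seed = 1L,
                                  scheme = c("three_class", "four_class"),
                                  horizon = PREICTAL_HORIZON_S,
                                  postictal_buffer = POSTICTAL_BUFFER_S) {
  scheme <- match.arg(scheme)
  annotations <- validate_annotations(annotations, duration)
  if (length(annotations) == 0L) stop("planning error: no seizures annotated")
  grid <- window_grid(duration)
  labs3 <- label_window(grid, annotations, "three_class")

  in_buffer <- rep(FALSE, length(grid))
  for (a in annotations)
    in_buffer <- in_buffer |
      (grid < a$offset_s + postictal_buffer & grid + 1 > a$offset_s)
  eligible_non <- grid[labs3 == "non_seizure" & !in_buffer]

  seiz_starts <- integer(0)
  pre_starts <- integer(0)
  quota <- data.frame(seizure = integer(0), duration = numeric(0),
                      n_seizure = integer(0), n_pre = integer(0),
                      n_non = integer(0))
  set.seed(as.integer(seed))
  prev_offset <- -Inf
  total_non_quota <- 0L
  for (si in seq_along(annotations)) {
    a <- annotations[[si]]
    D <- a$offset_s - a$onset_s
    s_windows <- grid[grid < a$offset_s & grid + 1 > a$onset_s]
    pre_quota <- min(floor(1.5 * D), horizon)
    non_quota <- floor(2 * D)
    lo <- max(a$onset_s - horizon, prev_offset + postictal_buffer, 0)
    cand_pre <- grid[grid + 1 > lo & grid < a$onset_s &
                       labs3 == "pre_seizure"]
    n_pre <- min(pre_quota, length(cand_pre))
    sel_pre <- sort(sample_int(cand_pre, n_pre))
    seiz_starts <- c(seiz_starts, s_windows)
    pre_starts <- c(pre_starts, sel_pre)
    quota <- rbind(quota, data.frame(seizure = si, duration = D,
                                     n_seizure = length(s_windows),
                                     n_pre = n_pre, n_non = non_quota))
    total_non_quota <- total_non_quota + non_quota
    prev_offset <- a$offset_s
  }
  if (length(eligible_non) < total_non_quota)
    stop(sprintf(paste0("planning error: insufficient eligible non-seizure ",
                        "time: need %d windows, have %d"),
                 total_non_quota, length(eligible_non)))
  non_starts <- sort(sample_int(eligible_non, total_non_quota))

  starts <- c(non_starts, pre_starts, seiz_starts)
  labels <- label_window(starts, annotations, scheme)
  structure(list(non_seizure = non_starts, pre_seizure = pre_starts,
                 seizure = seiz_starts, quota = quota,
                 starts = starts, labels = labels,
                 scheme = scheme, seed = as.integer(seed),
                 horizon = horizon, postictal_buffer = postictal_buffer),
            class = "szg_plan")
}

# sample() without the length-1 surprise
sample_int <- function(x, n) {
  if (n <= 0L) return(x[0])
  x[sample.int(length(x), n)]
}

#' Serialize a plan manifest to JSON
#' @param plan a `szg_plan`.
#' @param path output path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(
    list(seed = plan$seed, scheme = plan$scheme,
         horizon = plan$horizon, postictal_buffer = plan$postictal_buffer,
         non_seizure = plan$non_seizure, pre_seizure = plan$pre_seizure,
         seizure = plan$seizure),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stack consecutive windows into k-second samples
#'
#' Groups windows into non-overlapping runs of `k` consecutive seconds
#' sharing one label; runs mixing labels or shorter than `k` are
#' dropped.
#'
#' @param starts integer window start times.
#' @param labels label per window.
#' @param k samples per stack: 1, 2 or 6.
#' @return Data frame with one row per sample: `start` (first window)
#'   and `label`; attribute `k`.
#' @export
stack_consecutive <- function(starts, labels, k = 1L) {
  stopifnot(k %in% c(1L, 2L, 6L))
  o <- order(starts)
  starts <- starts[o]; labels <- labels[o]
  if (anyDuplicated(starts)) stop("windows must be unique")
  if (k == 1L) {
    out <- data.frame(start = starts, label = labels,
                      stringsAsFactors = FALSE)
    attr(out, "k") <- 1L
    return(out)
  }
  res_start <- integer(0); res_lab <- character(0)
  i <- 1L
  n <- length(starts)
  while (i + k - 1L <= n) {
    ok <- all(diff(starts[i:(i + k - 1L)]) == 1) &&
      length(unique(labels[i:(i + k - 1L)])) == 1L
    if (ok) {
      res_start <- c(res_start, starts[i])
      res_lab <- c(res_lab, labels[i])
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  out <- data.frame(start = res_start, label = res_lab,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- as.integer(k)
  out
}
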