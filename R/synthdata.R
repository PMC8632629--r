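# Synthetic simultaneous scalp + iEEG cohort generator.
#
# Signal model, per channel c and sample t:
#   y_c(t) = sigma_c * ( sqrt(1 - w1_c^2 - w2_c(t)^2) * eps_c(t)
#                        + w1_c * S_bg(t) + w2_c(t) * S_foc(t) )
#            + rhythm_c(t)
# with eps_c unit-variance pink (1/f-band) channel noise and S_bg,
# S_foc independent broadband shared sources, power-normalized per 1-s
# block.  rho is a shared-variance fraction (mixing weight sqrt(rho)):
# fully-weighted channel pairs correlate at rho_state.  S_bg is a
# background source every channel couples to at level rho0 through a
# fixed heterogeneous gain profile.  S_foc is a focal synchronization
# source, lateralized to the onset hemisphere and strongest over the
# mesial-temporal network, that channels couple to only in the
# pre-ictal (rho1) and ictal (rho2) states; focal-network channels also
# carry a state-dependent band-power (amplitude) modulation.  The
# pre-seizure state is thus a change in coupling topography and band
# power, not an eye-visible waveform.  The ictal rhythm is a sinusoid
# with an
# amplitude ramp injected into the mesial-temporal (amygdala +
# hippocampus) contact block of the onset hemisphere.  Scalp channels
# carry lambda-scaled ictal/pre-ictal content (both the focal coupling
# and a lateralized leak of the rhythm); lambda -> 0 yields the
# surface-negative pattern.  For delayed-onset seizures scalp ictal
# content begins at the annotated scalp onset, not the intracranial
# onset.

#' Synthetic-cohort generator configuration
#'
#' @param n_patients number of patients.
#' @param n_unilateral how many of them have unilateral implants
#'   (24 recorded SEEG contacts instead of 48); assigned to the first
#'   patients, implant side = onset side.
#' @param left_fraction probability that a patient's seizures are of
#'   left mesial-temporal onset.
#' @param rate sampling rate in Hz (default 512).
#' @param duration_s recording length per patient (s).
#' @param onset_range integer range (s) for the seizure onset draw;
#'   the default leaves the full 10-min pre-ictal horizon inside the
#'   recording.
#' @param seizure_duration integer range (s) of seizure durations.
#' @param rho length-3 shared-variance (coupling) levels: background
#'   source (all states), focal source in the pre-seizure state, focal
#'   source in the seizure state.  Two channels with full topography
#'   weight correlate at `rho_state`, so the ladder is a correlation
#'   ladder across states; `rho[1] < rho[2] < rho[3]` for learnable
#'   presets.
#' @param coupling_gain_range per-channel gain profile on the coupling
#'   coefficient, spread linearly across each montage block; makes the
#'   connectivity change spatially heterogeneous (as real pre-ictal
#'   synchronization is), so that scale-invariant graph metrics can see
#'   it.
#' @param amp_mod relative amplitude increase of focal-network channels
#'   at full focal coupling (pre-ictal band-power change); channel
#'   amplitude is scaled by `1 + amp_mod * h_c * rho_state` with `h_c`
#'   the focal topography weight.
#' @param lambda scalp leakage in `[0, 1]`; 0 = surface-negative
#'   pattern (no scalp expression of pre-ictal or ictal structure).
#' @param sigma_scalp,sigma_ieeg background amplitude (uV).
#' @param ictal_freq ictal rhythm frequency (Hz).
#' @param ictal_amp rhythm amplitude on the mesial iEEG block (uV).
#' @param scalp_amp rhythm leak amplitude on scalp before the
#'   `lambda` and laterality weighting (uV).
#' @param ramp_s rhythm amplitude ramp length (s).
#' @param category_mix named probabilities for
#'   `surface_negative` / `delayed` / `simultaneous` scalp expression.
#' @param delay_range integer range (s) of scalp-onset delays for the
#'   delayed category.
#' @param seed integer master seed.
#' @return A `szg_config`.
#' @export
generator_config <- function(n_patients = 19L, n_unilateral = 5L,
                             left_fraction = 0.26, rate = 512L,
                             duration_s = 1380L,
                             onset_range = c(610L, 640L),
                             seizure_duration = c(15L, 25L),
                             rho = c(0.1, 0.4, 0.8), lambda = 1,
                             coupling_gain_range = c(0.3, 1),
                             amp_mod = 0.6,
                             sigma_scalp = 20, sigma_ieeg = 50,
                             ictal_freq = 5, ictal_amp = 150,
                             scalp_amp = 40, ramp_s = 5,
                             category_mix = c(surface_negative = 0.34,
                                              delayed = 0.59,
                                              simultaneous = 0.07),
                             delay_range = c(3L, 8L), seed = 1L) {
  stopifnot(length(rho) == 3, lambda >= 0, lambda <= 1,
            n_unilateral <= n_patients, rate == round(rate))
  category_mix <- category_mix / sum(category_mix)
  if (category_mix["delayed"] > 0 && lambda == 0)
    stop("config error: delayed scalp onsets are inconsistent with ",
         "lambda = 0 (no scalp leakage)")
  structure(list(n_patients = as.integer(n_patients),
                 n_unilateral = as.integer(n_unilateral),
                 left_fraction = left_fraction, rate = as.integer(rate),
                 duration_s = as.integer(duration_s),
                 onset_range = as.integer(onset_range),
                 seizure_duration = as.integer(seizure_duration),
                 rho = rho, lambda = lambda,
                 coupling_gain_range = coupling_gain_range,
                 amp_mod = amp_mod,
                 sigma_scalp = sigma_scalp, sigma_ieeg = sigma_ieeg,
                 ictal_freq = ictal_freq, ictal_amp = ictal_amp,
                 scalp_amp = scalp_amp, ramp_s = ramp_s,
                 category_mix = category_mix,
                 delay_range = as.integer(delay_range),
                 seed = as.integer(seed)),
            class = "szg_config")
}

#' Documented generator presets
#'
#' * `strong_separation` - rho = (0.1, 0.4, 0.8), lambda = 1, 512 Hz,
#'   19 patients (5 unilateral); every pipeline stage should recover
#'   the class structure.
#' * `weak` - shallower coupling ladder and a faint rhythm.
#' * `null` - background coupling only (no focal source in any state)
#'   and no ictal rhythm: nothing distinguishes the states;
#'   classifiers should sit at chance.
#' * `surfneg_sweep` - all-surface-negative cohort; carries
#'   `$lambda_grid = c(0, 0.05, 0.1, 0.2)` for leakage sweeps (the
#'   config itself is at the first grid point).
#'
#' @param name preset name.
#' @param seed master seed stored in the config.
#' @return A `szg_config`.
#' @export
szg_preset <- function(name = c("strong_separation", "weak", "null",
                                "surfneg_sweep"), seed = 1L) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown preset; available: strong_separation, ",
                          "weak, null, surfneg_sweep"))
  cfg <- switch(name,
    strong_separation = generator_config(seed = seed),
    weak = generator_config(rho = c(0.1, 0.2, 0.3), lambda = 0.3,
                            ictal_amp = 40, scalp_amp = 10, seed = seed),
    null = generator_config(n_patients = 8L, n_unilateral = 2L,
                            rho = c(0.3, 0, 0), ictal_amp = 0,
                            scalp_amp = 0, amp_mod = 0,
                            category_mix = c(surface_negative = 0,
                                             delayed = 0,
                                             simultaneous = 1),
                            seed = seed),
    surfneg_sweep = {
      c0 <- generator_config(n_patients = 3L, n_unilateral = 0L,
                             lambda = 0,
                             category_mix = c(surface_negative = 1,
                                              delayed = 0,
                                              simultaneous = 0),
                             seed = seed)
      c0$lambda_grid <- c(0, 0.05, 0.1, 0.2)
      c0
    })
  cfg$preset <- name
  cfg
}

# unit-variance 1/f-band noise, n samples x m independent channels
# (autoregressive pink approximation, flat below the EEG band)
pink_noise <- function(n, m) {
  pink_filter(matrix(rnorm(n * m), n, m))
}

# rescale to unit RMS within each block of `rate` samples
block_normalize <- function(x, rate) {
  n_blk <- length(x) %/% rate
  dim(x) <- c(rate, n_blk)
  rms <- sqrt(colMeans(x^2))
  rms[rms == 0] <- 1
  as.vector(x / rep(rms, each = rate))
}

scalp_side_weights <- function(side) {
  labs <- scalp_channels()
  left_lat <- c("F7", "T7", "P7")
  right_lat <- c("F8", "T8", "P8")
  left_all <- c("Fp1", "F7", "F3", "T7", "C3", "P7", "P3", "O1")
  right_all <- c("Fp2", "F4", "F8", "C4", "T8", "P4", "P8", "O2")
  mid <- c("Fz", "Cz", "Pz")
  ipsi_lat <- if (side == "left") left_lat else right_lat
  ipsi <- if (side == "left") left_all else right_all
  w <- rep(0.1, length(labs))
  w[labs %in% mid] <- 0.3
  w[labs %in% ipsi] <- 0.5
  w[labs %in% ipsi_lat] <- 1
  stats::setNames(w, labs)
}

draw_annotations <- function(cfg) {
  onset <- sample(cfg$onset_range[1]:cfg$onset_range[2], 1L)
  D <- sample(cfg$seizure_duration[1]:cfg$seizure_duration[2], 1L)
  side <- if (runif(1) < cfg$left_fraction) "left" else "right"
  cat_ <- sample(names(cfg$category_mix), 1L, prob = cfg$category_mix)
  scalp_onset <- NULL
  if (cat_ == "delayed") {
    dmax <- min(cfg$delay_range[2], D - 1L)
    delay <- sample(cfg$delay_range[1]:max(cfg$delay_range[1], dmax), 1L)
    scalp_onset <- onset + delay
  } else if (cat_ == "simultaneous") {
    scalp_onset <- onset
  }
  list(seizure_annotation(onset, onset + D, side, cat_, scalp_onset,
                          clinical_type = "synthetic"),
       side = side)
}

#' Simulate one patient's recording
#'
#' @param cfg a `szg_config`.
#' @param patient index (1-based) within the cohort; drives the
#'   per-patient seed `cfg$seed * 1000 + patient` and the
#'   unilateral/bilateral assignment.
#' @return List: `recording` (raw `szg_recording` holding only recorded
#'   channels), `annotations`, `patient_id`, `laterality`, `side`.
#' @export
simulate_patient <- function(cfg, patient = 1L) {
  stopifnot(inherits(cfg, "szg_config"))
  set.seed(cfg$seed * 1000L + as.integer(patient))
  drawn <- draw_annotations(cfg)
  ann <- drawn[[1]]
  side <- drawn$side
  unilateral <- patient <= cfg$n_unilateral
  laterality <- if (!unilateral) "bilateral"
                else paste0("unilateral-", side)

  rate <- cfg$rate
  total <- cfg$duration_s * rate
  tm <- (seq_len(total) - 1) / rate

  scalp_labs <- scalp_channels()
  ieeg_labs <- if (unilateral) ieeg_hemisphere_channels(side)
               else ieeg_channels("bilateral")
  labs <- c(scalp_labs, ieeg_labs)
  n_ch <- length(labs)

  # states on the intracranial clock
  state <- rep(1L, total)                       # 1 non, 2 pre, 3 ictal
  state[tm >= ann$onset_s - PREICTAL_HORIZON_S & tm < ann$onset_s] <- 2L
  state[tm >= ann$onset_s & tm < ann$offset_s] <- 3L
  # scalp clock: ictal only from the scalp onset (delayed category);
  # surface-negative seizures use the intracranial onset (their faint
  # leak is what lambda scales)
  scalp_start <- if (ann$scalp_category == "delayed") ann$scalp_onset_s
                 else ann$onset_s
  state_sc <- state
  state_sc[state == 3L & tm < scalp_start] <- 2L

  eps <- pink_noise(total, n_ch)
  # shared sources are broadband (synchronization is wide-band) and
  # power-normalized per 1-s block: the coupling level a window
  # expresses is set by rho, not by the source's random envelope, and a
  # 1-s window carries a full second of effective samples
  s_bg <- block_normalize(rnorm(total), rate)
  s_foc <- block_normalize(rnorm(total), rate)

  # background coupling: fixed per-channel gains spread linearly across
  # the scalp block and each iEEG hemisphere block (heterogeneous
  # interictal synchronization)
  is_scalp <- labs %in% scalp_labs
  gain_profile <- function(nb) seq(cfg$coupling_gain_range[1],
                                   cfg$coupling_gain_range[2],
                                   length.out = nb)
  g <- numeric(n_ch)
  g[is_scalp] <- gain_profile(sum(is_scalp))
  n_ie <- sum(!is_scalp)
  g[!is_scalp] <- if (n_ie == 48L) rep(gain_profile(24L), 2L)
                  else gain_profile(n_ie)
  # focal-source topography: strongest over the onset hemisphere's
  # mesial-temporal network, faint contralaterally
  h <- numeric(n_ch)
  h[is_scalp] <- scalp_side_weights(side)[labs[is_scalp]]
  ipsi_pref <- if (side == "left") "L" else "R"
  ie_labs <- labs[!is_scalp]
  h_ie <- ifelse(ie_labs %in% mesial_block(side), 1,
                 ifelse(startsWith(ie_labs, ipsi_pref), 0.15, 0.1))
  h[!is_scalp] <- h_ie
  # per-state focal coupling strengths (scalp leakage scales them).
  # rho is the shared-variance fraction: two fully-weighted channels
  # correlate at rho_state, so the preset ladder is a correlation
  # ladder across states
  foc <- c(0, sqrt(cfg$rho[2]), sqrt(cfg$rho[3]))
  # mixing coefficients take one of three values per channel (one per
  # state): mix via per-state lookup tables
  sig <- matrix(0, n_ch, total)
  for (i in seq_len(n_ch)) {
    leak <- if (is_scalp[i]) cfg$lambda else 1
    w1 <- g[i] * sqrt(cfg$rho[1])
    w2tab <- h[i] * foc * leak
    # focal-network band-power change: amplitude rises with the focal
    # coupling level
    amptab <- 1 + cfg$amp_mod * h[i] * foc * leak
    st <- if (is_scalp[i]) state_sc else state
    sigma <- if (is_scalp[i]) cfg$sigma_scalp else cfg$sigma_ieeg
    sig[i, ] <- (sigma * amptab[st]) *
      (sqrt(1 - w1^2 - w2tab^2)[st] * eps[, i] +
         w1 * s_bg + w2tab[st] * s_foc)
  }

  # ictal rhythm: mesial block of the onset hemisphere
  if (cfg$ictal_amp > 0) {
    ict <- tm >= ann$onset_s & tm < ann$offset_s
    ramp <- pmin(1, (tm[ict] - ann$onset_s) / cfg$ramp_s)
    wave <- sin(2 * pi * cfg$ictal_freq * (tm[ict] - ann$onset_s))
    mes <- mesial_block(side)
    for (lab in intersect(mes, labs)) {
      i <- match(lab, labs)
      sig[i, ict] <- sig[i, ict] + cfg$ictal_amp * ramp * wave
    }
  }
  if (cfg$scalp_amp > 0 && cfg$lambda > 0) {
    ict_sc <- tm >= scalp_start & tm < ann$offset_s
    if (any(ict_sc)) {
      ramp <- pmin(1, (tm[ict_sc] - scalp_start) / cfg$ramp_s)
      wave <- sin(2 * pi * cfg$ictal_freq * (tm[ict_sc] - scalp_start))
      lw <- scalp_side_weights(side)
      for (lab in scalp_labs) {
        i <- match(lab, labs)
        sig[i, ict_sc] <- sig[i, ict_sc] +
          cfg$lambda * lw[lab] * cfg$scalp_amp * ramp * wave
      }
    }
  }

  rec <- recording(sig, rate, labs,
                   ifelse(labs %in% scalp_labs, "scalp", "ieeg"))
  list(recording = rec, annotations = list(ann),
       patient_id = sprintf("P%02d", patient),
       laterality = laterality, side = side)
}

#' Simulate a cohort in memory
#'
#' Deterministic given the config seed.
#'
#' @param cfg a `szg_config`.
#' @return List of patient objects (see [simulate_patient()]).
#' @export
simulate_cohort <- function(cfg) {
  lapply(seq_len(cfg$n_patients), function(i) simulate_patient(cfg, i))
}

#' Generate a cohort on disk as EDF + JSON sidecar pairs
#'
#' @param cfg a `szg_config`.
#' @param out_dir output directory (created if needed).
#' @return Data frame with `patient_id`, `edf`, `sidecar`, `laterality`.
#' @export
generate_cohort <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(cfg$n_patients), function(i) {
    p <- simulate_patient(cfg, i)
    edf <- file.path(out_dir, paste0(p$patient_id, ".edf"))
    sidecar <- file.path(out_dir, paste0(p$patient_id, ".json"))
    write_edf(p$recording, edf, patient_id = p$patient_id)
    write_annotations(p$annotations, sidecar, patient_id = p$patient_id,
                      implant_laterality = p$laterality)
    data.frame(patient_id = p$patient_id, edf = edf, sidecar = sidecar,
               laterality = p$laterality, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a labeled graph dataset from a cohort
#'
#' Runs the full pipeline per patient: montage assembly for the chosen
#' view, 4:3:2 class extraction, `k`-window stacking, similarity-graph
#' computation and vectorization.
#'
#' @param cohort list of patient objects from [simulate_cohort()] (or
#'   equivalent structures built from [read_recording()] output).
#' @param view `"scalp"`, `"ieeg"` or `"combined"`.
#' @param metric `"corr"`, `"mi"` or `"waxman"`.
#' @param scheme `"three_class"` or `"four_class"`.
#' @param k windows per sample (1, 2 or 6).
#' @param seed seed for the extraction plans (per-patient offsets are
#'   added).
#' @param n_bins histogram bins for the `mi` metric.
#' @return List: `x` (N x k*n^2 matrix), `y` (labels), `meta` (data
#'   frame: patient, start, label, state, side, scalp_category,
#'   scalp_onset_s), `k`, `view`, `metric`, `input_dim`.
#' @export
build_dataset <- function(cohort, view = "ieeg", metric = "waxman",
                          scheme = "three_class", k = 1L, seed = 1L,
                          n_bins = 16L) {
  xs <- list(); metas <- list()
  for (pi in seq_along(cohort)) {
    r <- patient_dataset(cohort[[pi]], pi, view, metric, scheme, k,
                         seed, n_bins)
    if (!is.null(r)) {
      xs[[length(xs) + 1L]] <- r$x
      metas[[length(metas) + 1L]] <- r$meta
    }
  }
  meta <- do.call(rbind, metas)
  list(x = do.call(rbind, xs), y = meta$label, meta = meta,
       k = as.integer(k), view = view, metric = metric,
       input_dim = (montage_spec(view)$n_contacts)^2)
}

#' Simulate a cohort and build its dataset one patient at a time
#'
#' Streaming equivalent of [simulate_cohort()] followed by
#' [build_dataset()]: each patient's signals are discarded as soon as
#' their selected windows are converted to graph vectors, so cohorts at
#' full sampling rate fit comfortably in memory.
#'
#' @inheritParams build_dataset
#' @param cfg a `szg_config`.
#' @return As [build_dataset()].
#' @export
simulate_dataset <- function(cfg, view = "ieeg", metric = "waxman",
                             scheme = "three_class", k = 1L, seed = 1L,
                             n_bins = 16L) {
  xs <- list(); metas <- list()
  for (pi in seq_len(cfg$n_patients)) {
    p <- simulate_patient(cfg, pi)
    r <- patient_dataset(p, pi, view, metric, scheme, k, seed, n_bins)
    rm(p)
    if (!is.null(r)) {
      xs[[length(xs) + 1L]] <- r$x
      metas[[length(metas) + 1L]] <- r$meta
    }
  }
  meta <- do.call(rbind, metas)
  list(x = do.call(rbind, xs), y = meta$label, meta = meta,
       k = as.integer(k), view = view, metric = metric,
       input_dim = (montage_spec(view)$n_contacts)^2)
}

#' Simulate a cohort once and build several datasets from it
#'
#' Like [simulate_dataset()], but each patient's signals are converted
#' to graph vectors for several (view, metric, scheme, k) requests
#' before being discarded, so one cohort simulation serves several
#' datasets.
#'
#' @param cfg a `szg_config`.
#' @param requests named list; each element a list with fields `view`,
#'   `metric`, and optionally `scheme` (default three_class), `k`
#'   (default 1) and `n_bins`.
#' @param seed extraction-plan seed (per-patient offsets are added).
#' @return Named list of datasets, one per request, each as
#'   [build_dataset()].
#' @export
simulate_datasets <- function(cfg, requests, seed = 1L) {
  acc <- lapply(requests, function(r) list(xs = list(), metas = list()))
  for (pi in seq_len(cfg$n_patients)) {
    p <- simulate_patient(cfg, pi)
    for (ri in seq_along(requests)) {
      rq <- requests[[ri]]
      r <- patient_dataset(p, pi, rq$view, rq$metric,
                           rq$scheme %||% "three_class",
                           rq$k %||% 1L, seed, rq$n_bins %||% 16L)
      if (!is.null(r)) {
        acc[[ri]]$xs[[length(acc[[ri]]$xs) + 1L]] <- r$x
        acc[[ri]]$metas[[length(acc[[ri]]$metas) + 1L]] <- r$meta
      }
    }
    rm(p)
  }
  out <- lapply(seq_along(requests), function(ri) {
    rq <- requests[[ri]]
    meta <- do.call(rbind, acc[[ri]]$metas)
    list(x = do.call(rbind, acc[[ri]]$xs), y = meta$label, meta = meta,
         k = as.integer(rq$k %||% 1L), view = rq$view,
         metric = rq$metric,
         input_dim = (montage_spec(rq$view)$n_contacts)^2)
  })
  names(out) <- names(requests)
  out
}

# one patient's share of a dataset: montage view, extraction plan,
# k-stacking, graph vectors, per-window metadata
patient_dataset <- function(p, pi, view, metric, scheme, k, seed,
                            n_bins) {
  {
    spec_m <- montage_spec(view, p$laterality)
    mrec <- assemble_montage(p$recording, spec_m)
    dur <- duration_s(mrec)
    plan <- build_extraction_plan(p$annotations, dur,
                                  seed = seed + pi, scheme = scheme)
    st <- stack_consecutive(plan$starts, plan$labels, k)
    if (nrow(st) == 0L) return(NULL)
    n2 <- spec_m$n_contacts^2
    xmat <- matrix(0, nrow(st), k * n2)
    for (si in seq_len(nrow(st))) {
      for (j in seq_len(k)) {
        g <- window_graph(mrec, st$start[si] + (j - 1L), metric,
                          n_bins = n_bins)
        xmat[si, ((j - 1L) * n2 + 1L):(j * n2)] <- vectorize_graph(g)
      }
    }
    state3 <- label_window(st$start, p$annotations, "three_class")
    # attribute each window to its owning seizure (ictal interval
    # first, then pre-ictal horizon, else the nearest following one)
    owner <- vapply(st$start, function(s) {
      for (ai in seq_along(p$annotations)) {
        a <- p$annotations[[ai]]
        if (s < a$offset_s && s + 1 > a$onset_s) return(ai)
      }
      for (ai in seq_along(p$annotations)) {
        a <- p$annotations[[ai]]
        if (s < a$onset_s && s + 1 > a$onset_s - PREICTAL_HORIZON_S)
          return(ai)
      }
      1L
    }, 1L)
    own <- p$annotations[owner]
    meta <- data.frame(
      patient = p$patient_id, start = st$start, label = st$label,
      state = state3,
      side = vapply(own, `[[`, "", "lateralization"),
      scalp_category = vapply(own, `[[`, "", "scalp_category"),
      scalp_onset_s = vapply(own, function(a)
        a$scalp_onset_s %||% NA_real_, 0),
      onset_s = vapply(own, `[[`, 0, "onset_s"),
      stringsAsFactors = FALSE)
    list(x = xmat, meta = meta)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
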