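test_that("presets are the documented parameter bundles", {
  st <- szg_preset("strong_separation")
  expect_equal(st$rho, c(0.1, 0.4, 0.8))
  expect_equal(st$lambda, 1)
  expect_equal(st$rate, 512L)
  expect_equal(st$n_patients, 19L)
  expect_equal(st$n_unilateral, 5L)
  nu <- szg_preset("null")
  expect_equal(nu$rho[2:3], c(0, 0))
  expect_equal(nu$ictal_amp, 0)
  sw <- szg_preset("surfneg_sweep")
  expect_equal(sw$lambda_grid, c(0, 0.05, 0.1, 0.2))
  expect_error(szg_preset("nope"), "available")
})

test_that("inconsistent configs are rejected", {
  expect_error(generator_config(lambda = 0,
                                category_mix = c(surface_negative = 0,
                                                 delayed = 1,
                                                 simultaneous = 0)),
               "config error")
})

test_that("generation is deterministic given the seed", {
  cfg <- tiny_config(duration_s = 700L)
  a <- simulate_patient(cfg, 2)
  b <- simulate_patient(cfg, 2)
  expect_identical(a$recording$signals, b$recording$signals)
  expect_identical(a$annotations, b$annotations)
  cfg2 <- tiny_config(duration_s = 700L)
  cfg2$seed <- 6L
  c_ <- simulate_patient(cfg2, 2)
  expect_false(identical(a$recording$signals, c_$recording$signals))
  # cohort files: byte-identical sidecars on regeneration
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  small <- tiny_config(n_patients = 1L, n_unilateral = 0L,
                       duration_s = 700L)
  f1 <- generate_cohort(small, d1)
  f2 <- generate_cohort(small, d2)
  expect_identical(readLines(f1$sidecar[1]), readLines(f2$sidecar[1]))
  expect_identical(readBin(f1$edf[1], "raw", 1e6),
                   readBin(f2$edf[1], "raw", 1e6))
})

test_that("unilateral patients get 24 recorded contacts, bilateral 48", {
  cfg <- tiny_config(duration_s = 700L)
  uni <- simulate_patient(cfg, 1)
  bil <- simulate_patient(cfg, 2)
  expect_equal(sum(uni$recording$channel_kind == "ieeg"), 24)
  expect_equal(sum(bil$recording$channel_kind == "ieeg"), 48)
  expect_match(uni$laterality, "unilateral")
  expect_equal(bil$laterality, "bilateral")
  # EDF + sidecar pairs come out one per patient
  dir <- withr::local_tempdir()
  files <- generate_cohort(tiny_config(duration_s = 700L), dir)
  expect_equal(nrow(files), 2)
  expect_true(all(file.exists(files$edf), file.exists(files$sidecar)))
})

test_that("the ictal rhythm lateralizes to the annotated hemisphere", {
  cfg <- tiny_config(n_patients = 6L, n_unilateral = 0L,
                     duration_s = 700L)
  for (i in 2:5) {
    p <- simulate_patient(cfg, i)
    a <- p$annotations[[1]]
    rec <- p$recording
    ict <- seq.int(floor(a$onset_s * rec$rate) + 1,
                   floor(a$offset_s * rec$rate))
    ipsi <- mesial_block(a$lateralization)
    contra <- mesial_block(setdiff(c("left", "right"), a$lateralization))
    pw <- function(chs) mean(rec$signals[match(chs, rec$channel_labels),
                                         ict]^2)
    expect_gt(pw(ipsi), 2 * pw(contra))
  }
})

test_that("delayed seizures keep scalp ictal content off until scalp onset", {
  cfg <- tiny_config(n_patients = 12L, n_unilateral = 0L,
                     duration_s = 700L,
                     category_mix = c(surface_negative = 0, delayed = 1,
                                      simultaneous = 0))
  found <- FALSE
  for (i in 2:12) {
    p <- simulate_patient(cfg, i)
    a <- p$annotations[[1]]
    if (a$scalp_category != "delayed") next
    found <- TRUE
    rec <- p$recording
    scalp_idx <- which(rec$channel_kind == "scalp")
    # strongest-leak channel: ipsilateral temporal chain
    lead <- if (a$lateralization == "left") "T7" else "T8"
    ch <- match(lead, rec$channel_labels)
    seg <- function(t0, t1)
      rec$signals[ch, (floor(t0 * rec$rate) + 1):floor(t1 * rec$rate)]
    # the pre-scalp-onset ictal portion looks like pre-seizure scalp,
    # the post-onset portion carries the rhythm
    pre_part <- seg(a$onset_s, a$scalp_onset_s)
    post_part <- seg(a$scalp_onset_s, a$offset_s)
    expect_gt(mean(post_part^2), 1.5 * mean(pre_part^2))
  }
  expect_true(found)
})

test_that("zero scalp leakage leaves ictal scalp graphs at baseline", {
  cfg <- tiny_config(n_patients = 1L, n_unilateral = 0L,
                     duration_s = 700L, lambda = 0,
                     category_mix = c(surface_negative = 1, delayed = 0,
                                      simultaneous = 0))
  p <- simulate_patient(cfg, 1)
  a <- p$annotations[[1]]
  ms <- assemble_montage(p$recording, montage_spec("scalp"))
  edge_mean <- function(starts) {
    vapply(starts, function(s) {
      g <- window_graph(ms, s, "corr")$adjacency
      mean(abs(g[upper.tri(g)]))
    }, 0)
  }
  ictal <- edge_mean(seq(a$onset_s, a$offset_s - 1))
  baseline <- edge_mean(0:29)
  # ictal scalp connectivity within 2 sd of the non-seizure baseline
  expect_lt(abs(mean(ictal) - mean(baseline)), 2 * sd(baseline))
})
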