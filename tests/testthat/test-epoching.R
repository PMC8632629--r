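test_that("window labels follow the ictal interval and 10-min horizon", {
  ann <- list(make_ann(onset = 700, dur = 60))
  # boundary cases around the horizon and the ictal interval
  expect_equal(label_window(699, ann), "pre_seizure")
  expect_equal(label_window(99, ann), "non_seizure")   # onset - 601
  expect_equal(label_window(100, ann), "pre_seizure")  # onset - 600
  expect_equal(label_window(700, ann), "seizure")
  expect_equal(label_window(759, ann), "seizure")
  expect_equal(label_window(760, ann), "non_seizure")  # [onset, offset) ends
  # partial ictal overlap counts as seizure
  ann2 <- list(make_ann(onset = 700.5, dur = 10))
  expect_equal(label_window(700, ann2), "seizure")
  # four-class carries lateralization
  annL <- list(make_ann(onset = 700, dur = 60, side = "left"))
  expect_equal(label_window(705, annL, "four_class"), "seizure_left")
  expect_equal(label_window(705, ann, "four_class"), "seizure_right")
  # past recording end is a range error
  expect_error(label_window(1000, ann, duration = 900), "range error")
})

test_that("label_window is pure and order-independent", {
  anns <- list(make_ann(onset = 700, dur = 30),
               make_ann(onset = 2000, dur = 40, side = "left"))
  starts <- c(0, 150, 699, 705, 1500, 1995, 2030)
  a <- label_window(starts, anns)
  b <- label_window(rev(starts), rev(anns))
  expect_equal(a, rev(b))
  expect_equal(a, label_window(starts, anns))
})

test_that("extraction quotas follow the 4:3:2 rule", {
  # 60-s seizure: 120 s non-seizure, 90 s pre-seizure
  plan <- build_extraction_plan(list(make_ann(onset = 700, dur = 60)),
                                duration = 2000, seed = 1)
  expect_length(plan$non_seizure, 120)
  expect_length(plan$pre_seizure, 90)
  expect_length(plan$seizure, 60)
  # 4-s seizure: 8 / 6 / 4
  plan4 <- build_extraction_plan(list(make_ann(onset = 700, dur = 4)),
                                 duration = 2000, seed = 1)
  expect_length(plan4$non_seizure, 8)
  expect_length(plan4$pre_seizure, 6)
  expect_length(plan4$seizure, 4)
  # 500-s seizure: pre-seizure quota capped by the 600-s horizon
  plan500 <- build_extraction_plan(list(make_ann(onset = 700, dur = 500)),
                                   duration = 4000, seed = 1)
  expect_length(plan500$pre_seizure, 600)
  expect_length(plan500$non_seizure, 1000)
})

test_that("plans never sample excluded non-seizure time", {
  set.seed(99)
  for (trial in 1:20) {
    n_seiz <- sample(1:3, 1)
    onsets <- sort(sample(seq(700, 6000, by = 1400), n_seiz))
    durs <- sample(10:80, n_seiz, replace = TRUE)
    anns <- lapply(seq_len(n_seiz), function(i)
      make_ann(onset = onsets[i], dur = durs[i]))
    plan <- build_extraction_plan(anns, duration = 8000,
                                  seed = 100 + trial)
    for (a in anns) {
      # no selected non-seizure window touches the seizure, its horizon,
      # or the post-ictal buffer
      bad <- plan$non_seizure + 1 > a$onset_s - 600 &
        plan$non_seizure < a$offset_s + 600
      expect_false(any(bad))
      # pre-seizure windows sit inside a horizon
      expect_true(all(plan$labels[match(plan$pre_seizure, plan$starts)] ==
                        "pre_seizure"))
    }
    # quota arithmetic holds per seizure
    expect_equal(plan$quota$n_non, floor(2 * plan$quota$duration))
  }
})

test_that("planning errors are informative", {
  # recording too short to fill the non-seizure quota
  expect_error(
    build_extraction_plan(list(make_ann(onset = 650, dur = 60)),
                          duration = 1320, seed = 1),
    "insufficient eligible non-seizure")
  expect_error(build_extraction_plan(list(), duration = 1000, seed = 1),
               "no seizures")
})

test_that("plans are reproducible under a seed", {
  anns <- list(make_ann(onset = 700, dur = 30))
  p1 <- build_extraction_plan(anns, 2500, seed = 7)
  p2 <- build_extraction_plan(anns, 2500, seed = 7)
  p3 <- build_extraction_plan(anns, 2500, seed = 8)
  expect_identical(p1$non_seizure, p2$non_seizure)
  expect_identical(p1$pre_seizure, p2$pre_seizure)
  expect_false(identical(p1$non_seizure, p3$non_seizure))
  # manifest round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(p1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$seed, 7)
  expect_equal(back$non_seizure, p1$non_seizure)
})

test_that("stack_consecutive groups uniform-label runs and drops the rest", {
  # 60 consecutive seizure windows at k = 6 -> 10 samples
  st <- stack_consecutive(0:59, rep("seizure", 60), k = 6)
  expect_equal(nrow(st), 10)
  expect_equal(st$start, seq(0, 54, by = 6))
  # shorter than k -> none
  expect_equal(nrow(stack_consecutive(0:4, rep("seizure", 5), k = 6)), 0)
  # a label boundary drops the straddling sample
  labs <- c(rep("pre_seizure", 3), rep("seizure", 3))
  st2 <- stack_consecutive(0:5, labs, k = 2)
  expect_equal(st2$start, c(0, 3))
  expect_equal(st2$label, c("pre_seizure", "seizure"))
  # non-contiguous windows cannot stack
  st3 <- stack_consecutive(c(0, 2, 4), rep("seizure", 3), k = 2)
  expect_equal(nrow(st3), 0)
})
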