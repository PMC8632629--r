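make_blobs <- function(n = 120, d = 36, classes = class_levels(), sep = 1,
                       seed = 1, k = 1) {
  set.seed(seed)
  y <- sample(classes, n, replace = TRUE)
  mu <- matrix(rnorm(length(classes) * d * k), length(classes))
  rownames(mu) <- classes
  x <- mu[y, , drop = FALSE] * sep + 0.4 * matrix(rnorm(n * d * k), n)
  list(x = x, y = y)
}

test_that("classifier specs enforce the family/k contract", {
  expect_error(classifier_spec("shallow", k = 2, input_dim = 361),
               "shallow")
  expect_error(classifier_spec("cnn", k = 3, input_dim = 361), "k must")
  expect_error(classifier_spec("lstm", k = 1, n_classes = 5,
                               input_dim = 361), "n_classes")
  expect_error(classifier_spec("lstm", k = 1, input_dim = 361,
                               matrix_mode = TRUE), "matrix_mode")
  # learning-rate defaults per family
  expect_equal(classifier_spec("cnn", input_dim = 361)$lr, 5e-4)
  expect_equal(classifier_spec("lstm", input_dim = 361)$lr, 1e-3)
})

test_that("built classifiers have the right input/output geometry", {
  for (cs in list(classifier_spec("cnn", 1, 3, 361),
                  classifier_spec("cnn", 2, 4, 2304),
                  classifier_spec("lstm", 6, 3, 4489,
                                  lstm_hidden = 16L),
                  classifier_spec("shallow", 1, 3, 361))) {
    clf <- build_classifier(cs)
    last <- clf$layers[[length(clf$layers)]]
    expect_equal(ncol(last$W), cs$n_classes)
  }
})

test_that("gradients agree with finite differences for every family", {
  specs <- list(
    classifier_spec("shallow", 1, 3, 20, seed = 3, hidden = 8L),
    classifier_spec("cnn", 2, 3, 30, seed = 4, conv_filters = c(4L, 6L),
                    dense_units = 8L),
    classifier_spec("cnn", 1, 4, 144, seed = 5, matrix_mode = TRUE,
                    dense_units = 8L),
    classifier_spec("lstm", 6, 3, 12, seed = 6, lstm_hidden = 9L))
  set.seed(11)
  for (spec in specs) {
    clf <- build_classifier(spec)
    n <- 5
    x <- matrix(rnorm(n * spec$k * spec$input_dim), n)
    y_idx <- sample.int(spec$n_classes, n, replace = TRUE)
    layers <- clf$layers
    shape <- function(l) szgraph:::shape_input(x, 1:n, spec)
    fw <- szgraph:::nn_forward(layers, shape())
    ls <- szgraph:::ce_loss(fw$out, y_idx)
    grads <- szgraph:::nn_backward(layers, fw$caches, ls$dlogits)
    lossfun <- function(layers)
      szgraph:::ce_loss(
        szgraph:::nn_forward(layers, shape(), want_cache = FALSE)$out,
        y_idx)$loss
    for (i in seq_along(layers)) {
      for (pn in szgraph:::layer_params(layers[[i]])) {
        p <- layers[[i]][[pn]]
        for (trial in 1:4) {
          j <- sample.int(length(p), 1)
          eps <- 1e-5
          lp <- layers
          lp[[i]][[pn]][j] <- p[j] + eps
          f1 <- lossfun(lp)
          lp[[i]][[pn]][j] <- p[j] - eps
          f0 <- lossfun(lp)
          num <- (f1 - f0) / (2 * eps)
          expect_lt(abs(num - grads[[i]][[pn]][j]),
                    1e-4 * max(1, abs(num)))
        }
      }
    }
  }
})

test_that("training is deterministic and reports a decreasing loss", {
  blobs <- make_blobs(n = 200, d = 36, seed = 8, sep = 2)
  spec <- classifier_spec("cnn", 1, 3, 36, seed = 2, epochs = 10,
                          batch_size = 32, conv_filters = c(8L, 8L),
                          dense_units = 16L)
  m1 <- train_classifier(spec, blobs$x, blobs$y)
  m2 <- train_classifier(spec, blobs$x, blobs$y)
  expect_identical(m1$manifest, m2$manifest)
  p1 <- predict_classifier(m1, blobs$x)
  p2 <- predict_classifier(m2, blobs$x)
  expect_identical(p1$prob, p2$prob)
  # smoothed early-epoch loss decreases on separable data
  lc <- m1$manifest$loss_curve
  expect_true(all(diff(lc[1:5]) < 0))
  expect_gt(mean(p1$class == blobs$y), 0.95)
})

test_that("training refuses data with an absent class", {
  blobs <- make_blobs(n = 60, d = 25, seed = 9)
  keep <- blobs$y != "pre_seizure"
  spec <- classifier_spec("shallow", 1, 3, 25, seed = 1, epochs = 2)
  expect_error(train_classifier(spec, blobs$x[keep, ], blobs$y[keep]),
               "pre_seizure")
})

test_that("predictions are proper probabilities with stable tie-breaks", {
  blobs <- make_blobs(n = 90, d = 25, seed = 10)
  spec <- classifier_spec("shallow", 1, 3, 25, seed = 1, epochs = 4)
  m <- train_classifier(spec, blobs$x, blobs$y)
  pr <- predict_classifier(m, blobs$x)
  expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-6))
  expect_true(all(pr$prob >= 0))
  # all-zero input (fully padded degenerate window) predicts cleanly
  pz <- predict_classifier(m, matrix(0, 1, 25))
  expect_true(all(is.finite(pz$prob)))
  expect_equal(sum(pz$prob), 1, tolerance = 1e-6)
  # dimension mismatch is an input error
  expect_error(predict_classifier(m, matrix(0, 1, 24)), "input error")
  # argmax ties break toward the earlier class in the fixed ordering
  fake <- m
  expect_equal(m$classes[max.col(matrix(c(0.4, 0.4, 0.2), 1),
                                 ties.method = "first")], "non_seizure")
})

test_that("lstm and matrix-mode cnn train end to end", {
  blobs <- make_blobs(n = 120, d = 16, seed = 12, k = 2, sep = 2)
  spec <- classifier_spec("lstm", 2, 3, 16, seed = 3, epochs = 20,
                          batch_size = 32, lstm_hidden = 12L)
  m <- train_classifier(spec, blobs$x, blobs$y)
  expect_gt(mean(predict_classifier(m, blobs$x)$class == blobs$y), 0.9)

  blobs2 <- make_blobs(n = 120, d = 64, seed = 13, sep = 2)
  spec2 <- classifier_spec("cnn", 1, 3, 64, seed = 3, epochs = 20,
                           batch_size = 32, matrix_mode = TRUE,
                           dense_units = 16L)
  m2 <- train_classifier(spec2, blobs2$x, blobs2$y)
  expect_gt(mean(predict_classifier(m2, blobs2$x)$class == blobs2$y), 0.9)
})
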