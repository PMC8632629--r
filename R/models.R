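#' Specify a classifier
#'
#' Three families over vectorized similarity graphs:
#' * `shallow` - single hidden layer (64 units) on the graph vector;
#'   baseline, valid only at `k = 1`.
#' * `cnn` - two 1-D convolution blocks (32 then 64 filters, kernel 5,
#'   stride 1, ReLU, max-pool 2) over the vector, the `k` graphs of a
#'   sample entering as `k` input channels, then dense 128 and softmax.
#'   With `matrix_mode = TRUE` the raw `n x n` adjacency is convolved
#'   with a single 2-D block (16 filters, 5 x 5, max-pool 2 x 2)
#'   instead; the vector mode is the default.
#' * `lstm` - one recurrent layer (hidden 128) over the length-`k`
#'   sequence of graph vectors, then softmax.
#'
#' Adam learning rates default to 0.0005 for the CNN and 0.001 for the
#' LSTM (and the shallow baseline).
#'
#' @param family `"shallow"`, `"cnn"` or `"lstm"`.
#' @param k consecutive 1-s windows per sample: 1, 2 or 6.
#' @param n_classes 3 (non/pre/seizure) or 4 (seizure split left/right).
#' @param input_dim graph-vector length `n^2` (361, 2304 or 4489 for
#'   the standard views; any square is accepted for `matrix_mode`).
#' @param lr Adam learning rate; `NULL` selects the family default.
#' @param epochs,batch_size training schedule (defaults 50 and 64).
#' @param seed integer seed controlling initialization and batching.
#' @param hidden shallow hidden width.
#' @param conv_filters,kernel CNN stack shape.
#' @param pool_widths max-pool widths after the two conv blocks
#'   (default `c(2, 2)`; a wider first pool trades spatial resolution
#'   for compute on the long iEEG/combined vectors).
#' @param lstm_hidden,dense_units LSTM/CNN head widths.
#' @param matrix_mode CNN only: convolve the n x n matrix in 2-D.
#' @param standardize z-scale each input feature using training-set
#'   statistics (stored with the model and re-applied at prediction
#'   time); similarity-graph edge weights span very different scales
#'   across metrics (Waxman weights are mostly below 1e-2), so this is
#'   on by default.
#' @return A `szg_spec`.
#' @export
classifier_spec <- function(family = c("shallow", "cnn", "lstm"),
                            k = 1L, n_classes = 3L, input_dim,
                            lr = NULL, epochs = 50L, batch_size = 64L,
                            seed = 1L, hidden = 64L,
                            conv_filters = c(32L, 64L), kernel = 5L,
                            pool_widths = c(2L, 2L),
                            lstm_hidden = 128L, dense_units = 128L,
                            matrix_mode = FALSE, standardize = TRUE) {
  family <- match.arg(family)
  if (!k %in% c(1L, 2L, 6L)) stop("spec error: k must be 1, 2 or 6")
  if (family == "shallow" && k != 1L)
    stop("spec error: the shallow baseline is only valid at k = 1")
  if (!n_classes %in% c(3L, 4L))
    stop("spec error: n_classes must be 3 or 4")
  if (matrix_mode && family != "cnn")
    stop("spec error: matrix_mode applies to the cnn family only")
  if (matrix_mode && round(sqrt(input_dim))^2 != input_dim)
    stop("spec error: matrix_mode requires a square input_dim")
  if (is.null(lr)) lr <- if (family == "cnn") 5e-4 else 1e-3
  structure(list(family = family, k = as.integer(k),
                 n_classes = as.integer(n_classes),
                 input_dim = as.integer(input_dim), lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), hidden = as.integer(hidden),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel),
                 pool_widths = as.integer(pool_widths),
                 lstm_hidden = as.integer(lstm_hidden),
                 dense_units = as.integer(dense_units),
                 matrix_mode = isTRUE(matrix_mode),
                 standardize = isTRUE(standardize)),
            class = "szg_spec")
}

conv_out_len <- function(l, kernel, pool = 2L) (l - kernel + 1L) %/% pool

#' Build an untrained classifier from a spec
#'
#' @param spec a `szg_spec`.
#' @return A `szg_classifier` with initialized (seeded) parameters.
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "szg_spec"))
  set.seed(spec$seed)
  D <- spec$input_dim
  layers <- switch(spec$family,
    shallow = list(nn_dense(D, spec$hidden, "relu"),
                   nn_dense(spec$hidden, spec$n_classes, "linear")),
    cnn = if (spec$matrix_mode) {
      n <- as.integer(round(sqrt(D)))
      h1 <- conv_out_len(n, spec$kernel)
      list(nn_conv2d(spec$k, 16L, spec$kernel), nn_pool2d(), nn_flatten(),
           nn_dense(16L * h1 * h1, spec$dense_units, "relu"),
           nn_dense(spec$dense_units, spec$n_classes, "linear"))
    } else {
      l1 <- conv_out_len(D, spec$kernel, spec$pool_widths[1])
      l2 <- conv_out_len(l1, spec$kernel, spec$pool_widths[2])
      list(nn_conv1d(spec$k, spec$conv_filters[1], spec$kernel),
           nn_pool1d(spec$pool_widths[1]),
           nn_conv1d(spec$conv_filters[1], spec$conv_filters[2],
                     spec$kernel), nn_pool1d(spec$pool_widths[2]),
           nn_flatten(),
           nn_dense(spec$conv_filters[2] * l2, spec$dense_units, "relu"),
           nn_dense(spec$dense_units, spec$n_classes, "linear"))
    },
    lstm = list(nn_lstm(D, spec$lstm_hidden),
                nn_dense(spec$lstm_hidden, spec$n_classes, "linear")))
  structure(list(spec = spec, layers = layers, trained = FALSE),
            class = "szg_classifier")
}

# reshape an N x (k*D) sample matrix into the family's input tensor for
# the rows in `idx`
shape_input <- function(x, idx, spec) {
  k <- spec$k; D <- spec$input_dim
  B <- length(idx)
  xb <- x[idx, , drop = FALSE]
  switch(spec$family,
    shallow = xb,
    cnn = if (spec$matrix_mode) {
      n <- as.integer(round(sqrt(D)))
      aperm(array(t(xb), dim = c(n, n, k, B)), c(3L, 2L, 1L, 4L))
    } else {
      # sample rows are k contiguous blocks of length D -> (k, D, B)
      aperm(array(t(xb), dim = c(D, k, B)), c(2L, 1L, 3L))
    },
    lstm = array(t(xb), dim = c(D, k, B)))
}

sample_fingerprint <- function(x, y) {
  c(n = nrow(x), dim = ncol(x), sum = sum(x), sumsq = sum(x^2),
    ysum = sum(as.integer(factor(y))))
}

#' Train a classifier
#'
#' Minibatch Adam on the softmax cross-entropy.  Deterministic given
#' the spec seed: initialization and batch shuffling both derive from
#' it.  Every class of the scheme must be present in `y`.
#'
#' @param clf an untrained `szg_classifier` (or a `szg_spec`).
#' @param x numeric sample matrix, N x (k * input_dim); the `k` graph
#'   vectors of a sample are laid out as consecutive blocks.
#' @param y character labels drawn from [class_levels()].
#' @param verbose print per-epoch loss.
#' @return The trained `szg_classifier`; `$manifest` records the seed,
#'   schedule, per-epoch mean loss and a data fingerprint.
#' @export
train_classifier <- function(clf, x, y, verbose = FALSE) {
  if (inherits(clf, "szg_spec")) clf <- build_classifier(clf)
  stopifnot(inherits(clf, "szg_classifier"))
  spec <- clf$spec
  levels_ <- class_levels(if (spec$n_classes == 3L) "three_class"
                          else "four_class")
  if (ncol(x) != spec$k * spec$input_dim)
    stop("input error: x has ", ncol(x), " columns; spec expects ",
         spec$k * spec$input_dim)
  missing_cls <- setdiff(levels_, unique(y))
  if (length(missing_cls) > 0L)
    stop("training error: class absent from training data: ",
         paste(missing_cls, collapse = ", "))
  if (!all(y %in% levels_))
    stop("training error: labels outside the scheme: ",
         paste(setdiff(unique(y), levels_), collapse = ", "))
  y_idx <- match(y, levels_)
  n <- nrow(x)
  if (spec$standardize) {
    mu <- colMeans(x)
    sdv <- sqrt(colMeans(x^2) - mu^2)
    sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
    clf$norm <- list(mu = mu, sd = sdv)
    x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  }
  set.seed(spec$seed)
  layers <- build_classifier(spec)$layers
  state <- adam_init(layers)
  t_step <- 0L
  losses <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq.int(1L, n, by = spec$batch_size)) {
      idx <- ord[b0:min(b0 + spec$batch_size - 1L, n)]
      xin <- shape_input(x, idx, spec)
      fw <- nn_forward(layers, xin)
      ls <- ce_loss(fw$out, y_idx[idx])
      grads <- nn_backward(layers, fw$caches, ls$dlogits)
      t_step <- t_step + 1L
      upd <- adam_step(layers, grads, state, spec$lr, t_step)
      layers <- upd$layers; state <- upd$state
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
    }
    losses[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %d  loss %.4f", ep, losses[ep]))
  }
  clf$layers <- layers
  clf$trained <- TRUE
  clf$classes <- levels_
  clf$manifest <- list(seed = spec$seed, epochs = spec$epochs,
                       batch_size = spec$batch_size, lr = spec$lr,
                       loss_curve = losses,
                       final_loss = losses[length(losses)],
                       data_fingerprint = sample_fingerprint(x, y))
  clf
}

#' Predict classes and probabilities
#'
#' Softmax probabilities per sample; the predicted class is the argmax,
#' ties broken toward the earlier class in the fixed ordering.
#'
#' @param model a trained `szg_classifier`.
#' @param x sample matrix, N x (k * input_dim).
#' @param batch_size forward-pass batch size.
#' @return List with `class` (character) and `prob` (N x n_classes
#'   matrix, columns named by class).
#' @export
predict_classifier <- function(model, x, batch_size = 256L) {
  stopifnot(inherits(model, "szg_classifier"), isTRUE(model$trained))
  spec <- model$spec
  if (ncol(x) != spec$k * spec$input_dim)
    stop("input error: x has ", ncol(x), " columns; model expects ",
         spec$k * spec$input_dim)
  if (!is.null(model$norm))
    x <- sweep(sweep(x, 2, model$norm$mu, "-"), 2, model$norm$sd, "/")
  n <- nrow(x)
  prob <- matrix(0, n, spec$n_classes)
  for (b0 in seq.int(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    xin <- shape_input(x, idx, spec)
    fw <- nn_forward(model$layers, xin, want_cache = FALSE)
    prob[idx, ] <- softmax(fw$out)
  }
  colnames(prob) <- model$classes
  cls <- model$classes[max.col(prob, ties.method = "first")]
  list(class = cls, prob = prob)
}

#' @export
predict.szg_classifier <- function(object, newdata, ...) {
  predict_classifier(object, newdata, ...)
}

#' @export
print.szg_classifier <- function(x, ...) {
  cat(sprintf("<szg_classifier> %s k=%d classes=%d input=%d %s\n",
              x$spec$family, x$spec$k, x$spec$n_classes, x$spec$input_dim,
              if (isTRUE(x$trained)) "(trained)" else "(untrained)"))
  invisible(x)
}
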