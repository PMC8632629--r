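# Similarity graphs over 1-s EEG windows.
#
# Each window of n channels yields a dense symmetric n x n weighted
# adjacency matrix under one of three pairwise similarity models:
#   corr   - Pearson correlation of the two channels' samples,
#   mi     - plug-in discrete mutual information (bits) over per-channel
#            equal-width histograms,
#   waxman - distance-decay weight beta * exp(-d_ij / (alpha * max d)),
#            with d_ij the Euclidean distance between the two channels'
#            sample vectors and max d the largest off-diagonal distance
#            among recorded channels in the window (beta = 0.4,
#            alpha = 0.1).
# Conventions shared by all metrics: zero diagonal (no self-edges) and
# identically-zero rows/columns for padded or unrecorded contacts.

WAXMAN_BETA <- 0.4
WAXMAN_ALPHA <- 0.1

new_simgraph <- function(adj, metric, recorded) {
  dimnames(adj) <- NULL
  adj[!recorded, ] <- 0
  adj[, !recorded] <- 0
  diag(adj) <- 0
  structure(list(adjacency = adj, metric = metric, recorded = recorded),
            class = "szg_graph")
}

#' @export
print.szg_graph <- function(x, ...) {
  cat(sprintf("<szg_graph> metric=%s n=%d (%d recorded)\n", x$metric,
              nrow(x$adjacency), sum(x$recorded)))
  invisible(x)
}

#' Correlation-coefficient similarity graph
#'
#' Entry (i, j) is the Pearson correlation of channels i and j within
#' the window.  Entries involving a zero-variance, padded, or
#' unrecorded channel are 0; the diagonal is 0.
#'
#' @param x numeric matrix, channels x samples, for one window.
#' @param recorded logical per channel; `FALSE` marks padded slots.
#' @return A `szg_graph` with entries in `[-1, 1]`.
#' @export
corr_graph <- function(x, recorded = rep(TRUE, nrow(x))) {
  stopifnot(ncol(x) >= 2)
  sds <- apply(x, 1, sd)
  a <- suppressWarnings(cor(t(x)))
  a[!is.finite(a)] <- 0
  a[sds == 0, ] <- 0
  a[, sds == 0] <- 0
  new_simgraph(a, "corr", recorded)
}

# equal-width binning of one channel over its per-window range;
# constant channels collapse into a single bin
bin_channel <- function(v, n_bins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  b <- floor((v - r[1]) / (r[2] - r[1]) * n_bins) + 1L
  b[b > n_bins] <- n_bins
  b
}

#' Mutual-information similarity graph
#'
#' Each channel's samples are discretized into `n_bins` equal-width
#' bins over that channel's per-window range; entry (i, j) is the
#' plug-in discrete mutual information of the two binned channels in
#' bits.  Padded-channel entries and the diagonal are 0.
#'
#' @param x numeric matrix, channels x samples.
#' @param recorded logical per channel.
#' @param n_bins number of histogram bins per channel (default 16).
#' @return A `szg_graph` with non-negative entries.
#' @export
mi_graph <- function(x, recorded = rep(TRUE, nrow(x)), n_bins = 16L) {
  n <- nrow(x); m <- ncol(x)
  if (m < n_bins)
    warning("window holds fewer samples than histogram bins")
  bins <- t(apply(x, 1, bin_channel, n_bins = n_bins))
  if (n == 1L) bins <- matrix(bins, nrow = 1L)
  a <- matrix(0, n, n)
  idx <- which(recorded)
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    for (jj in seq_along(idx)) {
      if (jj <= ii) next
      j <- idx[jj]
      a[i, j] <- a[j, i] <- mi_pair(bins[i, ], bins[j, ], n_bins)
    }
  }
  new_simgraph(a, "mi", recorded)
}

# plug-in MI in bits from two binned sequences
mi_pair <- function(bi, bj, n_bins) {
  joint <- tabulate((bi - 1L) * n_bins + bj, nbins = n_bins * n_bins)
  joint <- joint / length(bi)
  pj <- matrix(joint, n_bins, n_bins)      # rows: bj, cols: bi
  pi_ <- colSums(pj)
  pjm <- rowSums(pj)
  nz <- pj > 0
  outer_ <- outer(pjm, pi_)
  sum(pj[nz] * log2(pj[nz] / outer_[nz]))
}

#' Waxman-model similarity graph
#'
#' Entry (i, j) is `beta * exp(-d_ij / (alpha * max_d))` where `d_ij`
#' is the Euclidean (L2) distance between the two channels' sample
#' vectors in the window and `max_d` the maximum off-diagonal distance
#' among recorded channels in the same window.  Identical channels get
#' weight `beta`; the most dissimilar recorded pair gets
#' `beta * exp(-1/alpha)`.  If every recorded pair is identical
#' (`max_d = 0`) the limit convention assigns `beta` to all recorded
#' off-diagonal entries.
#'
#' @param x numeric matrix, channels x samples.
#' @param recorded logical per channel.
#' @param beta,alpha Waxman parameters (defaults 0.4, 0.1).
#' @return A `szg_graph` with entries in `[0, beta]`.
#' @export
waxman_graph <- function(x, recorded = rep(TRUE, nrow(x)),
                         beta = WAXMAN_BETA, alpha = WAXMAN_ALPHA) {
  if (sum(recorded) < 2L)
    stop("waxman graph requires at least two recorded channels")
  d <- as.matrix(dist(x))
  dr <- d[recorded, recorded]
  max_d <- max(dr[row(dr) != col(dr)])
  if (max_d == 0) {
    a <- matrix(beta, nrow(x), nrow(x))
  } else {
    a <- beta * exp(-d / (alpha * max_d))
  }
  new_simgraph(a, "waxman", recorded)
}

#' Compute the similarity graph of one 1-s window of a recording
#'
#' @param rec a `szg_recording` (already assembled to a montage view).
#' @param start_s window start on the integer grid.
#' @param metric `"corr"`, `"mi"` or `"waxman"`.
#' @param n_bins histogram bins for `mi`.
#' @return A `szg_graph`.
#' @export
window_graph <- function(rec, start_s, metric = c("corr", "mi", "waxman"),
                         n_bins = 16L) {
  metric <- match.arg(metric)
  rate <- rec$rate
  i0 <- round(start_s * rate)
  if (i0 + rate > ncol(rec$signals))
    stop("range error: window extends past recording end")
  x <- rec$signals[, (i0 + 1):(i0 + rate), drop = FALSE]
  switch(metric,
         corr = corr_graph(x, rec$recorded),
         mi = mi_graph(x, rec$recorded, n_bins = n_bins),
         waxman = waxman_graph(x, rec$recorded))
}

#' Vectorize a similarity graph
#'
#' Row-major flattening of the adjacency matrix; length `n^2`
#' (361, 2304 and 4489 for the scalp, iEEG and combined views).
#'
#' @param g a `szg_graph` or a plain adjacency matrix.
#' @return Numeric vector of length `n^2`.
#' @export
vectorize_graph <- function(g) {
  a <- if (inherits(g, "szg_graph")) g$adjacency else g
  as.vector(t(a))
}
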