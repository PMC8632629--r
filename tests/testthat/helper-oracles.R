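# Independent oracles: direct covariance formula for the correlation
# graph, exhaustive joint-histogram enumeration for mutual information,
# scalar substitution into the distance-decay formula for Waxman.

oracle_corr <- function(x) {
  n <- nrow(x)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    yi <- x[i, ]; yj <- x[j, ]
    num <- mean((yi - mean(yi)) * (yj - mean(yj)))
    den <- sqrt(mean((yi - mean(yi))^2)) * sqrt(mean((yj - mean(yj))^2))
    a[i, j] <- if (den == 0) 0 else num / den
  }
  a
}

oracle_bin <- function(v, nb) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  pmin(floor((v - r[1]) / (r[2] - r[1]) * nb) + 1L, nb)
}

oracle_mi <- function(x, nb = 16L) {
  n <- nrow(x); m <- ncol(x)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    bi <- oracle_bin(x[i, ], nb); bj <- oracle_bin(x[j, ], nb)
    s <- 0
    for (u in unique(bi)) for (v in unique(bj)) {
      p_uv <- mean(bi == u & bj == v)
      if (p_uv > 0)
        s <- s + p_uv * log2(p_uv / (mean(bi == u) * mean(bj == v)))
    }
    a[i, j] <- s
  }
  a
}

oracle_waxman <- function(x, beta = 0.4, alpha = 0.1) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  mx <- max(d)
  a <- beta * exp(-d / (alpha * mx))
  diag(a) <- 0
  a
}

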