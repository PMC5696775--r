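# Independent brute-force oracles and small fixture builders used across
# the suite. These are deliberately written as naive scalar loops so they
# share no code path with the package implementation.

# random RGB image in [0,1]
rand_img <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3L))
}

# uniform-colour image
flat_img <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3L))
}

rand_mask <- function(h, w, p = 0.5) {
  matrix(runif(h * w) < p, h, w)
}

# per-pixel truth-table segmentation scores
oracle_scores <- function(S, R) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_len(nrow(S))) {
    for (j in seq_len(ncol(S))) {
      if (S[i, j] && R[i, j]) tp <- tp + 1L
      else if (S[i, j] && !R[i, j]) fp <- fp + 1L
      else if (!S[i, j] && R[i, j]) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  nR <- tp + fn
  list(qseg = tp / (tp + fp + fn), sr = tp / nR, es = fp / nR)
}

# exhaustive between-class-variance search over the 256-bin histogram
oracle_otsu <- function(x, n_bins = 256L) {
  x <- as.vector(x)
  lo <- min(x); hi <- max(x)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- integer(n_bins)
  for (v in x) {
    b <- ceiling((v - lo) / (hi - lo) * n_bins)
    if (b < 1L) b <- 1L
    if (b > n_bins) b <- n_bins
    counts[b] <- counts[b] + 1L
  }
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  best_t <- NA_integer_; best_v <- -Inf
  n <- length(x)
  for (t in 1:(n_bins - 1L)) {
    n0 <- sum(counts[1:t]); n1 <- n - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- sum(counts[1:t] * mids[1:t]) / n0
    mu1 <- sum(counts[(t + 1L):n_bins] * mids[(t + 1L):n_bins]) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-15) { best_v <- v; best_t <- t }
  }
  edges[best_t + 1L]
}
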