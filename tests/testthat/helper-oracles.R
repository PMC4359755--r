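# Independent brute-force oracles used to pin down the numerical kernels.

# Reflect an index vector without repeating the edge pixel (1-based).
reflect_index <- function(i, n) {
  ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
}

# O(n * w^2 log w) median filter: explicit per-pixel neighbourhood sort over
# the reflect-padded array.  Deliberately naive and independent of the
# package implementation.
median_filter_oracle <- function(x, w) {
  p <- (w - 1) / 2
  h <- nrow(x)
  wd <- ncol(x)
  out <- matrix(0, h, wd)
  for (r in seq_len(h)) {
    rr <- reflect_index((r - p):(r + p), h)
    for (c in seq_len(wd)) {
      cc <- reflect_index((c - p):(c + p), wd)
      v <- sort(as.numeric(x[rr, cc]))
      out[r, c] <- v[(length(v) + 1) / 2]
    }
  }
  out
}

# round-trip a numeric vector/matrix through IEEE single precision
as_float32 <- function(x) {
  con <- rawConnection(raw(0), "r+")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4)
  seek(con, 0)
  v <- readBin(con, "numeric", n = length(x), size = 4)
  if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
}

# brute-force all-pairs nearest-neighbour MOA prediction with compound
# exclusion, independent of the package implementation
nn_oracle <- function(profiles, metric = "cosine") {
  feats <- grep("^(area_px$|total_|mean_)", names(profiles), value = TRUE)
  x <- as.matrix(profiles[, feats, drop = FALSE])
  tid <- sprintf("%s@%g", profiles$compound, profiles$concentration)
  n <- nrow(x)
  dmat <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (profiles$compound[i] == profiles$compound[j]) next
      dmat[i, j] <- if (metric == "cosine") {
        1 - sum(x[i, ] * x[j, ]) / (sqrt(sum(x[i, ]^2)) * sqrt(sum(x[j, ]^2)))
      } else {
        sqrt(sum((x[i, ] - x[j, ])^2))
      }
    }
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    cand <- which(is.finite(dmat[i, ]))
    best <- cand[order(dmat[i, cand], tid[cand])][1]
    pred[i] <- profiles$moa[best]
  }
  pred
}

# closed-form Welch t-test p-value
welch_p_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}
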