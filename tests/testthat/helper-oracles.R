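# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (double loops, O(windows x bins) sweeps) so they share
# no code path with the package implementation.

acf_oracle <- function(x) {
  n <- length(x)
  xb <- mean(x)
  denom <- sum((x - xb)^2)
  sapply(0:(n - 1), function(k) {
    sum((x[1:(n - k)] - xb) * (x[(1 + k):n] - xb)) / denom
  })
}

# lags -(n-1)..(n-1); convention: lag k correlates x_{t+k} with y_t
ccf_oracle <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  denom <- sqrt(sum((x - xb)^2) * sum((y - yb)^2))
  sapply(-(n - 1):(n - 1), function(k) {
    if (k >= 0) {
      sum((x[(1 + k):n] - xb) * (y[1:(n - k)] - yb)) / denom
    } else {
      sum((x[1:(n + k)] - xb) * (y[(1 - k):n] - yb)) / denom
    }
  })
}

# overlap-weighted average of a piecewise-constant track onto n_bins equal
# bins over (0, L]
condense_oracle <- function(lo, hi, v, L, n_bins) {
  out <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    b0 <- L * (b - 1) / n_bins
    b1 <- L * b / n_bins
    wsum <- 0; wlen <- 0
    for (i in seq_along(v)) {
      ov <- min(hi[i], b1) - max(lo[i], b0)
      if (ov > 0) { wsum <- wsum + ov * v[i]; wlen <- wlen + ov }
    }
    out[b] <- if (wlen > 0) wsum / wlen else NA_real_
  }
  out
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# windows of a track as a partition of (0, L]
track_edges <- function(track) {
  lo <- as.numeric(track$starts) - 1
  hi <- c(lo[-1], track$seq_length)
  hi <- pmin(hi, as.numeric(track$starts) + track$window_size - 1)
  list(lo = lo, hi = hi)
}

# hand-built autocorrelation-style series for peak-rule tests
correlation_series_stub <- function(r) {
  structure(list(kind = "auto", lags = 0:(length(r) - 1L),
                 coefficients = as.numeric(r), N = length(r),
                 confidence_level = 0.999,
                 ci = skewatlas::confidence_interval(length(r), 0.999),
                 bin_width = 1),
            class = "correlation_series")
}

svg_track_groups <- function(doc) {
  xml2::xml_find_all(doc, "//*[local-name()='g'][@class='track']")
}

svg_legend_groups <- function(doc) {
  xml2::xml_find_all(doc, "//*[local-name()='g'][@class='legend']")
}
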