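# Signal analysis of genomic properties: dyadic condensation, maximal-overlap
# discrete wavelet transform (MODWT), lagged correlation statistics.
#
# The MODWT uses the pyramid algorithm with periodic (circular) boundary
# conditions, appropriate for circular chromosomes: at level j,
#   W[j,t] = sum_l h[l]/sqrt(2) * V[j-1, (t - 2^(j-1) l) mod N]
#   V[j,t] = sum_l g[l]/sqrt(2) * V[j-1, (t - 2^(j-1) l) mod N]
# Every coefficient series has length N; the transform conserves energy and
# inverts exactly.

# Unit-energy scaling filters; wavelet filters follow by quadrature
# mirroring h[l] = (-1)^l g[L-1-l].  d4/la8 are the Daubechies
# extremal-phase 4-tap and least-asymmetric 8-tap filters; fk4 is the
# 4-tap Fejer-Korovkin filter.
wavelet_scaling_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  d4 = c(0.4829629131445341, 0.8365163037378079,
         0.2241438680420134, -0.1294095225512604),
  la8 = c(0.0322231006040427, -0.0126039672620378, -0.0992195435768472,
          0.2978577956052774, 0.8037387518059161, 0.4976186676320155,
          -0.0296355276459985, -0.0757657147892733),
  fk4 = c(0.6539275555697651, 0.7532724928394872,
          0.0531792287790598, -0.0461657148152177)
)

wavelet_filter <- function(filter_name) {
  g <- wavelet_scaling_filters[[filter_name]]
  if (is.null(g)) {
    stopf("unsupported wavelet filter '%s'; supported: %s", filter_name,
          paste(names(wavelet_scaling_filters), collapse = ", "))
  }
  L <- length(g)
  h <- (-1)^(seq_len(L) - 1) * rev(g)
  list(g = g, h = h, L = L)
}

#' Condense a property track to a dyadic vector
#'
#' Resamples a windowed property to exactly `2^m` equal-width bins spanning
#' the sequence, by overlap-weighted averaging of the source windows (a
#' piecewise-constant model of the track).  When the track has fewer windows
#' than bins the values are replicated proportionally.  All properties to be
#' cross-correlated must be condensed to the same size.
#'
#' @param track A [property_track()].
#' @param m Dyadic exponent; the vector length is `N = 2^m` (typical
#'   analyses use m between 10 and 15).
#' @return An object of class `condensed_vector` with fields `values`, `m`,
#'   `bin_width` (bp per element), `source` and `seq_length`.
#' @export
condense <- function(track, m) {
  stopifnot(inherits(track, "property_track"))
  if (!is_count(m)) stopf("m must be a positive integer")
  n_bins <- 2L^as.integer(m)
  L <- track$seq_length
  # window extents as a partition of (0, L]: window i covers
  # (starts[i]-1, min(starts[i]+window-1, next start-1, L)]
  lo <- as.numeric(track$starts) - 1
  hi <- c(lo[-1], L)
  hi <- pmin(hi, as.numeric(track$starts) + track$window_size - 1)
  vals <- resample_piecewise(lo, hi, track$values, L, n_bins)
  structure(list(values = vals, m = as.integer(m), bin_width = L / n_bins,
                 source = track$name, seq_length = L),
            class = "condensed_vector")
}

# Overlap-weighted resampling of a piecewise-constant function defined on
# intervals (lo_i, hi_i] with values v_i, onto n_bins equal bins over (0, L].
resample_piecewise <- function(lo, hi, v, L, n_bins) {
  bin_edges <- L * seq.int(0L, n_bins) / n_bins
  cuts <- sort(unique(c(lo, hi, bin_edges)))
  cuts <- cuts[cuts >= 0 & cuts <= L]
  mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
  len <- diff(cuts)
  win_of <- findInterval(mids, lo)           # windows sorted, contiguous
  bin_of <- pmin(findInterval(mids, bin_edges), n_bins)
  keep <- win_of >= 1L & mids <= hi[pmax(win_of, 1L)]
  wsum <- vapply(split(len[keep] * v[win_of[keep]], bin_of[keep]), sum, numeric(1))
  wlen <- vapply(split(len[keep], bin_of[keep]), sum, numeric(1))
  out <- numeric(n_bins)
  idx <- as.integer(names(wsum))
  out[idx] <- wsum / wlen
  # bins with no covered length (gaps in the track) inherit the nearest value
  if (any(wlen == 0) || length(idx) < n_bins) {
    filled <- seq_len(n_bins) %in% idx[wlen > 0]
    if (!all(filled)) {
      known <- which(filled)
      for (b in which(!filled)) out[b] <- out[known[which.min(abs(known - b))]]
    }
  }
  out
}

#' @export
print.condensed_vector <- function(x, ...) {
  cat(sprintf("<condensed_vector> '%s': N = %d (m = %d), %.6g bp/bin over %s bp\n",
              x$source, length(x$values), x$m, x$bin_width,
              format(x$seq_length, big.mark = ",")))
  invisible(x)
}

as_signal_vector <- function(x) {
  if (inherits(x, "condensed_vector")) return(x)
  if (is.numeric(x)) {
    return(structure(list(values = as.numeric(x), m = NA_integer_,
                          bin_width = 1, source = "numeric",
                          seq_length = length(x)),
                     class = "condensed_vector"))
  }
  stopf("expected a condensed_vector or numeric vector")
}

#' Maximal-overlap discrete wavelet transform
#'
#' Decomposes a condensed property vector into `J` levels of wavelet
#' (detail) coefficients plus the level-`J` scaling (smooth) coefficients,
#' using the non-decimated pyramid algorithm with periodic boundary.  For
#' the Haar filter the level-1 details are
#' `W[1,t] = (x[t] - x[t-1 mod N]) / 2`.  The `denoised` series is the
#' multiresolution smooth: the inverse transform with every detail series
#' zeroed, i.e. the reconstruction of the highest-level coefficients only.
#'
#' @param x A `condensed_vector` (from [condense()]) or numeric vector whose
#'   length is a power of two.
#' @param filter_name One of `"haar"` (default), `"d4"`, `"la8"`, `"fk4"`.
#' @param J Maximum decomposition level, `1 <= J <= log2(N)`.
#' @return An object of class `wavelet_result` with fields `filter_name`,
#'   `J`, `details` (an `N x J` matrix, one column per level), `smooth`,
#'   `denoised`, `x` (the input values) and `bin_width`.
#' @export
modwt <- function(x, filter_name = "haar", J = 4) {
  x <- as_signal_vector(x)
  v <- x$values
  N <- length(v)
  if (N < 2 || bitwAnd(N, N - 1L) != 0L) stopf("vector length must be a power of two")
  if (!is_count(J) || J > log2(N)) stopf("J must be an integer in [1, log2(N) = %d]", as.integer(log2(N)))
  f <- wavelet_filter(filter_name)
  ht <- f$h / sqrt(2)
  gt <- f$g / sqrt(2)
  details <- matrix(0, N, J)
  V <- v
  t0 <- seq_len(N)
  for (j in seq_len(J)) {
    stride <- 2L^(j - 1L)
    Wj <- numeric(N)
    Vj <- numeric(N)
    for (l in seq_len(f$L) - 1L) {
      idx <- ((t0 - 1L - stride * l) %% N) + 1L
      Wj <- Wj + ht[l + 1L] * V[idx]
      Vj <- Vj + gt[l + 1L] * V[idx]
    }
    details[, j] <- Wj
    V <- Vj
  }
  res <- structure(list(filter_name = filter_name, J = as.integer(J),
                        details = details, smooth = V, denoised = NULL,
                        x = v, bin_width = x$bin_width),
                   class = "wavelet_result")
  res$denoised <- imodwt(res, details_zeroed = TRUE)
  res
}

#' Inverse maximal-overlap discrete wavelet transform
#'
#' Reconstructs the original series from a [modwt()] result; with
#' `details_zeroed = TRUE` it reconstructs the smooth (denoised) series
#' from the level-`J` scaling coefficients only.
#'
#' @param wr A `wavelet_result`.
#' @param details_zeroed If `TRUE`, all detail coefficients are treated as
#'   zero (multiresolution smooth).
#' @return A numeric vector of length `N`.
#' @export
imodwt <- function(wr, details_zeroed = FALSE) {
  stopifnot(inherits(wr, "wavelet_result"))
  f <- wavelet_filter(wr$filter_name)
  ht <- f$h / sqrt(2)
  gt <- f$g / sqrt(2)
  N <- length(wr$smooth)
  V <- wr$smooth
  t0 <- seq_len(N)
  for (j in rev(seq_len(wr$J))) {
    stride <- 2L^(j - 1L)
    W <- if (details_zeroed) numeric(N) else wr$details[, j]
    Vprev <- numeric(N)
    for (l in seq_len(f$L) - 1L) {
      idx <- ((t0 - 1L + stride * l) %% N) + 1L
      Vprev <- Vprev + ht[l + 1L] * W[idx] + gt[l + 1L] * V[idx]
    }
    V <- Vprev
  }
  V
}

#' @export
print.wavelet_result <- function(x, ...) {
  cat(sprintf("<wavelet_result> %s filter, J = %d, N = %d\n",
              x$filter_name, x$J, length(x$x)))
  invisible(x)
}

#' Wavelet denoising of a condensed vector
#'
#' Convenience wrapper returning the [modwt()] `denoised` series: the
#' reconstruction of the level-`J` smooth with every detail (noise) series
#' removed.
#'
#' @inheritParams modwt
#' @return A numeric vector of length `N`.
#' @export
denoise <- function(x, filter_name = "haar", J = 4) {
  modwt(x, filter_name = filter_name, J = J)$denoised
}

#' Normal-approximation confidence bound for correlation series
#'
#' `CI = Z_p / sqrt(N)`, where `Z_p` is the two-sided standard-normal
#' critical value (the area between `-Z_p` and `Z_p` equals `p`).  For
#' p = 0.95, 0.99, 0.999 the critical values round to 1.96, 2.58, 3.29;
#' for N = 2048, p = 0.999 the bound rounds to 0.073.  A correlation
#' coefficient exceeding the bound in magnitude is considered significant.
#'
#' @param N Vector size.
#' @param p Confidence level in (0, 1).
#' @return The confidence bound.
#' @examples
#' round(confidence_interval(2048, 0.999), 3)  # 0.073
#' @export
confidence_interval <- function(N, p) {
  if (!is_count(N)) stopf("N must be a positive integer")
  if (!is_number(p) || p <= 0 || p >= 1) stopf("confidence level p must be in (0, 1)")
  stats::qnorm((1 + p) / 2) / sqrt(N)
}

correlation_series <- function(kind, lags, coefficients, N, p, bin_width) {
  structure(list(kind = kind, lags = as.integer(lags),
                 coefficients = as.numeric(coefficients), N = as.integer(N),
                 confidence_level = p, ci = confidence_interval(N, p),
                 bin_width = bin_width),
            class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat(sprintf("<correlation_series> %s, N = %d, lags %d..%d, %g%% CI = %.4g\n",
              x$kind, x$N, min(x$lags), max(x$lags),
              100 * x$confidence_level, x$ci))
  invisible(x)
}

#' Autocorrelation of a condensed vector
#'
#' Correlation of the vector with lagged copies of itself at lags
#' `0..N-1`, using the biased (divide-by-N, global-mean) estimator of
#' `stats::acf()`:
#' `r(k) = sum_t (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2`.
#' Peaks indicate rhythmic structure in the property.
#'
#' @param x A `condensed_vector` or numeric vector.
#' @param p Confidence level for the significance bound (default 0.999).
#' @return A `correlation_series` with `kind = "auto"`.
#' @export
autocorrelation <- function(x, p = 0.999) {
  x <- as_signal_vector(x)
  v <- x$values
  N <- length(v)
  if (N < 2) stopf("need at least 2 values")
  if (stats::sd(v) == 0) stopf("autocorrelation undefined for a zero-variance vector")
  a <- stats::acf(v, lag.max = N - 1, type = "correlation", plot = FALSE,
                  demean = TRUE)
  correlation_series("auto", 0:(N - 1), as.numeric(a$acf), N, p, x$bin_width)
}

#' Cross-correlation of two condensed vectors
#'
#' Biased cross-correlation (the `stats::ccf()` convention, normalized by
#' the product of the two standard deviations) at lags `-(N-1)..(N-1)`.
#' The peak lag aligns the two properties irrespective of where each
#' sequence's first base was defined.
#'
#' @param x,y `condensed_vector`s (or numeric vectors) of the same length.
#' @param p Confidence level for the significance bound (default 0.999).
#' @return A `correlation_series` with `kind = "cross"`; the coefficient at
#'   lag `k` correlates `x` shifted forward by `k` against `y`.
#' @export
cross_correlation <- function(x, y, p = 0.999) {
  x <- as_signal_vector(x); y <- as_signal_vector(y)
  if (length(x$values) != length(y$values)) {
    stopf("vectors must have equal size (got %d and %d); condense both with the same m",
          length(x$values), length(y$values))
  }
  N <- length(x$values)
  if (stats::sd(x$values) == 0 || stats::sd(y$values) == 0) {
    stopf("cross-correlation undefined for a zero-variance vector")
  }
  cc <- stats::ccf(x$values, y$values, lag.max = N - 1, plot = FALSE,
                   demean = TRUE)
  correlation_series("cross", as.integer(cc$lag), as.numeric(cc$acf), N, p,
                     x$bin_width)
}

#' Locate the dominant correlation peak
#'
#' Scans the local extrema of a correlation series by magnitude: a local
#' extremum has strictly greater `|r|` than both neighbours.  Among extrema
#' with `|lag| >= min_lag_bins` the one with maximum `|r|` is returned; ties
#' go to the smallest `|lag|`.  Lag 0 is always excluded for
#' autocorrelation, where `r(0) = 1` is structural.  If no local extremum
#' exists in range, the global max-`|r|` lag in range is returned flagged
#' not significant.
#'
#' @param series A `correlation_series`.
#' @param min_lag_bins Minimum `|lag|` (in bins) to consider; default 1.
#' @return An object of class `correlation_peak` with `lag_bins`, `lag_bp`,
#'   `coefficient` and `significant` (`|r|` exceeds the series' confidence
#'   bound).
#' @export
find_peak <- function(series, min_lag_bins = 1) {
  stopifnot(inherits(series, "correlation_series"))
  r <- series$coefficients
  lags <- series$lags
  n <- length(r)
  if (!n) stopf("empty correlation series")
  a <- abs(r)
  is_ext <- rep(FALSE, n)
  if (n >= 3) {
    mid <- 2:(n - 1)
    is_ext[mid] <- a[mid] > a[mid - 1] & a[mid] > a[mid + 1]
  }
  if (n >= 2) {
    is_ext[1] <- a[1] > a[2]
    is_ext[n] <- a[n] > a[n - 1]
  }
  in_range <- abs(lags) >= min_lag_bins
  if (series$kind == "auto") in_range <- in_range & lags != 0L
  cand <- which(is_ext & in_range)
  forced_insignificant <- FALSE
  if (!length(cand)) {
    cand <- which(in_range)
    if (!length(cand)) stopf("no lags at |lag| >= %d", min_lag_bins)
    forced_insignificant <- TRUE
  }
  ord <- cand[order(-a[cand], abs(lags[cand]), lags[cand])]
  best <- ord[1]
  sig <- !forced_insignificant && a[best] > series$ci
  structure(list(lag_bins = lags[best],
                 lag_bp = lags[best] * series$bin_width,
                 coefficient = r[best], significant = sig),
            class = "correlation_peak")
}

#' @export
print.correlation_peak <- function(x, ...) {
  cat(sprintf("<correlation_peak> lag %d bins (%.4g bp): r = %.4g%s\n",
              x$lag_bins, x$lag_bp, x$coefficient,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' Wavelet-based similarity summary of two properties
#'
#' For each decomposition level `j = 1..J`, the maximum absolute
#' cross-correlation between the level-`j` detail coefficients of the two
#' vectors is recorded; the maximum absolute cross-correlation between the
#' two denoised series is added, and the arithmetic mean of these `J + 1`
#' magnitudes is returned.  Values close to 1 indicate that both the noise
#' scales and the global shapes of the two properties align at some lag.
#'
#' @param x,y `condensed_vector`s of the same length.
#' @param filter_name Wavelet filter (default `"haar"`).
#' @param J Maximum decomposition level (default 4).
#' @param p Confidence level (kept on the underlying series; default 0.999).
#' @return A similarity score in `[0, 1]`.
#' @export
similarity_summary <- function(x, y, filter_name = "haar", J = 4, p = 0.999) {
  x <- as_signal_vector(x); y <- as_signal_vector(y)
  wx <- modwt(x, filter_name, J)
  wy <- modwt(y, filter_name, J)
  max_abs_ccf <- function(a, b) {
    max(abs(cross_correlation(a, b, p)$coefficients))
  }
  level_max <- vapply(seq_len(J), function(j) {
    max_abs_ccf(wx$details[, j], wy$details[, j])
  }, numeric(1))
  den_max <- max_abs_ccf(wx$denoised, wy$denoised)
  mean(c(level_max, den_max))
}

#' Haar reverse-cumulative similarity diagnostic
#'
#' The Haar (and FK4) filters reverse accumulation: the level-`J` Haar
#' detail coefficients of a cumulative signal resemble a denoised version
#' of the underlying (non-cumulative) signal at the same level.  This
#' diagnostic returns the Pearson correlation between (a) the level-`J`
#' Haar details of the running sum of `raw` and (b) the level-`J` denoised
#' `raw`, which is high (about 0.9 or above) for skew-like signals.
#'
#' The running sum of a finite realisation is not periodic (its net drift
#' reappears, scaled, in the wavelet coefficients that wrap around the
#' boundary), so the boundary-affected coefficients — the first `2^J`
#' positions under the periodic transform — are excluded from the
#' correlation, the usual treatment for circular-boundary artifacts.
#'
#' @param raw A `condensed_vector` of a non-cumulative property.
#' @param J Decomposition level.
#' @return The Pearson correlation coefficient.
#' @export
haar_reverse_cumulative_similarity <- function(raw, J = 4) {
  raw <- as_signal_vector(raw)
  if (stats::sd(raw$values) == 0) {
    stopf("similarity undefined for a zero-variance vector")
  }
  cum <- cumsum(raw$values)
  keep <- (2^J + 1):length(cum)
  det_j <- modwt(cum, "haar", J)$details[keep, J]
  den <- denoise(raw$values, "haar", J)[keep]
  if (stats::sd(det_j) == 0 || stats::sd(den) == 0) {
    stopf("similarity undefined: a compared series has zero variance")
  }
  stats::cor(det_j, den)
}
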