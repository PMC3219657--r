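# Condensation, MODWT, correlation statistics and similarity summaries.

test_that("condense averages source windows into dyadic bins", {
  set.seed(1)
  v <- rnorm(4096)
  tr <- property_track("p", "c", 10, seq(1, length.out = 4096, by = 10), v,
                       seq_length = 40960)
  cv <- condense(tr, 11)
  expect_equal(length(cv$values), 2048L)
  expect_equal(cv$values, colMeans(matrix(v, nrow = 2)))
  expect_equal(cv$bin_width, 40960 / 2048)

  const <- property_track("p", "c", 10, seq(1, 100, by = 10), rep(3.25, 10))
  expect_equal(condense(const, 5)$values, rep(3.25, 32))
})

test_that("condense matches the brute-force overlap-weighted oracle", {
  set.seed(7)
  n <- 300
  v <- rnorm(n)
  tr <- property_track("p", "c", 7, seq(1, length.out = n, by = 7), v,
                       seq_length = 7 * n)
  m <- 7  # 128 bins; ratio 300/128 is deliberately non-integer
  cv <- condense(tr, m)
  e <- track_edges(tr)
  expect_equal(cv$values, condense_oracle(e$lo, e$hi, v, tr$seq_length, 2^m),
               tolerance = 1e-12)

  # fewer windows than bins: piecewise-constant upsampling
  small <- property_track("p", "c", 100, seq(1, 1000, by = 100), rnorm(10),
                          seq_length = 1000)
  cs <- condense(small, 6)
  es <- track_edges(small)
  expect_equal(cs$values, condense_oracle(es$lo, es$hi, small$values, 1000, 64),
               tolerance = 1e-12)
  expect_error(condense(small, 0), "positive")
})

test_that("MODWT reproduces the Haar difference formula and degenerate cases", {
  const <- rep(2.5, 64)
  w <- modwt(const, "haar", 4)
  expect_equal(max(abs(w$details)), 0)
  expect_equal(w$denoised, const)

  set.seed(11)
  x <- rnorm(128)
  w1 <- modwt(x, "haar", 1)
  lagged <- c(x[128], x[-128])
  expect_equal(w1$details[, 1], (x - lagged) / 2, tolerance = 1e-12)

  expect_error(modwt(x, "haar", 8), "log2")
  expect_error(modwt(x, "coif5", 2), "haar, d4, la8, fk4")
  expect_error(modwt(rnorm(100), "haar", 2), "power of two")
})

test_that("MODWT is perfectly invertible and conserves energy for all filters", {
  for (N in c(64, 256, 2048)) {
    set.seed(N)
    x <- rnorm(N)
    for (f in c("haar", "d4", "la8", "fk4")) {
      J <- min(4, log2(N))
      w <- modwt(x, f, J)
      expect_lt(max(abs(imodwt(w) - x)), 1e-10)
      energy <- sum(w$details^2) + sum(w$smooth^2)
      expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-8)
      # smooth + sum of detail contributions is an additive decomposition
      expect_equal(length(w$smooth), N)
      expect_equal(dim(w$details), c(N, J))
    }
  }
})

test_that("denoising keeps smooth shapes and shrinks noise", {
  N <- 1024
  lam <- c(seq(0, 1, length.out = N / 2), seq(1, 0, length.out = N / 2))
  set.seed(3)
  noisy <- lam + rnorm(N, 0, 0.01)
  den <- denoise(noisy, "haar", 4)
  expect_gte(stats::cor(den, noisy), 0.99)

  wn <- rnorm(N)
  expect_lt(stats::var(denoise(wn, "haar", 4)), stats::var(wn))

  expect_error(denoise(wn, "haar", 0), "J")
})

test_that("autocorrelation equals the brute-force estimator at all lags", {
  set.seed(17)
  for (N in c(64, 257, 512)) {
    x <- rnorm(N)
    # non-dyadic lengths are fine for correlation (dyadic only needed by modwt)
    ac <- autocorrelation(x, p = 0.999)
    expect_equal(ac$coefficients[1], 1)
    expect_equal(ac$lags, 0:(N - 1))
    expect_equal(ac$coefficients, acf_oracle(x), tolerance = 1e-10)
  }
  expect_error(autocorrelation(rep(1, 32)), "variance")
})

test_that("cosine signals show autocorrelation peaks at multiples of the period", {
  N <- 512
  x <- cos(2 * pi * (0:(N - 1)) / (N / 8))
  ac <- autocorrelation(x)
  # extrema fall on half-period multiples; positive peaks on full periods
  pk <- find_peak(ac, min_lag_bins = 10)
  expect_equal(pk$lag_bins %% (N / 16), 0)
  per <- N / 8
  expect_gt(ac$coefficients[per + 1], 0.8)
  expect_gt(ac$coefficients[per + 1], ac$coefficients[per])
  expect_gt(ac$coefficients[per + 1], ac$coefficients[per + 2])
})

test_that("cross-correlation matches the oracle and swap antisymmetry", {
  set.seed(23)
  N <- 256
  x <- rnorm(N); y <- rnorm(N)
  cc <- cross_correlation(x, y)
  expect_equal(cc$lags, -(N - 1):(N - 1))
  expect_equal(cc$coefficients, ccf_oracle(x, y), tolerance = 1e-10)
  cc_swap <- cross_correlation(y, x)
  expect_equal(cc$coefficients, rev(cc_swap$coefficients), tolerance = 1e-12)

  self0 <- cross_correlation(x, x)
  expect_equal(self0$coefficients[self0$lags == 0], 1)

  s <- 17
  yshift <- c(x[(s + 1):N], x[1:s])  # y[t] = x[t + s]
  ccs <- cross_correlation(x, yshift)
  best <- ccs$lags[which.max(abs(ccs$coefficients))]
  expect_true(abs(best) == s)

  expect_error(cross_correlation(x, rnorm(128)), "equal size")
  expect_error(cross_correlation(x, rep(0, N)), "variance")
})

test_that("confidence bounds match the normal-quantile formula", {
  expect_equal(round(confidence_interval(2048, 0.999), 3), 0.073)
  expect_equal(round(stats::qnorm((1 + 0.95) / 2), 2), 1.96)
  expect_equal(round(stats::qnorm((1 + 0.99) / 2), 2), 2.58)
  expect_equal(round(stats::qnorm((1 + 0.999) / 2), 2), 3.29)
  expect_equal(confidence_interval(1, 0.95), stats::qnorm(0.975))
  # strictly decreasing in N, increasing in p
  Ns <- c(2, 16, 128, 1024)
  cis <- sapply(Ns, confidence_interval, p = 0.99)
  expect_true(all(diff(cis) < 0))
  ps <- c(0.9, 0.95, 0.99, 0.999)
  cis2 <- sapply(ps, function(p) confidence_interval(256, p))
  expect_true(all(diff(cis2) > 0))
  expect_error(confidence_interval(100, 1.2), "in \\(0, 1\\)")
})

test_that("find_peak selects the dominant local extremum by magnitude", {
  # symmetric triangular vector: the dominant extremum is the negative
  # trough near half length (the biased estimator's taper pulls it slightly
  # below N/2); the brute-force scan of the oracle ACF is the ground truth
  N <- 256
  lam <- c(seq(0, 1, length.out = N / 2), seq(1, 0, length.out = N / 2))
  ac <- autocorrelation(lam)
  pk <- find_peak(ac)
  r <- acf_oracle(lam)
  a <- abs(r)
  ext <- which(a > c(Inf, a[-N]) & a > c(a[-1], Inf) & (0:(N - 1)) >= 1)
  expect_equal(pk$lag_bins, (ext[which.max(a[ext])] - 1))
  expect_lt(pk$coefficient, 0)
  expect_gte(pk$lag_bins, 0.4 * N)
  expect_lte(pk$lag_bins, 0.6 * N)

  # a single injected extremum is found
  flat <- correlation_series_stub(c(1, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1))
  pk2 <- find_peak(flat)
  expect_equal(pk2$lag_bins, 3L)

  # monotone series: no local extremum -> global max in range, not significant
  mono <- correlation_series_stub(c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  pk3 <- find_peak(mono, min_lag_bins = 2)
  expect_equal(pk3$lag_bins, 2L)
  expect_false(pk3$significant)
})

test_that("white-noise autocorrelation peaks are insignificant at 99.9%", {
  n_ok <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    pk <- find_peak(autocorrelation(rnorm(128), p = 0.999))
    if (!pk$significant) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 95L)
})

test_that("similarity summary is 1 on self, scale-invariant and discriminative", {
  set.seed(41)
  N <- 2048
  tr <- make_periodic_track(N, 256, amplitude = 1, noise_sd = 0.2, seed = 5)
  x <- condense(tr, 11)
  expect_equal(similarity_summary(x, x), 1, tolerance = 1e-9)

  y <- x; y$values <- 3 * x$values - 7  # affine rescaling
  expect_equal(similarity_summary(x, y), similarity_summary(x, x),
               tolerance = 1e-9)

  s <- 128
  shifted <- x
  shifted$values <- c(x$values[(s + 1):N], x$values[1:s])
  expect_gte(similarity_summary(x, shifted), 0.9)

  sims <- sapply(1:20, function(k) {
    set.seed(k)
    similarity_summary(rnorm(N), rnorm(N))
  })
  expect_lt(max(sims), 0.2)
})

test_that("Haar details of a cumulative signal track the denoised raw signal", {
  spec <- skew_genome_spec(500000, oric_pos = 150000, skew_strength = 0.3,
                           noise_sd = 0.05, seed = 19)
  rec <- make_skewed_genome(spec)
  w <- window_size_for(rec$length, 2048)
  raw <- condense(sliding_property(rec, w, fn = gc_skew), 11)
  expect_gte(haar_reverse_cumulative_similarity(raw, 1), 0.9)
  expect_gte(haar_reverse_cumulative_similarity(raw, 4), 0.9)

  const <- property_track("c", "c", 10, seq(1, 640, by = 10), rep(1, 64))
  expect_error(haar_reverse_cumulative_similarity(condense(const, 6), 2),
               "variance")
})

test_that("pairwise analysis of k tracks yields k(k-1)/2 cross-correlations", {
  out_dir <- withr::local_tempdir()
  paths <- character(4)
  for (i in 1:4) {
    tr <- make_periodic_track(64, 16, amplitude = 1, noise_sd = 0.3, seed = i)
    tr$name <- paste0("t", i)
    paths[i] <- file.path(out_dir, paste0("t", i, ".gdf"))
    write_gdf(tr, paths[i])
  }
  res <- cmd_analyze(paths, m = 6, J = 3, out_dir = file.path(out_dir, "res"),
                     plots = FALSE)
  expect_equal(length(res$pairs), 4 * 3 / 2)
})
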