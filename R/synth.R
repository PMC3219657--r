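# Synthetic sequences and tracks with known ground truth.
#
# Genomes are sampled base-by-base (independent draws) with a programmed
# skew polarity: on the leading replichore, running clockwise from the
# replication origin to the terminus, P(G) exceeds P(C) by
# skew_strength * gc_content; the excess is reversed on the other
# replichore.  The cumulative GC skew of such a genome is V-shaped with its
# trough at the origin (Lambda-shaped when the origin is at base 1), which
# is exactly the signal used to localise oriC in real chromosomes.

#' Specify a synthetic skewed genome
#'
#' @param length Genome length in bp.
#' @param oric_pos Replication-origin position (bp).
#' @param ter_pos Terminus position (bp); must differ from `oric_pos`.
#'   Defaults to the position opposite `oric_pos`.
#' @param skew_strength Expected per-window GC skew on the leading strand,
#'   in `(0, 0.5]` (0 gives a skew-free genome).
#' @param gc_content Genome GC fraction in (0, 1).
#' @param noise_sd Standard deviation of a per-kilobase Gaussian jitter
#'   applied to the skew (in skew units); models local compositional
#'   heterogeneity.
#' @param period Optional period (bp) of a sinusoidal GC-content
#'   modulation (amplitude 10% of `gc_content`), for exercising
#'   periodicity detection.
#' @param seed Integer seed; generation is reproducible.
#' @return A list of class `skew_genome_spec`.
#' @export
skew_genome_spec <- function(length, oric_pos = 1,
                             ter_pos = (oric_pos + length %/% 2 - 1) %% length + 1,
                             skew_strength = 0.3, gc_content = 0.5,
                             noise_sd = 0, period = NULL, seed = 1) {
  if (!is_count(length, min = 2)) stopf("length must be an integer >= 2")
  if (!is_count(oric_pos) || oric_pos > length) stopf("oric_pos must be in [1, length]")
  if (!is_count(ter_pos) || ter_pos > length) stopf("ter_pos must be in [1, length]")
  if (oric_pos == ter_pos) stopf("oric_pos and ter_pos must differ")
  if (!is_number(skew_strength) || skew_strength < 0 || skew_strength > 0.5) {
    stopf("skew_strength must be in [0, 0.5]")
  }
  if (!is_number(gc_content) || gc_content <= 0 || gc_content >= 1) {
    stopf("gc_content must be in (0, 1)")
  }
  structure(list(length = as.integer(length), oric_pos = as.integer(oric_pos),
                 ter_pos = as.integer(ter_pos), skew_strength = skew_strength,
                 gc_content = gc_content, noise_sd = noise_sd,
                 period = period, seed = as.integer(seed)),
            class = "skew_genome_spec")
}

#' Generate a synthetic genome with programmed skew polarity
#'
#' @param spec A [skew_genome_spec()].
#' @return A circular [sequence_record()] whose cumulative GC skew has its
#'   minimum at `oric_pos` and maximum at `ter_pos` (in expectation).
#' @examples
#' rec <- make_skewed_genome(skew_genome_spec(20000, oric_pos = 1, seed = 7))
#' @export
make_skewed_genome <- function(spec) {
  stopifnot(inherits(spec, "skew_genome_spec"))
  L <- spec$length
  pos <- seq_len(L)
  # leading replichore: clockwise from oriC (inclusive) up to terminus
  on_leading <- if (spec$oric_pos < spec$ter_pos) {
    pos >= spec$oric_pos & pos < spec$ter_pos
  } else {
    pos >= spec$oric_pos | pos < spec$ter_pos
  }
  gc <- rep(spec$gc_content, L)
  if (!is.null(spec$period)) {
    gc <- gc * (1 + 0.1 * sin(2 * pi * pos / spec$period))
  }
  with_seed(spec$seed, {
    delta <- spec$skew_strength * gc
    if (spec$noise_sd > 0) {
      n_blk <- ceiling(L / 1000)
      eps <- stats::rnorm(n_blk, 0, spec$noise_sd)
      delta <- delta + eps[(pos - 1L) %/% 1000L + 1L] * gc
    }
    delta <- ifelse(on_leading, delta, -delta)
    pG <- pmin(pmax(gc / 2 + delta / 2, 0), gc)
    pC <- gc - pG
    pA <- (1 - gc) / 2
    u <- stats::runif(L)
    base_idx <- 1L + (u > pA) + (u > 2 * pA) + (u > 2 * pA + pC)
    residues <- paste(c("A", "T", "C", "G")[base_idx], collapse = "")
    sequence_record(sprintf("synth_skew_%d", spec$seed), residues,
                    topology = "circular",
                    name = sprintf("synthetic skewed genome (seed %d)", spec$seed))
  })
}

#' Generate a periodic synthetic property track
#'
#' A sinusoid of the given period plus seeded Gaussian noise, for testing
#' periodicity (autocorrelation) detection.
#'
#' @param n_windows Number of windows.
#' @param period_windows Period in windows (>= 2).
#' @param amplitude Sinusoid amplitude.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @param window_size Window size in bp (default 1000).
#' @return A [property_track()].
#' @export
make_periodic_track <- function(n_windows, period_windows, amplitude = 1,
                                noise_sd = 0, seed = 1, window_size = 1000) {
  if (!is_count(n_windows)) stopf("n_windows must be a positive integer")
  if (!is_number(period_windows) || period_windows < 2) {
    stopf("period_windows must be >= 2")
  }
  i <- seq_len(n_windows)
  values <- with_seed(seed, {
    amplitude * sin(2 * pi * i / period_windows) +
      stats::rnorm(n_windows, 0, noise_sd)
  })
  property_track(sprintf("periodic_%g", period_windows), "synth",
                 window_size, (i - 1L) * window_size + 1L, values)
}

#' Write a minimal GenBank flat-file fixture
#'
#' Emits a valid GenBank flat file (LOCUS with topology, FEATURES with
#' CDS/tRNA/rRNA locations including `complement()` and origin-spanning
#' `join()` forms, ORIGIN block) that [read_genbank()] round-trips.
#'
#' @param record A [sequence_record()].
#' @param features A data frame of genomic features (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
make_genbank_fixture <- function(record, features = NULL, path) {
  stopifnot(inherits(record, "sequence_record"))
  topo <- if (record$topology == "circular") "circular" else "linear"
  lines <- sprintf("LOCUS       %-16s %d bp    DNA     %-8s BCT 01-JAN-2026",
                   record$id, record$length, topo)
  lines <- c(lines,
             sprintf("DEFINITION  %s.", record$name),
             sprintf("ACCESSION   %s", record$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", record$length))
  if (!is.null(features) && nrow(features)) {
    for (i in seq_len(nrow(features))) {
      s <- features$start[i]; e <- features$end[i]
      loc <- if (e >= s) sprintf("%d..%d", s, e)
             else sprintf("join(%d..%d,1..%d)", s, record$length, e)
      if (features$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      lines <- c(lines, sprintf("     %-15s %s", features$category[i], loc))
      if (nzchar(features$label[i])) {
        lines <- c(lines, sprintf('                     /gene="%s"', features$label[i]))
      }
    }
  }
  lines <- c(lines, "ORIGIN")
  seq <- tolower(record$residues)
  starts <- seq.int(1L, record$length, by = 60L)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59L, record$length))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}
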