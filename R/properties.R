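# Sliding-window genomic properties and cumulative forms.
#
# All skew denominators count unambiguous bases only; windows whose
# denominator is zero return 0 so downstream wavelet/correlation stages see
# finite vectors (reported once per track via a warning).

base_counts <- function(window) {
  r <- charToRaw(window)
  c(A = sum(r == as.raw(65L)), C = sum(r == as.raw(67L)),
    G = sum(r == as.raw(71L)), T = sum(r == as.raw(84L)))
}

skew_ratio <- function(num, den) if (den == 0) 0 else num / den

is_skew_fn <- function(fn) identical(fn, gc_skew)

#' GC skew of a window
#'
#' `(G - C) / (G + C)` over the unambiguous bases of a window.  In
#' prokaryotes the sign of the GC skew typically flips at the replication
#' origin and terminus.  Windows with no G or C return 0.
#'
#' @param window A DNA string (one window of sequence).
#' @return A value in `[-1, 1]`.
#' @examples
#' gc_skew("GGGC")  # 0.5
#' @export
gc_skew <- function(window) {
  n <- base_counts(toupper(window))
  skew_ratio(n[["G"]] - n[["C"]], n[["G"]] + n[["C"]])
}

#' AT skew of a window
#'
#' `(A - T) / (A + T)` over the unambiguous bases; 0 when the window has no
#' A or T.
#'
#' @inheritParams gc_skew
#' @return A value in `[-1, 1]`.
#' @export
at_skew <- function(window) {
  n <- base_counts(toupper(window))
  skew_ratio(n[["A"]] - n[["T"]], n[["A"]] + n[["T"]])
}

#' Keto skew of a window
#'
#' Keto (G, T) versus amino (A, C) bases:
#' `(G + T - A - C) / (G + T + A + C)`; 0 when the window has no
#' unambiguous bases.
#'
#' @inheritParams gc_skew
#' @return A value in `[-1, 1]`.
#' @export
keto_skew <- function(window) {
  n <- base_counts(toupper(window))
  skew_ratio(n[["G"]] + n[["T"]] - n[["A"]] - n[["C"]], sum(n))
}

#' GC content of a window
#'
#' `(G + C)` divided by the number of unambiguous bases in the window; 0
#' when the window has none.
#'
#' @inheritParams gc_skew
#' @return A value in `[0, 1]`.
#' @export
gc_content <- function(window) {
  n <- base_counts(toupper(window))
  skew_ratio(n[["G"]] + n[["C"]], sum(n))
}

#' Window size for a display/condensation resolution
#'
#' The tiling window size (bp) that condenses a sequence of `length` bp into
#' at most `resolution` units: `ceiling(length / resolution)`.  A 4,639 kb
#' chromosome condensed to 4,000 units uses 1,160 bp windows.
#'
#' @param length Sequence length in bp.
#' @param resolution Number of track units.
#' @return Window size in bp.
#' @examples
#' window_size_for(4639000, 4000)  # 1160
#' @export
window_size_for <- function(length, resolution) {
  if (!is_count(length) || !is_count(resolution)) {
    stopf("length and resolution must be positive integers")
  }
  if (resolution > length) {
    stopf("resolution (%d) exceeds sequence length (%d): windows would be sub-bp",
          resolution, length)
  }
  as.integer(ceiling(length / resolution))
}

#' Compute a sliding-window property track
#'
#' Applies a per-window function along the sequence.  Windows start at
#' position 1 and advance by `step` (default: non-overlapping tiles with
#' `step == window`).  On linear sequences the final window is truncated at
#' the sequence end; on circular sequences it wraps around the origin.
#'
#' @param record A [sequence_record()].
#' @param window Window size in bp.
#' @param step Step in bp between window starts (default `window`).
#' @param fn Per-window function mapping a DNA string to a number, e.g.
#'   [gc_skew()].
#' @param name Track name; defaults to the name of `fn`.
#' @return A [property_track()].
#' @examples
#' rec <- sequence_record("x", "GGGGGCCCCC")
#' sliding_property(rec, window = 5, fn = gc_skew)$values  # c(1, -1)
#' @export
sliding_property <- function(record, window, step = window, fn = gc_skew,
                             name = deparse(substitute(fn))) {
  stopifnot(inherits(record, "sequence_record"))
  L <- record$length
  if (!is_count(window) || window > L) stopf("window must be in [1, %d]", L)
  if (!is_count(step)) stopf("step must be a positive integer")
  starts <- seq.int(1L, L, by = step)
  windows <- vapply(starts, function(s) {
    e <- s + window - 1L
    if (e <= L) {
      substr(record$residues, s, e)
    } else if (record$topology == "circular") {
      paste0(substr(record$residues, s, L),
             substr(record$residues, 1L, e - L))
    } else {
      substr(record$residues, s, L)
    }
  }, character(1))
  values <- vapply(windows, fn, numeric(1), USE.NAMES = FALSE)
  if (is_skew_fn(fn)) {
    n_zero <- sum(!grepl("[GCgc]", windows))
    if (n_zero > 0) {
      warnf("%d window(s) with zero skew denominator reported as 0", n_zero)
    }
  }
  property_track(name, record$id, window, starts, values, step = step,
                 seq_length = L)
}

#' Cumulative form of a property track
#'
#' Running sum of the windowed values: the k-th output value is the sum of
#' the first k input values.  The cumulative GC skew of a chromosome with
#' skew polarity forms a Lambda- or V-shaped curve whose extrema mark the
#' replication origin and terminus.
#'
#' @param track A [property_track()].
#' @return A [property_track()] with the same windows, values replaced by
#'   their running sum, and the name suffixed `" cumulative"`.
#' @export
cumulate <- function(track) {
  stopifnot(inherits(track, "property_track"))
  property_track(paste(track$name, "cumulative"), track$seq_id,
                 track$window_size, track$starts, cumsum(track$values),
                 step = track$step, seq_length = track$seq_length)
}

#' Locate the global extrema of a property track
#'
#' Positions (window starts) of the global minimum and maximum values.
#' Ties are broken by the smallest position.  On a cumulative GC skew the
#' minimum and maximum typically coincide with the replication origin and
#' terminus.
#'
#' @param track A [property_track()].
#' @return A list of class `extrema_report` with `min_pos`, `min_value`,
#'   `max_pos`, `max_value`.
#' @export
locate_extrema <- function(track) {
  stopifnot(inherits(track, "property_track"))
  i_min <- which.min(track$values)
  i_max <- which.max(track$values)
  structure(list(min_pos = track$starts[i_min], min_value = track$values[i_min],
                 max_pos = track$starts[i_max], max_value = track$values[i_max]),
            class = "extrema_report")
}

#' @export
print.extrema_report <- function(x, ...) {
  cat(sprintf("<extrema_report> min %.6g at bp %d; max %.6g at bp %d\n",
              x$min_value, x$min_pos, x$max_value, x$max_pos))
  invisible(x)
}
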