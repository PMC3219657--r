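# Core containers.  Coordinates are 1-based inclusive throughout the data
# model (GenBank convention); rendering converts internally.

#' Create a sequence record
#'
#' A chromosome or plasmid sequence with its topology.  Residues are
#' upper-cased; length is derived from the residue string.
#'
#' @param id Accession-like identifier (non-empty string).
#' @param residues IUPAC DNA string.
#' @param topology `"linear"` or `"circular"`.
#' @param name Display name; defaults to `id`.
#' @return An object of class `sequence_record` with fields `id`, `name`,
#'   `length`, `residues` and `topology`.
#' @examples
#' rec <- sequence_record("chr1", "ACGTACGT", topology = "circular")
#' rec$length
#' @export
sequence_record <- function(id, residues, topology = c("linear", "circular"),
                            name = id) {
  topology <- match.arg(topology)
  if (!is_string(id) || !nzchar(id)) stopf("sequence id must be a non-empty string")
  if (!is_string(residues)) stopf("residues must be a single string")
  residues <- toupper(residues)
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", residues)
  if (nzchar(bad)) {
    stopf("residues contain non-IUPAC characters: %s",
          paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  structure(list(id = id, name = name, length = nchar(residues),
                 residues = residues, topology = topology),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%s): %s bp, %s\n", x$id,
              x$name, format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' Create a genomic feature
#'
#' One positional annotation on a sequence.  On circular sequences
#' `start > end` denotes an origin-spanning feature and is permitted.
#'
#' @param seq_id Identifier of the parent sequence.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"`, `"-"` or `"."` (strandless).
#' @param label Display label.
#' @param category Feature class, e.g. `"CDS"`, `"tRNA"`, `"rRNA"` or a
#'   custom string.
#' @param color Hex color string, or `NA` for unset.
#' @return A one-row data frame with the feature columns.
#' @export
genomic_feature <- function(seq_id, start, end, strand = ".", label = "",
                            category = "misc", color = NA_character_) {
  if (!is_count(start) || !is_count(end)) stopf("start/end must be positive integers")
  if (!strand %in% c("+", "-", ".")) stopf("strand must be one of '+', '-', '.'")
  data.frame(seq_id = seq_id, start = as.integer(start), end = as.integer(end),
             strand = strand, label = label, category = category,
             color = color, stringsAsFactors = FALSE)
}

#' Create a feature track
#'
#' An ordered collection of genomic features on one sequence, stored as a
#' data frame with columns `seq_id`, `start`, `end`, `strand`, `label`,
#' `category`, `color`.
#'
#' @param name Track name.
#' @param seq_id Identifier of the parent sequence.
#' @param features Data frame of features (as built by [genomic_feature()],
#'   row-bound), or an empty data frame.
#' @param seq_length Length of the parent sequence in bp (used for
#'   coordinate validation and rendering); may be `NA`.
#' @return An object of class `feature_track`.
#' @export
feature_track <- function(name, seq_id, features = NULL, seq_length = NA) {
  if (is.null(features) || nrow(features) == 0L) {
    features <- genomic_feature(seq_id, 1, 1)[0, ]
  }
  needed <- c("seq_id", "start", "end", "strand", "label", "category", "color")
  miss <- setdiff(needed, names(features))
  if (length(miss)) stopf("feature data frame lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(features) && !all(features$seq_id == seq_id)) {
    stopf("all features in track '%s' must share seq_id '%s'", name, seq_id)
  }
  if (!is.na(seq_length) && nrow(features)) {
    if (any(features$start < 1L | features$end < 1L |
            features$start > seq_length | features$end > seq_length)) {
      stopf("feature coordinates outside [1, %d] in track '%s'", seq_length, name)
    }
  }
  structure(list(name = name, seq_id = seq_id,
                 features = features[, needed],
                 seq_length = seq_length),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track> '%s' on %s: %d features\n",
              x$name, x$seq_id, nrow(x$features)))
  invisible(x)
}

#' @export
length.feature_track <- function(x) nrow(x$features)

#' Create a property track
#'
#' A windowed numeric genomic property: one value per window, windows
#' identified by their 1-based start positions.
#'
#' @param name Track name.
#' @param seq_id Identifier of the parent sequence.
#' @param window_size Window size in bp.
#' @param starts Strictly increasing 1-based window start positions.
#' @param values Numeric values, one per window.
#' @param step Step between window starts in bp; defaults to `window_size`
#'   (non-overlapping tiles).
#' @param seq_length Parent sequence length in bp; defaults to the end of
#'   the last window.
#' @return An object of class `property_track` with a `stats` field holding
#'   min, max, mean and sd of the values.
#' @export
property_track <- function(name, seq_id, window_size, starts, values,
                           step = window_size, seq_length = NULL) {
  if (length(starts) != length(values)) stopf("|starts| must equal |values|")
  if (!length(values)) stopf("property track '%s' has no windows", name)
  if (!is_count(window_size)) stopf("window_size must be a positive integer")
  if (is.unsorted(starts, strictly = TRUE)) stopf("window starts must be strictly increasing")
  if (!all(is.finite(values))) stopf("property values must be finite")
  if (is.null(seq_length)) seq_length <- starts[length(starts)] + window_size - 1
  structure(list(name = name, seq_id = seq_id,
                 window_size = as.integer(window_size), step = as.integer(step),
                 starts = as.integer(starts), values = as.numeric(values),
                 seq_length = as.numeric(seq_length),
                 stats = track_stats(values)),
            class = "property_track")
}

track_stats <- function(values) {
  list(min = min(values), max = max(values),
       mean = mean(values), sd = if (length(values) > 1L) stats::sd(values) else 0)
}

#' @export
print.property_track <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<property_track> '%s' on %s: %d windows of %d bp (step %d)\n  min %.4g  max %.4g  mean %.4g  sd %.4g\n",
    x$name, x$seq_id, length(x$values), x$window_size, x$step,
    s$min, s$max, s$mean, s$sd))
  invisible(x)
}

#' @export
length.property_track <- function(x) length(x$values)
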