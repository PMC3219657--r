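# Sequence and track input/output.
#
# GenBank flat files are parsed with a purpose-built reader (LOCUS line,
# CDS/tRNA/rRNA locations, ORIGIN block); FASTA goes through Biostrings.
# The tab-delimited GDF track format used here is defined in `read_gdf()`.

#' Read a GenBank flat file
#'
#' Parses the LOCUS line (length, topology), the CDS/tRNA/rRNA entries of
#' the FEATURES table, and the ORIGIN sequence block.  A
#' `join(a..L, 1..b)` location on a circular sequence becomes a single
#' origin-spanning feature with `start = a`, `end = b`; other multi-segment
#' joins are collapsed to their overall span.  Features whose location
#' cannot be parsed are skipped with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with elements `record` (a [sequence_record()]) and
#'   `features` (a data frame of genomic features).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stopf("not a GenBank flat file (no LOCUS line): %s", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "[[:space:]]+")[[1]]
  name <- locus[2]
  bp_i <- match("bp", locus)
  stated_len <- if (!is.na(bp_i) && bp_i > 2) suppressWarnings(as.integer(locus[bp_i - 1])) else NA
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  acc_i <- grep("^ACCESSION", lines)
  id <- if (length(acc_i)) strsplit(trimws(lines[acc_i[1]]), "[[:space:]]+")[[1]][2] else name
  if (is.na(id) || !nzchar(id)) id <- name

  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stopf("GenBank file has no ORIGIN sequence block: %s", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(residues)) stopf("GenBank ORIGIN block contains no sequence: %s", path)

  record <- sequence_record(id, residues, topology = topology, name = name)
  if (!is.na(stated_len) && stated_len != record$length) {
    warnf("LOCUS states %d bp but ORIGIN holds %d bp; using the sequence",
          stated_len, record$length)
  }

  features <- parse_genbank_features(lines, origin_i[1], record)
  list(record = record, features = features)
}

parse_genbank_features <- function(lines, origin_i, record) {
  feat_i <- grep("^FEATURES", lines)
  empty <- genomic_feature(record$id, 1, 1)[0, ]
  if (!length(feat_i) || feat_i[1] > origin_i) return(empty)
  block <- lines[(feat_i[1] + 1L):(origin_i - 1L)]
  # feature keys sit at column 6; continuation/qualifier lines start deeper
  key_rows <- grep("^ {5}[A-Za-z]", block)
  if (!length(key_rows)) return(empty)
  out <- list()
  for (k in seq_along(key_rows)) {
    from <- key_rows[k]
    to <- if (k < length(key_rows)) key_rows[k + 1] - 1L else length(block)
    entry <- block[from:to]
    head <- strsplit(trimws(entry[1]), "[[:space:]]+")[[1]]
    key <- head[1]
    if (!key %in% c("CDS", "tRNA", "rRNA")) next
    # location may continue over lines until the first qualifier (/...)
    qual_start <- grep("^[[:space:]]*/", entry)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(entry)
    loc <- paste(c(head[-1], trimws(entry[seq_len(loc_end)][-1])), collapse = "")
    coords <- parse_gb_location(loc, record$length, record$topology)
    if (is.null(coords)) {
      warnf("skipping %s feature with unparseable location: %s", key, loc)
      next
    }
    label <- gb_qualifier(entry, c("gene", "locus_tag", "product"))
    out[[length(out) + 1L]] <- genomic_feature(
      record$id, coords$start, coords$end, strand = coords$strand,
      label = label, category = key)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

gb_qualifier <- function(entry, names) {
  for (q in names) {
    m <- grep(sprintf("^[[:space:]]*/%s=", q), entry, value = TRUE)
    if (length(m)) return(gsub('"', "", sub(sprintf(".*/%s=", q), "", m[1])))
  }
  ""
}

# Returns list(start, end, strand) or NULL when unparseable.
parse_gb_location <- function(loc, seq_len, topology) {
  strand <- "+"
  loc <- gsub("[[:space:]<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  segs <- strsplit(loc, ",")[[1]]
  m <- regmatches(segs, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", segs))
  if (!length(segs) || any(vapply(m, length, integer(1)) == 0L)) return(NULL)
  starts <- as.integer(vapply(m, `[`, character(1), 2))
  ends <- vapply(m, `[`, character(1), 4)
  ends <- ifelse(nzchar(ends) & !is.na(ends), as.integer(ends), starts)
  if (any(is.na(starts)) || any(is.na(ends))) return(NULL)
  if (length(starts) > 1L && topology == "circular" &&
      ends[1] == seq_len && starts[length(starts)] == 1L) {
    return(list(start = starts[1], end = ends[length(ends)], strand = strand))
  }
  list(start = min(starts), end = max(ends), strand = strand)
}

#' Read a single-record FASTA file
#'
#' @param path Path to a FASTA file holding exactly one record.
#' @param topology Topology to assign (FASTA does not encode it);
#'   default `"linear"`.
#' @return A [sequence_record()]; the id is the first whitespace-delimited
#'   token of the header.
#' @export
read_fasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stopf("expected a single-record FASTA, found %d records in %s",
          length(set), path)
  }
  header <- names(set)[1]
  id <- strsplit(header, "[[:space:]]+")[[1]][1]
  sequence_record(id, as.character(set[[1]]), topology = topology, name = header)
}

#' Write a sequence record to FASTA
#'
#' @param record A [sequence_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(record, path) {
  stopifnot(inherits(record, "sequence_record"))
  set <- Biostrings::DNAStringSet(record$residues)
  names(set) <- record$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a GDF track file
#'
#' GDF (genome data format) is the tab-delimited track exchange dialect used
#' by this package: UTF-8 TSV; comment lines start with `#`; the header line
#' is `#gdf<TAB>feature|property<TAB>seq_id<TAB>seq_length`, optionally
#' followed by `#name<TAB>track name` and, for property tracks,
#' `#window<TAB>window_size<TAB>step`.  Feature rows are
#' `start end strand(+|-|.) label color(hex or .)`; property rows are
#' `start end value`.  Rows are sorted by start.
#'
#' The original web tool's format of the same name is no longer documented
#' anywhere public; this dialect is a self-contained stand-in.
#'
#' @param path Path to a GDF file.
#' @return A [feature_track()] or [property_track()] depending on the
#'   header mode.
#' @export
read_gdf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines) || !startsWith(lines[1], "#gdf\t")) {
    stopf("%s is not a GDF file (missing '#gdf' header)", path)
  }
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 4L) stopf("malformed GDF header in %s", path)
  mode <- hdr[2]
  if (!mode %in% c("feature", "property")) {
    stopf("GDF mode must be 'feature' or 'property', got '%s'", mode)
  }
  seq_id <- hdr[3]
  seq_length <- as.numeric(hdr[4])
  name <- sub("\\.gdf$", "", basename(path))
  window_size <- NA_integer_; step <- NA_integer_
  body_idx <- integer(0)
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (f[1] == "#name" && length(f) >= 2) name <- f[2]
      if (f[1] == "#window" && length(f) >= 3) {
        window_size <- as.integer(f[2]); step <- as.integer(f[3])
      }
      next
    }
    body_idx <- c(body_idx, i)
  }
  rows <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  ncols <- lengths(rows)
  if (mode == "feature") {
    if (length(rows) && any(ncols != 5L)) {
      stopf("GDF feature rows need 5 columns; line %d has %d",
            body_idx[which(ncols != 5L)[1]], ncols[ncols != 5L][1])
    }
    feats <- lapply(seq_along(rows), function(k) {
      f <- rows[[k]]
      start <- as.integer(f[1]); end <- as.integer(f[2])
      if (is.na(start) || is.na(end)) {
        stopf("non-integer coordinates at line %d of %s", body_idx[k], path)
      }
      genomic_feature(seq_id, start, end, strand = f[3], label = f[4],
                      category = "custom",
                      color = if (f[5] == ".") NA_character_ else f[5])
    })
    features <- if (length(feats)) do.call(rbind, feats) else NULL
    return(feature_track(name, seq_id, features, seq_length = seq_length))
  }
  # property mode
  if (!length(rows)) stopf("GDF property file %s has no value rows", path)
  if (any(ncols != 3L)) {
    stopf("GDF property rows need 3 columns; line %d has %d",
          body_idx[which(ncols != 3L)[1]], ncols[ncols != 3L][1])
  }
  start <- as.integer(vapply(rows, `[`, character(1), 1))
  end <- as.integer(vapply(rows, `[`, character(1), 2))
  value <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 3)))
  if (any(is.na(value))) {
    stopf("non-numeric value column at line %d of %s",
          body_idx[which(is.na(value))[1]], path)
  }
  bad <- which(end < start)
  if (length(bad)) {
    stopf("window end < start at line %d of %s", body_idx[bad[1]], path)
  }
  if (is.na(window_size)) window_size <- end[1] - start[1] + 1L
  if (is.na(step)) step <- if (length(start) > 1L) start[2] - start[1] else window_size
  property_track(name, seq_id, window_size, start, value, step = step,
                 seq_length = seq_length)
}

#' Write a track to a GDF file
#'
#' Inverse of [read_gdf()]: the written file round-trips exactly.
#'
#' @param track A [feature_track()] or [property_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gdf <- function(track, path) {
  if (inherits(track, "feature_track")) {
    f <- track$features
    hdr <- c(sprintf("#gdf\tfeature\t%s\t%s", track$seq_id,
                     num_chr(as.numeric(track$seq_length))),
             sprintf("#name\t%s", track$name))
    body <- if (nrow(f)) {
      sprintf("%d\t%d\t%s\t%s\t%s", f$start, f$end, f$strand, f$label,
              ifelse(is.na(f$color), ".", f$color))
    } else character(0)
    writeLines(c(hdr, body), path, useBytes = TRUE)
  } else if (inherits(track, "property_track")) {
    ends <- pmin(track$starts + track$window_size - 1, track$seq_length)
    hdr <- c(sprintf("#gdf\tproperty\t%s\t%s", track$seq_id,
                     num_chr(track$seq_length)),
             sprintf("#name\t%s", track$name),
             sprintf("#window\t%d\t%d", track$window_size, track$step))
    body <- sprintf("%d\t%d\t%s", track$starts, as.integer(ends),
                    num_chr(track$values))
    writeLines(c(hdr, body), path, useBytes = TRUE)
  } else {
    stopf("write_gdf() needs a feature_track or property_track")
  }
  invisible(path)
}

#' Split CDS features into forward- and reverse-strand tracks
#'
#' Non-CDS features are ignored.  Strandless CDS features are assigned to
#' the forward track with a warning.
#'
#' @param features A data frame of genomic features (e.g. from
#'   [read_genbank()]).
#' @param seq_length Parent sequence length in bp (optional).
#' @return A list with `forward` and `reverse` [feature_track()]s.
#' @export
extract_strand_tracks <- function(features, seq_length = NA) {
  stopifnot(is.data.frame(features))
  cds <- features[features$category == "CDS", , drop = FALSE]
  seq_id <- if (nrow(features)) features$seq_id[1] else "unknown"
  n_dot <- sum(cds$strand == ".")
  if (n_dot > 0) {
    warnf("%d strandless CDS feature(s) assigned to the forward track", n_dot)
  }
  fwd <- cds[cds$strand %in% c("+", "."), , drop = FALSE]
  rev <- cds[cds$strand == "-", , drop = FALSE]
  list(forward = feature_track("CDS forward", seq_id, fwd, seq_length = seq_length),
       reverse = feature_track("CDS reverse", seq_id, rev, seq_length = seq_length))
}
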