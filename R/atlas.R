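# Genome-atlas SVG rendering: linear and circular track layouts, property
# styles (histogram / dots / gradient), feature tracks, legends, static
# track transforms and the caterpillar duplication device.
#
# Geometry conventions: the angle origin of circular layouts is 12 o'clock
# and angles grow clockwise; property values grow outward from the annulus
# baseline (set `invert = TRUE` on a track spec to grow inward).  Documents
# are assembled as text, then parsed once with xml2, so every returned
# atlas is well-formed XML.

LEGEND_W <- 240
ATLAS_MARGIN <- 40

#' Create a static track transform
#'
#' The exploratory manipulations (move, rotate, flip, caterpillar, radial
#' size) expressed as a static configuration applied at render time.
#'
#' @param dx,dy Translation in canvas units.
#' @param rotation Rotation in degrees, clockwise, in `[0, 360)`
#'   (circular layouts only).
#' @param flip_h,flip_v Mirror the track horizontally / vertically.
#' @param caterpillar Flank a linear track with two `<use>` replicas so
#'   content shifted off one canvas edge reappears at the other (linear
#'   layouts only).
#' @param radial_offset Radial displacement in canvas units (circular
#'   layouts; used to overlap tracks by changing their diameter).
#' @return An object of class `track_transform`.
#' @export
track_transform <- function(dx = 0, dy = 0, rotation = 0, flip_h = FALSE,
                            flip_v = FALSE, caterpillar = FALSE,
                            radial_offset = 0) {
  if (!is_number(rotation) || rotation < 0 || rotation >= 360) {
    stopf("rotation must be in [0, 360)")
  }
  structure(list(dx = dx, dy = dy, rotation = rotation,
                 flip_h = isTRUE(flip_h), flip_v = isTRUE(flip_v),
                 caterpillar = isTRUE(caterpillar),
                 radial_offset = radial_offset),
            class = "track_transform")
}

#' Compose two track transforms
#'
#' Applying `a` then `b` equals applying `compose_transforms(a, b)`:
#' translations and radial offsets add, rotations add modulo 360, flips
#' toggle, caterpillar is sticky.
#'
#' @param a,b `track_transform` objects.
#' @return A `track_transform`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "track_transform"), inherits(b, "track_transform"))
  track_transform(dx = a$dx + b$dx, dy = a$dy + b$dy,
                  rotation = (a$rotation + b$rotation) %% 360,
                  flip_h = xor(a$flip_h, b$flip_h),
                  flip_v = xor(a$flip_v, b$flip_v),
                  caterpillar = a$caterpillar || b$caterpillar,
                  radial_offset = a$radial_offset + b$radial_offset)
}

#' Create a track specification
#'
#' Pairs a data source with a drawing style.  `solid` is only valid for
#' feature tracks; `histogram`, `dots` and `gradient` only for property
#' tracks.
#'
#' @param source A [feature_track()] or [property_track()].
#' @param style One of `"solid"`, `"histogram"`, `"dots"`, `"gradient"`.
#' @param width Track width in canvas units.
#' @param opacity Color opacity in `[0, 1]`.
#' @param colors Two-color scheme `c(low, high)` used for the
#'   threshold split and the gradient ramp.
#' @param threshold Split value for the two-color scheme; default is the
#'   track mean.
#' @param transform A [track_transform()].
#' @param invert For circular property tracks, draw values growing inward.
#' @return An object of class `track_spec`.
#' @export
track_spec <- function(source, style, width = 30, opacity = 1,
                       colors = c("#2166ac", "#b2182b"), threshold = NULL,
                       transform = track_transform(), invert = FALSE) {
  if (!style %in% c("solid", "histogram", "dots", "gradient")) {
    stopf("unknown track style '%s'", style)
  }
  is_feat <- inherits(source, "feature_track")
  is_prop <- inherits(source, "property_track")
  if (!is_feat && !is_prop) stopf("track source must be a feature_track or property_track")
  if (is_feat && style != "solid") {
    stopf("style '%s' is only valid for property tracks; feature tracks use 'solid'", style)
  }
  if (is_prop && style == "solid") {
    stopf("style 'solid' is only valid for feature tracks")
  }
  if (!is_number(opacity) || opacity < 0 || opacity > 1) stopf("opacity must be in [0, 1]")
  stopifnot(inherits(transform, "track_transform"))
  structure(list(source = source, style = style, width = width,
                 opacity = opacity, colors = colors, threshold = threshold,
                 transform = transform, invert = isTRUE(invert)),
            class = "track_spec")
}

#' Create an atlas configuration
#'
#' @param layout `"linear"` or `"circular"`.
#' @param canvas_size Canvas size in units (width of the linear span /
#'   diameter budget of the circular atlas).
#' @param resolution Track resolution: the number of display units each
#'   property track is condensed into (default 3000).
#' @param spacer Units between adjacent tracks (default 10).
#' @param scale_mode `"proportional"` (spans proportional to bp length) or
#'   `"scale_independent"` (all sequences drawn at the same span).
#' @param tracks List of [track_spec()]s (at least one).
#' @param seed Seed for random palette assignment of uncolored features.
#' @return An object of class `atlas_config`.
#' @export
atlas_config <- function(layout = c("linear", "circular"), canvas_size = 1000,
                         resolution = 3000, spacer = 10,
                         scale_mode = c("proportional", "scale_independent"),
                         tracks = list(), seed = 1) {
  layout <- match.arg(layout)
  scale_mode <- match.arg(scale_mode)
  if (!is_number(canvas_size) || canvas_size <= 0) stopf("canvas_size must be positive")
  if (!is_count(resolution)) stopf("resolution must be a positive integer")
  if (!length(tracks)) stopf("an atlas needs at least one track")
  for (i in seq_along(tracks)) {
    if (!inherits(tracks[[i]], "track_spec")) stopf("tracks[%d] is not a track_spec", i)
    if (layout == "circular" && tracks[[i]]$transform$caterpillar) {
      stopf("tracks[%d]: caterpillar is only available for linear layouts", i)
    }
  }
  structure(list(layout = layout, canvas_size = canvas_size,
                 resolution = as.integer(resolution), spacer = spacer,
                 scale_mode = scale_mode, tracks = tracks, seed = seed),
            class = "atlas_config")
}

track_seq_length <- function(spec) {
  L <- spec$source$seq_length
  if (is.null(L) || is.na(L)) {
    if (inherits(spec$source, "feature_track") && nrow(spec$source$features)) {
      return(max(spec$source$features$end))
    }
    stopf("track '%s' has no sequence length", spec$source$name)
  }
  as.numeric(L)
}

#' Display lengths under a scaling mode
#'
#' `proportional` keeps true bp lengths, so drawn spans keep the length
#' ratios of the chromosomes; `scale_independent` discards the ratios and
#' maps every sequence onto an identical display length (the maximum), so
#' organisational patterns can be compared across genomes of different
#' sizes.
#'
#' @param lengths Numeric vector of sequence lengths in bp.
#' @param scale_mode `"proportional"` or `"scale_independent"`.
#' @return Numeric vector of display lengths, same order as `lengths`.
#' @export
scale_lengths <- function(lengths, scale_mode = c("proportional", "scale_independent")) {
  scale_mode <- match.arg(scale_mode)
  if (!length(lengths)) stopf("need at least one sequence length")
  if (scale_mode == "proportional") as.numeric(lengths)
  else rep(max(as.numeric(lengths)), length(lengths))
}

#' Style a property vector into drawable units
#'
#' Maps each value to the color and normalized geometry of one drawable
#' unit.  Histogram and dot styles use a two-color split at `threshold`
#' (default mean): `colors[2]` strictly above, `colors[1]` at or below; bar
#' heights are proportional to `|value - threshold|`.  The gradient style
#' interpolates the value linearly into the `colors[1] -> colors[2]` ramp,
#' the ramp ends marking the minimum and maximum values.
#'
#' @param values Finite numeric vector (one element per display unit).
#' @param style `"histogram"`, `"dots"` or `"gradient"`.
#' @param colors Two-color scheme `c(low, high)`.
#' @param threshold Split value; default `mean(values)`.
#' @return A data frame with one row per unit: `unit`, `value`, `color`,
#'   `frac` (value position in the min-max range) and `hfrac`
#'   (normalized bar height).
#' @export
style_property <- function(values, style = c("histogram", "dots", "gradient"),
                           colors = c("#2166ac", "#b2182b"), threshold = NULL) {
  style <- match.arg(style)
  if (!all(is.finite(values))) stopf("property values must be finite")
  if (is.null(threshold)) threshold <- mean(values)
  rng <- range(values)
  span <- diff(rng)
  frac <- if (span == 0) rep(0.5, length(values)) else (values - rng[1]) / span
  dev <- abs(values - threshold)
  hfrac <- if (max(dev) == 0) rep(0, length(values)) else dev / max(dev)
  color <- if (style == "gradient") {
    ramp <- grDevices::colorRamp(colors)
    grDevices::rgb(ramp(frac), maxColorValue = 255)
  } else {
    ifelse(values > threshold, colors[2], colors[1])
  }
  data.frame(unit = seq_along(values), value = values, color = color,
             frac = frac, hfrac = hfrac, stringsAsFactors = FALSE)
}

#' Default feature color palette
#'
#' Twenty distinct hex colors used for customized features that carry no
#' color of their own.
#' @return Character vector of hex colors.
#' @export
feature_palette <- function() {
  c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd", "#8c564b",
    "#e377c2", "#7f7f7f", "#bcbd22", "#17becf", "#aec7e8", "#ffbb78",
    "#98df8a", "#ff9896", "#c5b0d5", "#c49c94", "#f7b6d2", "#c7c7c7",
    "#dbdb8d", "#9edae5")
}

#' Assign colors to the features of a track
#'
#' Forward-strand CDS features are colored blue and reverse-strand CDS
#' red (the conventional atlas scheme).  Other features lacking an explicit
#' color receive palette colors drawn with a seeded generator, so the
#' assignment is reproducible.  Explicit colors are never touched.
#'
#' @param track A [feature_track()].
#' @param seed Integer seed for the palette draw.
#' @return The track with every feature colored.
#' @export
assign_feature_colors <- function(track, seed = 1) {
  stopifnot(inherits(track, "feature_track"))
  f <- track$features
  if (!nrow(f)) return(track)
  missing_col <- is.na(f$color) | f$color == ""
  is_cds <- f$category == "CDS"
  f$color[missing_col & is_cds & f$strand %in% c("+", ".")] <- "#0000FF"
  f$color[missing_col & is_cds & f$strand == "-"] <- "#FF0000"
  still <- which(is.na(f$color) | f$color == "")
  if (length(still)) {
    pal <- feature_palette()
    picks <- with_seed(seed, sample(pal, length(still), replace = TRUE))
    f$color[still] <- picks
  }
  track$features <- f
  track
}

# ---- geometry -------------------------------------------------------------

#' Linear layout geometry for one track
#'
#' Position `t` (bp) maps to
#' `x = left_margin + track_span * (t / L_display)`; tracks are stacked
#' top to bottom with `spacer` units between them.
#'
#' @param track A [track_spec()].
#' @param config An [atlas_config()] with `layout = "linear"`.
#' @param index Position of the track in the config (determines stacking).
#' @return A list with `x_of(t)` (bp to x-coordinate), `span` (drawn track
#'   span), `y_top`, `y_base` and `margin`.
#' @export
layout_linear <- function(track, config, index = 1) {
  stopifnot(inherits(config, "atlas_config"))
  if (config$layout != "linear") stopf("layout_linear() needs a linear atlas config")
  lens <- vapply(config$tracks, track_seq_length, numeric(1))
  disp <- scale_lengths(lens, config$scale_mode)
  full_span <- config$canvas_size - 2 * ATLAS_MARGIN
  track_span <- full_span * disp[index] / max(disp)
  widths <- vapply(config$tracks, function(t) t$width, numeric(1))
  y_top <- ATLAS_MARGIN +
    if (index > 1) sum(widths[seq_len(index - 1)]) + (index - 1) * config$spacer else 0
  L_display <- disp[index]
  list(kind = "linear",
       x_of = function(t) ATLAS_MARGIN + track_span * (t / L_display),
       span = track_span, L_display = L_display,
       y_top = y_top, y_base = y_top + config$tracks[[index]]$width,
       margin = ATLAS_MARGIN)
}

#' Circular layout geometry for one track
#'
#' Position `t` (bp) maps to angle `360 * t / L_display` degrees, measured
#' clockwise from 12 o'clock; each track occupies an annulus, stacked
#' outward in configuration order, and property values extend radially.
#'
#' @inheritParams layout_linear
#' @return A list with `center`, `r_inner`, `r_outer`, `angle_of(t)`
#'   (degrees, including the track's rotation transform) and
#'   `point_of(t, r)` (xy coordinates).
#' @export
layout_circular <- function(track, config, index = 1) {
  stopifnot(inherits(config, "atlas_config"))
  if (config$layout != "circular") stopf("layout_circular() needs a circular atlas config")
  lens <- vapply(config$tracks, track_seq_length, numeric(1))
  disp <- scale_lengths(lens, config$scale_mode)
  cx <- config$canvas_size / 2
  cy <- config$canvas_size / 2
  widths <- vapply(config$tracks, function(t) t$width, numeric(1))
  r0 <- max(30, config$canvas_size / 2 -
              sum(widths) - config$spacer * length(widths) - ATLAS_MARGIN)
  r_inner <- r0 +
    (if (index > 1) sum(widths[seq_len(index - 1)]) + (index - 1) * config$spacer else 0) +
    config$tracks[[index]]$transform$radial_offset
  rot <- config$tracks[[index]]$transform$rotation
  L_display <- disp[index]
  angle_of <- function(t) (360 * t / L_display + rot) %% 360
  point_of <- function(t, r) {
    a <- angle_of(t) * pi / 180
    c(x = cx + r * sin(a), y = cy - r * cos(a))
  }
  list(kind = "circular", center = c(x = cx, y = cy),
       r_inner = r_inner, r_outer = r_inner + config$tracks[[index]]$width,
       L_display = L_display, angle_of = angle_of, point_of = point_of)
}

# ---- SVG assembly ---------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

fmt_u <- function(x) sprintf("%.8g", x)

svg_tag <- function(tag, attrs = character(0), body = NULL) {
  a <- if (length(attrs)) {
    paste0(" ", paste(sprintf('%s="%s"', names(attrs), attrs), collapse = " "))
  } else ""
  if (is.null(body)) sprintf("<%s%s/>", tag, a)
  else sprintf("<%s%s>%s</%s>", tag, a, paste(body, collapse = ""), tag)
}

arc_point <- function(cx, cy, r, a_deg) {
  a <- a_deg * pi / 180
  c(cx + r * sin(a), cy - r * cos(a))
}

# annular sector path between angles a0 < a1 (degrees clockwise from top)
annular_sector <- function(cx, cy, r0, r1, a0, a1) {
  sweep <- min(a1 - a0, 359.99)
  a1 <- a0 + sweep
  large <- if (sweep > 180) 1 else 0
  p1 <- arc_point(cx, cy, r1, a0); p2 <- arc_point(cx, cy, r1, a1)
  p3 <- arc_point(cx, cy, r0, a1); p4 <- arc_point(cx, cy, r0, a0)
  sprintf("M%s,%s A%s,%s 0 %d 1 %s,%s L%s,%s A%s,%s 0 %d 0 %s,%s Z",
          fmt_u(p1[1]), fmt_u(p1[2]), fmt_u(r1), fmt_u(r1), large,
          fmt_u(p2[1]), fmt_u(p2[2]), fmt_u(p3[1]), fmt_u(p3[2]),
          fmt_u(r0), fmt_u(r0), large, fmt_u(p4[1]), fmt_u(p4[2]))
}

# condense a property track to `resolution` display units
track_display_values <- function(track, resolution) {
  L <- track$seq_length
  lo <- as.numeric(track$starts) - 1
  hi <- c(lo[-1], L)
  hi <- pmin(hi, as.numeric(track$starts) + track$window_size - 1)
  resample_piecewise(lo, hi, track$values, L, resolution)
}

render_property_linear <- function(spec, geo, resolution) {
  vals <- track_display_values(spec$source, resolution)
  sty <- style_property(vals, spec$style, spec$colors, spec$threshold)
  bw <- geo$span / resolution
  x0 <- geo$x_of(0)
  els <- character(resolution)
  for (i in seq_len(resolution)) {
    x <- x0 + (i - 1) * bw
    if (spec$style == "histogram") {
      h <- max(sty$hfrac[i] * spec$width, 0.01)
      els[i] <- svg_tag("rect", c(x = fmt_u(x), y = fmt_u(geo$y_base - h),
                                  width = fmt_u(bw), height = fmt_u(h),
                                  fill = sty$color[i]))
    } else if (spec$style == "dots") {
      els[i] <- svg_tag("circle", c(cx = fmt_u(x + bw / 2),
                                    cy = fmt_u(geo$y_base - sty$frac[i] * spec$width),
                                    r = fmt_u(max(bw * 0.45, 0.4)),
                                    fill = sty$color[i]))
    } else {
      els[i] <- svg_tag("rect", c(x = fmt_u(x), y = fmt_u(geo$y_top),
                                  width = fmt_u(bw), height = fmt_u(spec$width),
                                  fill = sty$color[i]))
    }
  }
  els
}

render_property_circular <- function(spec, geo, resolution) {
  vals <- track_display_values(spec$source, resolution)
  sty <- style_property(vals, spec$style, spec$colors, spec$threshold)
  cx <- geo$center[["x"]]; cy <- geo$center[["y"]]
  da <- 360 / resolution
  w <- spec$width
  base_r <- if (spec$invert) geo$r_outer else geo$r_inner
  dir <- if (spec$invert) -1 else 1
  els <- character(resolution)
  for (i in seq_len(resolution)) {
    a0 <- (i - 1) * da
    if (spec$style == "histogram") {
      h <- max(sty$hfrac[i] * w, 0.01)
      rr <- sort(c(base_r, base_r + dir * h))
      els[i] <- svg_tag("path", c(d = annular_sector(cx, cy, rr[1], rr[2], a0, a0 + da),
                                  fill = sty$color[i]))
    } else if (spec$style == "dots") {
      p <- arc_point(cx, cy, base_r + dir * sty$frac[i] * w, a0 + da / 2)
      els[i] <- svg_tag("circle", c(cx = fmt_u(p[1]), cy = fmt_u(p[2]),
                                    r = fmt_u(max(pi * geo$r_inner * da / 360 * 0.9, 0.4)),
                                    fill = sty$color[i]))
    } else {
      els[i] <- svg_tag("path", c(d = annular_sector(cx, cy, geo$r_inner, geo$r_outer,
                                                     a0, a0 + da),
                                  fill = sty$color[i]))
    }
  }
  els
}

render_features_linear <- function(spec, geo) {
  f <- spec$source$features
  if (!nrow(f)) return(character(0))
  L <- track_seq_length(spec)
  vapply(seq_len(nrow(f)), function(i) {
    s <- f$start[i]; e <- f$end[i]
    col <- if (is.na(f$color[i])) "#808080" else f$color[i]
    if (e >= s) {
      svg_tag("rect", c(x = fmt_u(geo$x_of(s - 1)), y = fmt_u(geo$y_top),
                        width = fmt_u(max(geo$x_of(e) - geo$x_of(s - 1), 0.1)),
                        height = fmt_u(spec$width), fill = col,
                        class = "feature"))
    } else {
      # origin-spanning: one path with two rectangular subpaths
      x1 <- geo$x_of(s - 1); x2 <- geo$x_of(L)
      x3 <- geo$x_of(0); x4 <- geo$x_of(e)
      d <- sprintf("M%s,%s H%s V%s H%s Z M%s,%s H%s V%s H%s Z",
                   fmt_u(x1), fmt_u(geo$y_top), fmt_u(x2), fmt_u(geo$y_base), fmt_u(x1),
                   fmt_u(x3), fmt_u(geo$y_top), fmt_u(x4), fmt_u(geo$y_base), fmt_u(x3))
      svg_tag("path", c(d = d, fill = col, class = "feature"))
    }
  }, character(1))
}

render_features_circular <- function(spec, geo) {
  f <- spec$source$features
  if (!nrow(f)) return(character(0))
  L <- track_seq_length(spec)
  cx <- geo$center[["x"]]; cy <- geo$center[["y"]]
  vapply(seq_len(nrow(f)), function(i) {
    s <- f$start[i]; e <- f$end[i]
    if (e < s) e <- e + L  # origin-spanning wraps natively in angle space
    a0 <- 360 * (s - 1) / L
    a1 <- 360 * e / L
    col <- if (is.na(f$color[i])) "#808080" else f$color[i]
    svg_tag("path", c(d = annular_sector(cx, cy, geo$r_inner, geo$r_outer, a0, a1),
                      fill = col, class = "feature"))
  }, character(1))
}

track_transform_attr <- function(spec, geo, config) {
  tr <- spec$transform
  parts <- character(0)
  if (tr$dx != 0 || tr$dy != 0) {
    parts <- c(parts, sprintf("translate(%s,%s)", fmt_u(tr$dx), fmt_u(tr$dy)))
  }
  if (geo$kind == "circular") {
    cx <- geo$center[["x"]]; cy <- geo$center[["y"]]
    # rotation is baked into angle_of(); only flips need an SVG transform
    if (tr$flip_h) parts <- c(parts, sprintf("translate(%s,0) scale(-1,1)", fmt_u(2 * cx)))
    if (tr$flip_v) parts <- c(parts, sprintf("translate(0,%s) scale(1,-1)", fmt_u(2 * cy)))
  } else {
    xc <- geo$x_of(0) + geo$span / 2
    yc <- (geo$y_top + geo$y_base) / 2
    if (tr$flip_h) parts <- c(parts, sprintf("translate(%s,0) scale(-1,1)", fmt_u(2 * xc)))
    if (tr$flip_v) parts <- c(parts, sprintf("translate(0,%s) scale(1,-1)", fmt_u(2 * yc)))
  }
  paste(parts, collapse = " ")
}

render_legend <- function(spec, index, x, y) {
  src <- spec$source
  w <- LEGEND_W - 20; h <- 64
  body <- c(svg_tag("rect", c(x = fmt_u(x), y = fmt_u(y), width = fmt_u(w),
                              height = fmt_u(h), fill = "none",
                              stroke = "#444444", "stroke-width" = "0.8")),
            svg_tag("text", c(x = fmt_u(x + w / 2), y = fmt_u(y + 14),
                              "text-anchor" = "middle", "font-size" = "11"),
                    xml_escape(src$name)))
  if (inherits(src, "property_track")) {
    s <- src$stats
    fmtn <- function(v) xml_escape(format(signif(v, 4)))
    body <- c(body,
      svg_tag("text", c(x = fmt_u(x + 4), y = fmt_u(y + 28), "font-size" = "9"),
              paste0("min ", fmtn(s$min))),
      svg_tag("text", c(x = fmt_u(x + w - 4), y = fmt_u(y + 28),
                        "text-anchor" = "end", "font-size" = "9"),
              paste0("max ", fmtn(s$max))),
      svg_tag("text", c(x = fmt_u(x + 4), y = fmt_u(y + 44), "font-size" = "9"),
              paste0("mean ", fmtn(s$mean))),
      svg_tag("text", c(x = fmt_u(x + w - 4), y = fmt_u(y + 44),
                        "text-anchor" = "end", "font-size" = "9"),
              paste0("sd ", fmtn(s$sd))),
      svg_tag("text", c(x = fmt_u(x + w / 2), y = fmt_u(y + 58),
                        "text-anchor" = "middle", "font-size" = "9"),
              sprintf("window size %d bp", src$window_size)))
  } else {
    body <- c(body,
      svg_tag("text", c(x = fmt_u(x + 4), y = fmt_u(y + 32), "font-size" = "9"),
              sprintf("%d features", nrow(src$features))))
  }
  svg_tag("g", c(class = "legend", id = sprintf("legend-%d", index)), body)
}

#' Render a genome atlas to SVG
#'
#' Produces a standalone SVG 1.1 document: one named group per configured
#' track (in order), a legend group per track on the right-hand panel
#' (min/max/mean/sd at the legend corners, window size below), property
#' tracks condensed to the configured resolution, and static transforms
#' (move/rotate/flip/caterpillar) applied.  All validation happens before
#' any drawing.
#'
#' @param config An [atlas_config()].
#' @param path Optional output path; when given, the document is written
#'   there.
#' @return An `xml2` document (invisibly when `path` is given).
#' @export
render_atlas <- function(config, path = NULL) {
  stopifnot(inherits(config, "atlas_config"))
  # validate every pairing before drawing anything
  for (i in seq_along(config$tracks)) {
    sp <- config$tracks[[i]]
    if (!inherits(sp, "track_spec")) stopf("tracks[%d] is not a track_spec", i)
    if (config$layout == "circular" && sp$transform$caterpillar) {
      stopf("tracks[%d]: caterpillar requested on a circular layout", i)
    }
  }
  n <- length(config$tracks)
  widths <- vapply(config$tracks, function(t) t$width, numeric(1))
  height <- if (config$layout == "linear") {
    2 * ATLAS_MARGIN + sum(widths) + (n - 1) * config$spacer
  } else {
    config$canvas_size
  }
  height <- max(height, 30 + n * 74)
  width <- config$canvas_size + LEGEND_W

  groups <- character(0)
  for (i in seq_len(n)) {
    sp <- config$tracks[[i]]
    if (inherits(sp$source, "feature_track")) {
      sp$source <- assign_feature_colors(sp$source, seed = config$seed + i)
    }
    geo <- if (config$layout == "linear") layout_linear(sp, config, i)
           else layout_circular(sp, config, i)
    els <- if (inherits(sp$source, "property_track")) {
      if (config$layout == "linear") render_property_linear(sp, geo, config$resolution)
      else render_property_circular(sp, geo, config$resolution)
    } else {
      if (config$layout == "linear") render_features_linear(sp, geo)
      else render_features_circular(sp, geo)
    }
    tattr <- track_transform_attr(sp, geo, config)
    content_attrs <- c(id = sprintf("track-%d-content", i))
    if (nzchar(tattr)) content_attrs <- c(content_attrs, transform = tattr)
    content <- svg_tag("g", content_attrs, c(els, ""))
    kids <- content
    if (config$layout == "linear" && sp$transform$caterpillar) {
      kids <- c(kids, caterpillar_uses(i, geo$span))
    }
    groups <- c(groups, svg_tag("g", c(id = sprintf("track-%d", i),
                                       class = "track",
                                       opacity = fmt_u(sp$opacity)),
                                kids))
  }
  legends <- vapply(seq_len(n), function(i) {
    render_legend(config$tracks[[i]], i, config$canvas_size + 10,
                  20 + (i - 1) * 74)
  }, character(1))

  doc_txt <- svg_tag("svg",
    c(xmlns = "http://www.w3.org/2000/svg",
      "xmlns:xlink" = "http://www.w3.org/1999/xlink",
      version = "1.1", width = fmt_u(width), height = fmt_u(height),
      viewBox = sprintf("0 0 %s %s", fmt_u(width), fmt_u(height))),
    c(svg_tag("rect", c(x = "0", y = "0", width = fmt_u(width),
                        height = fmt_u(height), fill = "#ffffff")),
      groups, legends))
  doc <- xml2::read_xml(doc_txt)
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

caterpillar_uses <- function(index, span) {
  href <- sprintf("#track-%d-content", index)
  c(svg_tag("use", c("xlink:href" = href,
                     transform = sprintf("translate(%s,0)", fmt_u(-span)))),
    svg_tag("use", c("xlink:href" = href,
                     transform = sprintf("translate(%s,0)", fmt_u(span)))))
}

#' Flank a linear track with caterpillar replicas
#'
#' Implements the caterpillar device: the track's content group is
#' referenced twice more with `<use>` elements translated one full span to
#' the left and to the right, so content shifted off one canvas edge
#' reappears at the other and a circular chromosome keeps its wrap-around
#' behaviour in a linear layout.
#'
#' @param doc An SVG document produced by [render_atlas()].
#' @param index Track index (1-based) to duplicate.
#' @param span The track's drawn span in canvas units.
#' @param layout The atlas layout; requesting caterpillar on a circular
#'   layout is an error.
#' @return The modified document.
#' @export
apply_caterpillar <- function(doc, index, span, layout = "linear") {
  if (layout != "linear") stopf("caterpillar is only available for linear layouts")
  grp <- xml2::xml_find_first(doc, sprintf("//*[@id='track-%d']", index))
  if (inherits(grp, "xml_missing")) stopf("no track group with index %d", index)
  href <- sprintf("#track-%d-content", index)
  xml2::xml_add_child(grp, "use", "xlink:href" = href,
                      transform = sprintf("translate(%s,0)", fmt_u(-span)))
  xml2::xml_add_child(grp, "use", "xlink:href" = href,
                      transform = sprintf("translate(%s,0)", fmt_u(span)))
  doc
}
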