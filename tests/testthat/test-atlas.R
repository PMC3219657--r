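# SVG atlas rendering: structure, geometry, styles, transforms.

prop_track_fixture <- function(n = 50, seed = 1, name = "p", L = n * 1000) {
  set.seed(seed)
  property_track(name, "chr", 1000, seq(1, length.out = n, by = 1000),
                 rnorm(n), seq_length = L)
}

feat_track_fixture <- function(name = "f", L = 50000) {
  feats <- rbind(
    genomic_feature("chr", max(1, round(L * 0.01)), round(L * 0.1), "+", "a", "CDS"),
    genomic_feature("chr", round(L * 0.4), round(L * 0.6), "-", "b", "CDS"))
  feature_track(name, "chr", feats, seq_length = L)
}

test_that("a linear atlas has one track group and one legend per track", {
  cfg <- atlas_config("linear", canvas_size = 800, resolution = 100,
                      tracks = list(track_spec(feat_track_fixture(), "solid"),
                                    track_spec(prop_track_fixture(), "histogram")))
  doc <- render_atlas(cfg)
  expect_equal(length(svg_track_groups(doc)), 2L)
  expect_equal(length(svg_legend_groups(doc)), 2L)
  root <- xml2::xml_root(doc)
  expect_equal(xml2::xml_name(root), "svg")
  expect_equal(xml2::xml_attr(root, "version"), "1.1")
})

test_that("a 3-genome x 4-track circular atlas yields 12 track groups", {
  # three chromosomes of different lengths, scale-independent, canvas 1000,
  # resolution 3000 (the classic three-Mycoplasma demonstration layout)
  lens <- c(50000, 29000, 41000)
  tracks <- list()
  for (g in 1:3) {
    L <- lens[g]
    tracks <- c(tracks, list(
      track_spec(feat_track_fixture(sprintf("g%d fwd", g), L), "solid"),
      track_spec(feat_track_fixture(sprintf("g%d rev", g), L), "solid"),
      track_spec(prop_track_fixture(50, g, sprintf("g%d skew", g), L), "dots"),
      track_spec(prop_track_fixture(50, g + 10, sprintf("g%d cumskew", g), L),
                 "dots")))
  }
  cfg <- atlas_config("circular", canvas_size = 1000, resolution = 3000,
                      scale_mode = "scale_independent", tracks = tracks)
  doc <- render_atlas(cfg)
  expect_equal(length(svg_track_groups(doc)), 12L)
  expect_equal(length(svg_legend_groups(doc)), 12L)
})

test_that("an atlas with no tracks is rejected", {
  expect_error(atlas_config("linear", tracks = list()), "at least one")
})

test_that("style/track pairing is validated before drawing", {
  expect_error(track_spec(prop_track_fixture(), "solid"), "feature")
  expect_error(track_spec(feat_track_fixture(), "histogram"), "property")
  expect_error(track_spec(feat_track_fixture(), "sparkline"), "unknown")
})

test_that("property tracks contribute exactly `resolution` drawable units", {
  for (style in c("histogram", "dots", "gradient")) {
    cfg <- atlas_config("linear", canvas_size = 500, resolution = 64,
                        tracks = list(track_spec(prop_track_fixture(37), style)))
    doc <- render_atlas(cfg)
    units <- xml2::xml_find_all(doc,
      "//*[@id='track-1-content']/*[local-name()='rect' or local-name()='circle' or local-name()='path']")
    expect_equal(length(units), 64L)
  }
  # circular layouts draw the same number of units
  cfg2 <- atlas_config("circular", canvas_size = 600, resolution = 48,
                       tracks = list(track_spec(prop_track_fixture(37), "histogram")))
  units2 <- xml2::xml_find_all(render_atlas(cfg2), "//*[@id='track-1-content']/*")
  expect_equal(length(units2), 48L)
})

test_that("circular geometry puts position 0 at 12 o'clock, clockwise", {
  cfg <- atlas_config("circular", canvas_size = 1000, resolution = 100,
                      tracks = list(track_spec(prop_track_fixture(50), "dots")))
  geo <- layout_circular(cfg$tracks[[1]], cfg, 1)
  L <- geo$L_display
  expect_equal(geo$angle_of(0), 0)
  p_top <- geo$point_of(0, 100)
  expect_equal(unname(p_top), c(500, 400))          # straight up from center
  expect_equal(geo$angle_of(L / 4), 90)              # 3 o'clock
  p_right <- geo$point_of(L / 4, 100)
  expect_equal(unname(p_right), c(600, 500))

  # a 90-degree clockwise rotation moves the quarter point to 6 o'clock
  cfg$tracks[[1]]$transform <- track_transform(rotation = 90)
  geo_rot <- layout_circular(cfg$tracks[[1]], cfg, 1)
  expect_equal(geo_rot$angle_of(L / 4), 180)
  expect_equal(unname(geo_rot$point_of(L / 4, 100)), c(500, 600))
})

test_that("linear geometry stacks tracks with the configured spacer", {
  cfg <- atlas_config("linear", canvas_size = 2000, resolution = 100, spacer = 45,
                      tracks = list(track_spec(prop_track_fixture(50), "histogram",
                                               width = 30),
                                    track_spec(prop_track_fixture(50, 2), "histogram",
                                               width = 30)))
  g1 <- layout_linear(cfg$tracks[[1]], cfg, 1)
  g2 <- layout_linear(cfg$tracks[[2]], cfg, 2)
  expect_equal(g2$y_top - g1$y_base, 45)
  expect_equal(g1$x_of(g1$L_display), g1$x_of(0) + g1$span)  # right edge

  # dx translation appears on the content group transform
  cfg$tracks[[1]]$transform <- track_transform(dx = 120)
  doc <- render_atlas(cfg)
  tr <- xml2::xml_attr(xml2::xml_find_first(doc, "//*[@id='track-1-content']"),
                       "transform")
  expect_match(tr, "translate\\(120,0\\)")
})

test_that("caterpillar triples the drawn instances with full-span flanks", {
  cfg <- atlas_config("linear", canvas_size = 1000, resolution = 50,
                      tracks = list(track_spec(prop_track_fixture(50), "histogram",
                                               transform = track_transform(caterpillar = TRUE))))
  doc <- render_atlas(cfg)
  grp <- xml2::xml_find_first(doc, "//*[@id='track-1']")
  kids <- xml2::xml_children(grp)
  expect_equal(length(kids), 3L)  # content + 2 <use> replicas
  uses <- kids[xml2::xml_name(kids) == "use"]
  expect_equal(length(uses), 2L)
  geo <- layout_linear(cfg$tracks[[1]], cfg, 1)
  tfs <- xml2::xml_attr(uses, "transform")
  expect_setequal(tfs, sprintf("translate(%g,0)", c(-geo$span, geo$span)))
  # a left shift of 10% of the span leaves the right replica covering
  # [0.9 span, 1.9 span): its left 10% sits inside the original span
  shift <- -0.1 * geo$span
  right_replica_start <- shift + geo$span
  expect_lt(right_replica_start, geo$span)
  expect_gte(right_replica_start, 0.89 * geo$span)

  # caterpillar on a circular layout is rejected
  expect_error(
    atlas_config("circular", tracks = list(
      track_spec(prop_track_fixture(50), "dots",
                 transform = track_transform(caterpillar = TRUE)))),
    "caterpillar")
})

test_that("scale modes control display lengths", {
  lens <- c(1e6, 0.58e6, 0.82e6)
  eq <- scale_lengths(lens, "scale_independent")
  expect_true(all(eq == eq[1]))
  pr <- scale_lengths(c(2e6, 1e6), "proportional")
  expect_equal(pr[1] / pr[2], 2)
  expect_equal(scale_lengths(5e5, "proportional"),
               scale_lengths(5e5, "scale_independent"))
})

test_that("property styling follows the two-color and gradient rules", {
  v <- c(1, 2, 3, 10)
  sty <- style_property(v, "histogram", c("#000088", "#880000"), threshold = 5)
  expect_equal(sty$color, c("#000088", "#000088", "#000088", "#880000"))
  # bar heights proportional to |value - threshold|
  expect_equal(sty$hfrac, abs(v - 5) / max(abs(v - 5)))

  shifted <- style_property(v + 100, "dots", c("#000088", "#880000"),
                            threshold = 5)  # all above -> single color
  expect_true(all(shifted$color == "#880000"))

  const <- style_property(rep(4, 6), "gradient", c("#000000", "#ffffff"))
  expect_equal(length(unique(const$color)), 1L)
  expect_true(all(abs(grDevices::col2rgb(const$color[1]) - 127.5) <= 1))  # mid-ramp

  grad <- style_property(c(0, 1), "gradient", c("#000000", "#ffffff"))
  expect_equal(toupper(grad$color), c("#000000", "#FFFFFF"))  # darkest ends
})

test_that("feature coloring is conventional, seeded and non-destructive", {
  fwd <- feature_track("cds+", "chr",
                       rbind(genomic_feature("chr", 1, 10, "+", "", "CDS"),
                             genomic_feature("chr", 21, 30, "+", "", "CDS")), 100)
  expect_true(all(assign_feature_colors(fwd)$features$color == "#0000FF"))
  rev <- feature_track("cds-", "chr",
                       rbind(genomic_feature("chr", 1, 10, "-", "", "CDS")), 100)
  expect_true(all(assign_feature_colors(rev)$features$color == "#FF0000"))

  cust <- feature_track("c", "chr", rbind(
    genomic_feature("chr", 1, 10, "+", "", "island"),
    genomic_feature("chr", 21, 30, "+", "", "island"),
    genomic_feature("chr", 41, 50, "+", "", "island", "#123456")), 100)
  a <- assign_feature_colors(cust, seed = 7)
  b <- assign_feature_colors(cust, seed = 7)
  expect_identical(a$features$color, b$features$color)
  expect_equal(a$features$color[3], "#123456")
  expect_true(all(a$features$color[1:2] %in% feature_palette()))
})

test_that("transforms compose as a group action", {
  f <- track_transform(flip_h = TRUE)
  expect_false(compose_transforms(f, f)$flip_h)
  r1 <- track_transform(rotation = 250)
  r2 <- track_transform(rotation = 200)
  expect_equal(compose_transforms(r1, r2)$rotation, 90)
  id <- track_transform()
  moved <- track_transform(dx = 5, dy = -3)
  expect_equal(compose_transforms(moved, id), moved)
})
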