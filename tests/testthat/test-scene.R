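test_that("stripe boundaries: zero jitter gives the nominal grid", {
  sf <- sample_stripe_boundaries(jitter_sd = 0, seed = 1)
  expect_identical(sf$boundaries, as.integer(128 * 1:7))
})

test_that("stripe field is deterministic under a seed and keeps the midline", {
  a <- sample_stripe_boundaries(seed = 7)
  b <- sample_stripe_boundaries(seed = 7)
  expect_identical(a, b)
  for (s in 1:50) {
    sf <- sample_stripe_boundaries(seed = s)
    expect_true(512 %in% sf$boundaries)
    expect_true(all(diff(sf$boundaries) > 0))
    expect_length(sf$boundaries, 7L)
  }
})

test_that("colour order is a fair, seeded coin", {
  expect_identical(sample_colour_order(seed = 3), sample_colour_order(seed = 3))
  orders <- vapply(1:2000, function(s) sample_colour_order(seed = s),
                   character(1))
  expect_true(all(orders %in% c("AB_start", "BA_start")))
  frac <- mean(orders == "AB_start")
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("squares: 4 per non-midline boundary, offsets in range, no overlap", {
  for (s in 1:25) {
    sf <- sample_stripe_boundaries(seed = s)
    for (side in c(32L, 64L)) {
      sq <- place_squares(sf, side, seed = s)
      expect_equal(nrow(sq), 24L)
      expect_false(512 %in% sq$boundary_x)
      expect_true(all(table(sq$boundary_x) == 4L))
      u <- sq$top_y - sq$quadrant * 192
      expect_true(all(u >= 1 & u <= 192 - 2 * side))
      expect_false(camobreak:::squares_overlap(sq))
    }
  }
  sf <- sample_stripe_boundaries(seed = 1)
  expect_error(place_squares(sf, 96), "32 or 64")
})

test_that("targets obey the treatment placement rules", {
  for (s in 1:40) {
    sf <- sample_stripe_boundaries(seed = s)
    sq <- place_squares(sf, if (s %% 2) 32L else 64L, seed = s + 100)
    for (tr in c("Dark", "Light", "Stripe", "Square", "Border")) {
      tg <- place_target(sf, sq, tr, seed = s)
      # whole disc strictly inside one screen half
      expect_true(tg$centre_x + 8 <= 511 || tg$centre_x - 8 >= 513)
      px <- camobreak:::disc_pixels(tg$centre_x, tg$centre_y)
      tn <- camobreak:::scene_tone(sf, sq, px$x, px$y)
      if (tr %in% c("Dark", "Light")) {
        expect_false(tg$split)
        expect_true(all(tn == if (tr == "Dark") 0L else 1L))
        # clear of every square
        hit <- any(tg$centre_x + 8 > sq$boundary_x - sq$side / 2 &
                   tg$centre_x - 8 < sq$boundary_x + sq$side / 2 &
                   tg$centre_y + 8 > sq$top_y &
                   tg$centre_y - 8 < sq$top_y + sq$side)
        expect_false(hit)
      } else {
        expect_true(tg$split)
        left <- tn[px$x < tg$centre_x]
        right <- tn[px$x >= tg$centre_x]
        expect_length(unique(left), 1L)
        expect_length(unique(right), 1L)
        expect_false(left[1] == right[1])
      }
      if (tr == "Stripe") expect_true(tg$centre_x %in%
                                        setdiff(sf$boundaries, 512L))
      if (tr == "Square") expect_true(tg$centre_x %in% sq$boundary_x)
      if (tr == "Border") {
        edges <- c(sq$boundary_x - sq$side / 2, sq$boundary_x + sq$side / 2)
        expect_true(tg$centre_x %in% edges)
      }
    }
  }
})

test_that("renderer paints two tones plus a 10%-lighter 16 px target", {
  sc <- build_scene("Dark", "small", seed = 11)
  rend <- render_scene(sc)
  expect_equal(dim(rend$raster), c(768, 1024, 3))
  vals <- sort(unique(as.vector(rend$raster[, , 1])))
  expect_equal(vals, c(0.40, 0.40 * 1.10, 0.60), tolerance = 1e-12)
  expect_false(rend$metadata$gamut_clipped)
  # target pixels are exactly lighten_factor times the dark tone
  px <- camobreak:::disc_pixels(sc$target$centre_x, sc$target$centre_y)
  tvals <- rend$raster[cbind(px$y + 1L, px$x + 1L, 1L)]
  expect_true(all(abs(tvals / 0.40 - 1.10) < 1e-12))
  # widest row of the disc is exactly 16 px
  widths <- tapply(px$x, px$y, function(x) diff(range(x)) + 1L)
  expect_equal(max(widths), 16L)
  # without the target the raster holds exactly the two scene tones
  sc$palette$lighten_factor <- 1 + 1e-15
  rend2 <- render_scene(sc)
  expect_equal(length(unique(round(as.vector(rend2$raster[, , 1]), 6))), 2L)
})

test_that("bi-tone treatments share identical local contrast", {
  # the design's central property: the two tones flanking the target
  # boundary are the same pair in Stripe, Square and Border scenes
  pairs <- lapply(c("Stripe", "Square", "Border"), function(tr) {
    sc <- build_scene(tr, "large", seed = 23)
    px <- camobreak:::disc_pixels(sc$target$centre_x, sc$target$centre_y)
    tn <- camobreak:::scene_tone(sc$stripes, sc$squares, px$x, px$y)
    sort(unique(tn))
  })
  for (p in pairs) expect_identical(p, c(0L, 1L))
})

test_that("scene construction is bit-identical under a fixed seed", {
  a <- render_scene(build_scene("Border", "large", seed = 5))
  b <- render_scene(build_scene("Border", "large", seed = 5))
  expect_identical(a$raster, b$raster)
  expect_identical(a$metadata, b$metadata)
})

test_that("jitter statistics converge to mean 0, SD 16", {
  offs <- unlist(lapply(1:2000, function(s) {
    sf <- sample_stripe_boundaries(seed = s)
    sf$boundaries[-4] - 128 * c(1:3, 5:7)
  }))
  expect_lt(abs(mean(offs)), 0.5)
  expect_lt(abs(sd(offs) - 16), 0.5)
})

test_that("scene files round-trip to PNG/PGM with JSON ground truth", {
  sc <- build_scene("Square", "small", seed = 31)
  d <- withr::local_tempdir()
  png_path <- file.path(d, "scene.png")
  write_scene(sc, png_path)
  expect_true(file.exists(png_path))
  meta <- jsonlite::read_json(file.path(d, "scene.json"))
  expect_equal(meta$treatment, "Square")
  expect_equal(meta$answer_side, sc$target$screen_side)
  img <- png::readPNG(png_path)
  expect_equal(dim(img), c(768, 1024, 3))
  pgm_path <- file.path(d, "scene.pgm")
  write_scene(sc, pgm_path, metadata = FALSE)
  expect_true(file.exists(pgm_path))
  expect_identical(readLines(pgm_path, n = 1), "P2")
})
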