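#' Sample the striped background geometry
#'
#' Displays are 1024 x 768 px with eight vertical stripes: four either side
#' of the midline, which is itself always a colour boundary. The seven
#' interior boundaries sit nominally at 128 px intervals; the six
#' non-midline boundaries are jittered by independent normal draws
#' (SD 16 px by default) and rounded to the pixel grid, while the midline
#' (x = 512) is a fixed design anchor and is never jittered. If a jitter
#' draw breaks the strict left-to-right ordering the whole field is
#' redrawn, which preserves the normal marginal distribution of offsets.
#'
#' @param width Display width in pixels (must be divisible by
#'   `nominal_interval`).
#' @param nominal_interval Nominal stripe width in pixels.
#' @param jitter_sd Standard deviation of the boundary jitter in pixels.
#' @param seed Optional integer seed.
#' @return An object of class `camo_stripes`: list with integer
#'   `boundaries` (length 7, strictly increasing, midline included),
#'   `colour_order` (`"AB_start"` or `"BA_start"`), `nominal_interval`,
#'   `jitter_sd`, `width`.
#' @examples
#' sample_stripe_boundaries(jitter_sd = 0)$boundaries  # 128, 256, ..., 896
#' @export
sample_stripe_boundaries <- function(width = 1024, nominal_interval = 128,
                                     jitter_sd = 16, seed = NULL) {
  if (nominal_interval <= 0) stop("`nominal_interval` must be positive")
  if (width %% nominal_interval != 0) stop("`width` must be divisible by `nominal_interval`")
  if (jitter_sd < 0) stop("`jitter_sd` must be non-negative")
  n_stripes <- width / nominal_interval
  nominal <- nominal_interval * seq_len(n_stripes - 1L)
  midline <- width / 2
  jit_idx <- which(nominal != midline)
  with_seed(seed, {
    repeat {
      b <- nominal
      b[jit_idx] <- round(nominal[jit_idx] + rnorm(length(jit_idx), 0, jitter_sd))
      if (all(diff(b) > 0) && b[1] > 0 && b[length(b)] < width) break
    }
    structure(list(boundaries = as.integer(b),
                   colour_order = sample_colour_order(),
                   nominal_interval = nominal_interval,
                   jitter_sd = jitter_sd, width = as.integer(width)),
              class = "camo_stripes")
  })
}

#' Sample the left-to-right colour order
#'
#' The order of tones (A-B-A-B-... or B-A-B-A-...) is chosen with equal
#' probability, so a scene cannot be anticipated from the previous one.
#'
#' @param seed Optional integer seed.
#' @return `"AB_start"` or `"BA_start"`.
#' @export
sample_colour_order <- function(seed = NULL) {
  with_seed(seed, if (runif(1) < 0.5) "AB_start" else "BA_start")
}

#' Place the colour-reversed foreground squares
#'
#' Four squares straddle every interior stripe boundary except the display
#' midline (6 boundaries x 4 vertical quadrants = 24 squares). Each square
#' is centred horizontally on its boundary so its internal colour boundary
#' coincides with the stripe boundary; its colours are the reverse of the
#' underlying stripes, which creates the illusion of striped squares
#' resting on a striped background. The vertical offset of each square
#' within its 192 px quadrant is a uniform integer on
#' `[1, 192 - 2 * side]`, keeping squares apart vertically. In the rare
#' event that two squares on closely jittered boundaries overlap, the
#' vertical offsets are redrawn.
#'
#' @param stripes A `camo_stripes` object.
#' @param side Square side in pixels, 32 (small) or 64 (large).
#' @param height Display height in pixels.
#' @param seed Optional integer seed.
#' @return Data frame with one row per square: `boundary_x`, `top_y`,
#'   `side`, `quadrant` (0-3).
#' @export
place_squares <- function(stripes, side, height = 768, seed = NULL) {
  stopifnot(inherits(stripes, "camo_stripes"))
  if (!side %in% c(32L, 64L)) stop("`side` must be 32 or 64")
  quad_h <- height / 4
  if (192 - 2 * side < 1) stop("square side too large for the quadrant range")
  midline <- stripes$width / 2
  bx <- stripes$boundaries[stripes$boundaries != midline]
  with_seed(seed, {
    for (try in 1:100) {
      sq <- expand.grid(boundary_x = bx, quadrant = 0:3)
      u <- sample.int(192L - 2L * side, nrow(sq), replace = TRUE)
      sq$top_y <- as.integer(sq$quadrant * quad_h + u)
      sq$side <- as.integer(side)
      sq <- sq[c("boundary_x", "top_y", "side", "quadrant")]
      if (!squares_overlap(sq)) return(sq)
    }
    stop("could not place squares without overlap; regenerate the stripe field")
  })
}

#' @keywords internal
#' @noRd
squares_overlap <- function(sq) {
  n <- nrow(sq)
  x0 <- sq$boundary_x - sq$side / 2; x1 <- sq$boundary_x + sq$side / 2
  y0 <- sq$top_y; y1 <- sq$top_y + sq$side
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    hit <- x0[j] < x1[i] & x1[j] > x0[i] & y0[j] < y1[i] & y1[j] > y0[i]
    if (any(hit)) return(TRUE)
  }
  FALSE
}

# Scene tone lookup: 0 = tone A, 1 = tone B at pixel (x, y), 0-based
# half-open pixel coordinates (a pixel's tone is evaluated at its centre).
# Inside a square the underlying stripe tone is reversed pointwise.
#' @keywords internal
#' @noRd
scene_tone <- function(stripes, squares, x, y) {
  stripe_idx <- findInterval(x + 0.5, stripes$boundaries)
  tone <- stripe_idx %% 2L
  if (stripes$colour_order == "BA_start") tone <- 1L - tone
  if (nrow(squares)) {
    for (k in seq_len(nrow(squares))) {
      s <- squares[k, ]
      inside <- x + 0.5 > s$boundary_x - s$side / 2 &
                x + 0.5 < s$boundary_x + s$side / 2 &
                y + 0.5 > s$top_y & y + 0.5 < s$top_y + s$side
      tone[inside] <- 1L - tone[inside]
    }
  }
  tone
}

# Pixel mask of the 16 px target disc centred at integer grid point
# (cx, cy): pixels whose centres lie within radius 8. The widest row is
# exactly 16 px and the disc splits 8|8 about the vertical line x = cx.
#' @keywords internal
#' @noRd
disc_pixels <- function(cx, cy, radius = 8) {
  xs <- (cx - radius):(cx + radius - 1L)
  ys <- (cy - radius):(cy + radius - 1L)
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x + 0.5 - cx)^2 + (g$y + 0.5 - cy)^2 <= radius^2
  g[keep, , drop = FALSE]
}

#' Place the target disc for a treatment
#'
#' The circular target (16 px diameter) is placed uniformly at random
#' among locations eligible under the treatment's rules:
#' \describe{
#'   \item{Dark / Light}{monotone target wholly on a homogeneous region of
#'     the matching tone, on the background stripes and clear of every
#'     square by at least 2 px.}
#'   \item{Stripe}{two-tone target centred on a stripe-stripe boundary
#'     (never the midline), clear of all squares.}
#'   \item{Square}{two-tone target centred on the internal colour midline
#'     of a square, wholly inside it.}
#'   \item{Border}{two-tone target centred on the vertical outer edge of a
#'     square, the inner half on the square and the outer half on a
#'     homogeneous stretch of background.}
#' }
#' Two-tone targets are always perfectly in phase with the underlying
#' boundary: each half takes the tone of its own side. Every placement
#' keeps the whole disc at least 1 px inside one screen half, so the
#' correct answer (left/right) is unambiguous. Placement is by rejection
#' sampling from the uniform distribution over candidate positions, which
#' yields the uniform distribution over eligible positions; if no eligible
#' position is found within the retry budget a condition of class
#' `camo_regenerate_scene` is signalled.
#'
#' @param stripes A `camo_stripes` object.
#' @param squares Square table from [place_squares()].
#' @param treatment One of `"Dark"`, `"Light"`, `"Stripe"`, `"Square"`,
#'   `"Border"`.
#' @param height Display height in pixels.
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling budget.
#' @return List with `centre_x`, `centre_y`, `diameter`, `treatment`,
#'   `split` (two-tone?), `screen_side` (`"left"`/`"right"`).
#' @export
place_target <- function(stripes, squares, treatment, height = 768,
                         seed = NULL, max_tries = 5000) {
  treatment <- match.arg(treatment, TREATMENTS)
  w <- stripes$width; mid <- w / 2; r <- 8L
  split <- treatment %in% c("Stripe", "Square", "Border")
  sq_x0 <- squares$boundary_x - squares$side / 2
  sq_x1 <- squares$boundary_x + squares$side / 2
  sq_y0 <- squares$top_y; sq_y1 <- squares$top_y + squares$side

  clear_of_squares <- function(cx, cy, clearance = 2) {
    !any(cx + r + clearance > sq_x0 & cx - r - clearance < sq_x1 &
         cy + r + clearance > sq_y0 & cy - r - clearance < sq_y1)
  }
  in_one_half <- function(cx) (cx - r >= 1 && cx + r <= mid - 1) ||
                              (cx - r >= mid + 1 && cx + r <= w - 1)
  tone_ok <- function(cx, cy) {
    px <- disc_pixels(cx, cy, r)
    tn <- scene_tone(stripes, squares, px$x, px$y)
    if (!split) {
      want <- if (treatment == "Dark") 0L else 1L
      all(tn == want)
    } else {
      left <- px$x < cx
      length(unique(tn[left])) == 1L && length(unique(tn[!left])) == 1L &&
        tn[left][1] != tn[!left][1]
    }
  }
  interior_bnds <- stripes$boundaries
  nonmid_bnds <- interior_bnds[interior_bnds != mid]

  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      if (treatment %in% c("Dark", "Light")) {
        cx <- sample.int(w - 2L * r - 2L, 1L) + r
        cy <- sample.int(height - 2L * r, 1L) + r - 1L
        if (!in_one_half(cx)) next
        # disc must sit inside a single stripe of the matching tone
        if (any(abs(interior_bnds - cx) < r + 1)) next
        if (!clear_of_squares(cx, cy)) next
        if (!tone_ok(cx, cy)) next
      } else if (treatment == "Stripe") {
        cx <- nonmid_bnds[sample.int(length(nonmid_bnds), 1L)]
        cy <- sample.int(height - 2L * r, 1L) + r - 1L
        if (!in_one_half(cx)) next
        if (!clear_of_squares(cx, cy)) next
        if (!tone_ok(cx, cy)) next
      } else if (treatment == "Square") {
        k <- sample.int(nrow(squares), 1L)
        s <- squares[k, ]
        cx <- s$boundary_x
        lo <- s$top_y + r; hi <- s$top_y + s$side - r
        cy <- if (hi > lo) sample(lo:hi, 1L) else lo
        if (!in_one_half(cx)) next
        if (!tone_ok(cx, cy)) next
      } else { # Border
        k <- sample.int(nrow(squares), 1L)
        s <- squares[k, ]
        edge <- if (runif(1) < 0.5) -1 else 1
        cx <- as.integer(s$boundary_x + edge * s$side / 2)
        lo <- s$top_y + r; hi <- s$top_y + s$side - r
        cy <- if (hi > lo) sample(lo:hi, 1L) else lo
        if (!in_one_half(cx)) next
        # the outer half must be clear of other squares and boundaries
        other <- squares[-k, , drop = FALSE]
        ox0 <- if (edge < 0) cx - r - 2 else cx
        ox1 <- if (edge < 0) cx else cx + r + 2
        if (any(other$boundary_x - other$side / 2 < ox1 &
                other$boundary_x + other$side / 2 > ox0 &
                other$top_y < cy + r + 2 & other$top_y + other$side > cy - r - 2)) next
        if (!tone_ok(cx, cy)) next
      }
      return(list(centre_x = as.integer(cx), centre_y = as.integer(cy),
                  diameter = 2L * r, treatment = treatment, split = split,
                  screen_side = if (cx < mid) "left" else "right"))
    }
    cond <- structure(class = c("camo_regenerate_scene", "error", "condition"),
                      list(message = sprintf(
                        "no eligible %s target location found; regenerate the scene",
                        treatment), call = sys.call(-1)))
    stop(cond)
  })
}

#' Build a complete scene specification
#'
#' Draws the stripe field, colour order, squares and target for one trial,
#' retrying with fresh geometry in the rare case that a treatment has no
#' eligible target location.
#'
#' @param treatment Target treatment (see [place_target()]).
#' @param square_size `"small"` (32 px squares) or `"large"` (64 px).
#' @param palette A `camo_palette`.
#' @param seed Integer seed; the scene is a deterministic function of
#'   (arguments, seed).
#' @return Object of class `camo_scene`: width/height, palette, stripes,
#'   squares, target, square size and seed.
#' @examples
#' sc <- build_scene("Border", "large", seed = 7)
#' sc$target$screen_side
#' @export
build_scene <- function(treatment, square_size = c("small", "large"),
                        palette = camo_palette(), seed = NULL) {
  square_size <- match.arg(square_size)
  side <- if (square_size == "small") 32L else 64L
  with_seed(seed, {
    for (attempt in 1:20) {
      stripes <- sample_stripe_boundaries()
      squares <- place_squares(stripes, side)
      tgt <- tryCatch(place_target(stripes, squares, treatment),
                      camo_regenerate_scene = function(e) NULL)
      if (!is.null(tgt)) {
        return(structure(list(width = stripes$width, height = 768L,
                              palette = palette, stripes = stripes,
                              squares = squares, target = tgt,
                              square_size = square_size, seed = seed),
                         class = "camo_scene"))
      }
    }
    stop("failed to build an eligible scene after 20 regenerations")
  })
}

#' Render a scene to a raster
#'
#' Paints the striped background and colour-reversed squares, then the
#' target: each target pixel takes the local background tone scaled by the
#' palette's `lighten_factor` (each half of a two-tone target is lightened
#' relative to its own side's tone). Channels exceeding the display gamut
#' after scaling are clipped and flagged in the metadata.
#'
#' @param scene A `camo_scene`.
#' @return List with `raster` (height x width x 3 array in `[0, 1]`) and
#'   `metadata` (geometry, treatment, correct answer side, clipping flag).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "camo_scene"))
  w <- scene$width; h <- scene$height
  pal <- rbind(scene$palette$colour_a, scene$palette$colour_b)
  col_tone <- scene_tone(scene$stripes, scene$squares[0, ], seq_len(w) - 1L, 0)
  tone <- matrix(rep(col_tone, each = h), nrow = h)  # stripes only
  for (k in seq_len(nrow(scene$squares))) {
    s <- scene$squares[k, ]
    rows <- (s$top_y + 1L):(s$top_y + s$side)
    cols <- (s$boundary_x - s$side / 2 + 1L):(s$boundary_x + s$side / 2)
    tone[rows, cols] <- 1L - tone[rows, cols]
  }
  raster <- array(0, dim = c(h, w, 3))
  for (ch in 1:3)
    raster[, , ch] <- pal[tone + 1L, ch]
  tgt <- scene$target
  px <- disc_pixels(tgt$centre_x, tgt$centre_y)
  clipped <- FALSE
  for (i in seq_len(nrow(px))) {
    rr <- px$y[i] + 1L; cc <- px$x[i] + 1L
    val <- raster[rr, cc, ] * scene$palette$lighten_factor
    if (any(val > 1)) { val <- pmin(val, 1); clipped <- TRUE }
    raster[rr, cc, ] <- val
  }
  meta <- list(width = w, height = h, palette_mode = scene$palette$mode,
               colour_order = scene$stripes$colour_order,
               boundaries = scene$stripes$boundaries,
               squares = scene$squares, treatment = tgt$treatment,
               square_size = scene$square_size,
               target_centre = c(tgt$centre_x, tgt$centre_y),
               target_diameter = tgt$diameter, split_target = tgt$split,
               answer_side = tgt$screen_side, gamut_clipped = clipped,
               seed = scene$seed)
  list(raster = raster, metadata = meta)
}

#' Write a rendered scene to disk
#'
#' Writes the raster as 8-bit RGB PNG (or ASCII PGM for achromatic
#' scenes) and the ground-truth metadata as JSON alongside it.
#'
#' @param scene A `camo_scene`.
#' @param path Output path; extension `.png` or `.pgm`.
#' @param metadata Write the JSON sidecar? Default `TRUE`.
#' @return Invisibly, the path.
#' @export
write_scene <- function(scene, path, metadata = TRUE) {
  rend <- render_scene(scene)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    png::writePNG(rend$raster, target = path)
  } else if (ext == "pgm") {
    if (scene$palette$mode != "achromatic")
      stop("PGM output is only supported for achromatic scenes")
    g <- round(rend$raster[, , 1] * 255)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
    write(t(g), con, ncolumns = 16)
  } else stop("unsupported extension: ", ext)
  if (metadata) {
    jsonlite::write_json(rend$metadata,
                         sub("\\.[^.]+$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @export
print.camo_scene <- function(x, ...) {
  cat("<camo_scene>", x$width, "x", x$height, "px,", x$palette$mode, "\n")
  cat("  treatment:", x$target$treatment, "| squares:", nrow(x$squares),
      "x", x$squares$side[1], "px | target at (",
      x$target$centre_x, ",", x$target$centre_y, ") on the",
      x$target$screen_side, "\n")
  invisible(x)
}
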