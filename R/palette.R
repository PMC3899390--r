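#' Display palettes
#'
#' A palette holds the two scene tones. `colour_a` plays the "dark" role
#' (the tone the Dark treatment sits on) and `colour_b` the "light" role.
#' The achromatic default uses greys at 40% and 60% of maximum intensity,
#' symmetric about mid-grey so that a 10% multiplicative lightening of
#' either tone stays inside the display gamut. The chromatic pairs are
#' approximately isoluminant red/green and blue/yellow shades (matched to
#' roughly equal CIELab lightness); exact monitor calibration is out of
#' scope, as detection in these displays relies on the tone/hue contrast
#' structure rather than on precise luminance values.
#'
#' @param mode One of `"achromatic"`, `"red_green"`, `"blue_yellow"`.
#' @param lighten_factor Multiplicative factor applied per channel to the
#'   local background tone to obtain the target colour (default 1.10,
#'   i.e. a 10% lighter target).
#' @return An object of class `camo_palette`: a list with `colour_a`,
#'   `colour_b` (RGB triples in `[0, 1]`), `mode` and `lighten_factor`.
#' @examples
#' camo_palette("achromatic")
#' @export
camo_palette <- function(mode = c("achromatic", "red_green", "blue_yellow"),
                         lighten_factor = 1.10) {
  mode <- match.arg(mode)
  stopifnot(lighten_factor > 1)
  cols <- switch(mode,
    achromatic  = list(a = rep(0.40, 3), b = rep(0.60, 3)),
    red_green   = list(a = c(0.80, 0.33, 0.30), b = c(0.22, 0.62, 0.31)),
    blue_yellow = list(a = c(0.33, 0.45, 0.85), b = c(0.62, 0.55, 0.20)))
  structure(list(colour_a = cols$a, colour_b = cols$b,
                 mode = mode, lighten_factor = lighten_factor),
            class = "camo_palette")
}

#' @export
print.camo_palette <- function(x, ...) {
  cat("<camo_palette>", x$mode, "\n")
  cat("  tone A (dark role): ", paste(round(x$colour_a, 3), collapse = ", "), "\n")
  cat("  tone B (light role):", paste(round(x$colour_b, 3), collapse = ", "), "\n")
  cat("  lighten factor:", x$lighten_factor, "\n")
  invisible(x)
}
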