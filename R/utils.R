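# Internal RNG helpers.

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based seed spawning: deterministic child seeds from a master seed,
# kept strictly below 2^31 so they are valid R integer seeds.
#' @keywords internal
#' @noRd
derive_seed <- function(master, counter) {
  m <- 2147483647  # 2^31 - 1
  s <- (as.numeric(master) %% m) + 1
  # two rounds of a multiplicative congruential mix keep nearby counters apart
  x <- (s * 48271) %% m
  x <- (x + (as.numeric(counter) %% m) * 16807) %% m
  x <- (x * 69621) %% m
  as.integer(x)
}

TREATMENTS <- c("Dark", "Light", "Stripe", "Square", "Border")
SIZES <- c("small", "large")

#' @keywords internal
#' @noRd
as_treatment <- function(x) factor(x, levels = TREATMENTS)

#' @keywords internal
#' @noRd
as_size <- function(x) factor(x, levels = SIZES)
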