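#' Construct a synthetic observer model
#'
#' The observer is the generative mirror of the analysis model. On each
#' trial the latent detection time is log-normal,
#' \deqn{T = \exp(\mu_{ts} + u_j + \sigma z),}
#' with a cell location \eqn{\mu_{ts}} per treatment x square size, a
#' subject random intercept \eqn{u_j \sim N(0, \tau_{rt}^2)} and standard
#' normal noise \eqn{z}. Times at or beyond the 15 s time-out are
#' right-censored (no response recorded); recorded times are rounded to
#' the nearest 10 ms after the censoring check. Given a response, a
#' wrong-side error occurs with probability
#' \eqn{\mathrm{logit}^{-1}(\beta_{ts} + v_j)}, with its own subject
#' intercept \eqn{v_j \sim N(0, \tau_{err}^2)}. Errors are independent of
#' the response time given the cell — the simplest structure consistent
#' with the analysis, and a documented limitation.
#'
#' @param mu 5 x 2 matrix of log-second locations (rows: treatments
#'   Dark, Light, Stripe, Square, Border; columns: small, large).
#' @param sigma Within-cell log-scale SD (log-seconds).
#' @param tau_rt SD of the subject random intercept on log-RT.
#' @param beta_err 5 x 2 matrix of wrong-side log-odds.
#' @param tau_err SD of the subject random intercept on the error logit.
#' @param censor_time Time-out in seconds (15).
#' @param rt_resolution Recording resolution in seconds (0.01).
#' @return Object of class `camo_observer`.
#' @seealso [preset_effect_profiles()] for ready-made parameter sets.
#' @export
observer_model <- function(mu, sigma, tau_rt, beta_err, tau_err,
                           censor_time = 15, rt_resolution = 0.01) {
  mu <- as.matrix(mu); beta_err <- as.matrix(beta_err)
  stopifnot(all(dim(mu) == c(5L, 2L)), all(dim(beta_err) == c(5L, 2L)),
            sigma > 0, tau_rt >= 0, tau_err >= 0, censor_time > 0,
            rt_resolution > 0)
  dimnames(mu) <- dimnames(beta_err) <- list(TREATMENTS, SIZES)
  structure(list(mu = mu, sigma = sigma, tau_rt = tau_rt,
                 beta_err = beta_err, tau_err = tau_err,
                 censor_time = censor_time, rt_resolution = rt_resolution),
            class = "camo_observer")
}

#' Preset observer parameter profiles
#'
#' Three documented parameter sets:
#' \describe{
#'   \item{null}{all treatment and size effects equal — for type-I-error
#'     and calibration studies. Median RT 2 s, error rate 4% everywhere.}
#'   \item{chromatic_like}{the qualitative pattern of the isoluminant
#'     chromatic displays: detection-time means
#'     Border > (Square = Stripe) > (Dark = Light)
#'     (4.2, 3.0, 3.0, 1.6, 1.6 s) and error rates in the same order
#'     (18%, 8%, 8%, 2%, 2%), with no square-size effect.}
#'   \item{achromatic_like}{the grey-tone pattern, where the Stripe and
#'     Square treatments reverse between square sizes: with small squares
#'     (Square = Border) > Stripe > (Dark = Light); with large squares
#'     Stripe > (Square = Border) > (Dark = Light). Error rates are
#'     highest for Border at both sizes.}
#' }
#' The presets are qualitative: the underlying human response-time
#' distributions were never published, so magnitudes are chosen as
#' plausible visual-search values reproducing the ordering patterns, not
#' fitted quantities.
#'
#' @param name `"null"`, `"chromatic_like"` or `"achromatic_like"`.
#' @return A `camo_observer`.
#' @examples
#' preset_effect_profiles("chromatic_like")
#' @export
preset_effect_profiles <- function(name = c("null", "chromatic_like",
                                            "achromatic_like")) {
  name <- match.arg(name)
  sigma <- 0.55
  # locations chosen so that exp(mu + sigma^2/2) equals the stated means
  mu_of_mean <- function(m) log(m) - sigma^2 / 2
  if (name == "null") {
    mu <- matrix(log(2), 5, 2)
    beta <- matrix(qlogis(0.04), 5, 2)
    obs <- observer_model(mu, sigma = 0.45, tau_rt = 0.20,
                          beta_err = beta, tau_err = 0.30)
  } else if (name == "chromatic_like") {
    means <- c(Dark = 1.6, Light = 1.6, Stripe = 3.0, Square = 3.0,
               Border = 4.2)
    errs <- c(Dark = 0.02, Light = 0.02, Stripe = 0.08, Square = 0.08,
              Border = 0.18)
    mu <- matrix(mu_of_mean(means), 5, 2)
    beta <- matrix(qlogis(errs), 5, 2)
    obs <- observer_model(mu, sigma = sigma, tau_rt = 0.25,
                          beta_err = beta, tau_err = 0.30)
  } else {
    means_small <- c(Dark = 1.6, Light = 1.6, Stripe = 3.0, Square = 4.2,
                     Border = 4.2)
    means_large <- c(Dark = 1.6, Light = 1.6, Stripe = 4.2, Square = 3.0,
                     Border = 3.0)
    errs <- c(Dark = 0.025, Light = 0.025, Stripe = 0.05, Square = 0.07,
              Border = 0.15)
    mu <- cbind(mu_of_mean(means_small), mu_of_mean(means_large))
    beta <- matrix(qlogis(errs), 5, 2)
    obs <- observer_model(mu, sigma = sigma, tau_rt = 0.25,
                          beta_err = beta, tau_err = 0.30)
  }
  attr(obs, "profile") <- name
  obs
}

#' Simulate one trial
#'
#' Mostly useful for illustration; [simulate_experiment()] vectorises the
#' same generative process.
#'
#' @param observer A `camo_observer`.
#' @param u,v Subject random intercepts on log-RT and error logit.
#' @param treatment,square_size The trial's cell.
#' @param true_side Correct answer side, `"left"` or `"right"`.
#' @param seed Optional integer seed.
#' @return One-row data frame with `rt`, `censored`, `response_side`,
#'   `error`.
#' @export
simulate_trial <- function(observer, u = 0, v = 0, treatment, square_size,
                           true_side = "left", seed = NULL) {
  treatment <- match.arg(treatment, TREATMENTS)
  square_size <- match.arg(square_size, SIZES)
  with_seed(seed, {
    lat <- exp(observer$mu[treatment, square_size] + u +
               observer$sigma * rnorm(1))
    if (lat >= observer$censor_time) {
      data.frame(rt = observer$censor_time, censored = TRUE,
                 response_side = "none", error = NA)
    } else {
      rt <- round(lat / observer$rt_resolution) * observer$rt_resolution
      err <- runif(1) < plogis(observer$beta_err[treatment, square_size] + v)
      side <- if (err) setdiff(c("left", "right"), true_side) else true_side
      data.frame(rt = rt, censored = FALSE, response_side = side,
                 error = err)
    }
  })
}

#' Simulate a full multi-subject experiment
#'
#' Builds one session plan per subject, draws the subject random effects
#' once per subject, and generates every trial's outcome. The result is a
#' tidy trial table ready for [estimate_cells()].
#'
#' @param observer A `camo_observer`.
#' @param n_subjects Number of subjects (the reference design uses 25).
#' @param master_seed Integer master seed; the table is a deterministic
#'   function of (observer, n_subjects, master_seed, n_blocks).
#' @param n_blocks Main blocks per subject (default 4).
#' @param include_practice Keep the flagged practice trials in the output?
#' @return Data frame with one row per trial: `subject`, `block`, `trial`,
#'   `treatment`, `square_size`, `practice`, `true_side`, `response_side`,
#'   `rt` (seconds), `censored`, `error` (`NA` on time-outs).
#' @examples
#' tr <- simulate_experiment(preset_effect_profiles("null"), 2, 1)
#' nrow(tr[!tr$practice, ])  # 2 x 200
#' @export
simulate_experiment <- function(observer, n_subjects, master_seed,
                                n_blocks = 4L, include_practice = TRUE) {
  stopifnot(inherits(observer, "camo_observer"), n_subjects >= 1)
  out <- vector("list", n_subjects)
  for (j in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", j)
    sseed <- derive_seed(master_seed, 500000L + j)
    plan <- build_session(sid, master_seed = derive_seed(master_seed, j),
                          n_blocks = n_blocks)
    out[[j]] <- with_seed(sseed, {
      u <- rnorm(1, 0, observer$tau_rt)
      v <- rnorm(1, 0, observer$tau_err)
      n <- nrow(plan)
      idx <- cbind(as.integer(plan$treatment), as.integer(plan$square_size))
      lat <- exp(observer$mu[idx] + u + observer$sigma * rnorm(n))
      censored <- lat >= observer$censor_time
      rt <- ifelse(censored, observer$censor_time,
                   round(lat / observer$rt_resolution) * observer$rt_resolution)
      true_side <- sample(c("left", "right"), n, replace = TRUE)
      err <- runif(n) < plogis(observer$beta_err[idx] + v)
      err[censored] <- NA
      response_side <- ifelse(censored, "none",
                              ifelse(err, ifelse(true_side == "left",
                                                 "right", "left"),
                                     true_side))
      cbind(plan, data.frame(true_side = true_side,
                             response_side = response_side,
                             rt = rt, censored = censored, error = err))
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!include_practice) res <- res[!res$practice, , drop = FALSE]
  class(res) <- "data.frame"
  res
}

#' @rdname simulate_experiment
#' @param object A `camo_observer` (for the `simulate` method).
#' @param nsim Number of subjects to simulate.
#' @param seed Master seed.
#' @param ... Passed on to [simulate_experiment()].
#' @export
simulate.camo_observer <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  simulate_experiment(object, n_subjects = nsim, master_seed = seed, ...)
}

#' @export
print.camo_observer <- function(x, ...) {
  prof <- attr(x, "profile")
  cat("<camo_observer>", if (!is.null(prof)) paste0("profile: ", prof), "\n")
  cat("  cell mean RTs (s):\n")
  print(round(exp(x$mu + x$sigma^2 / 2), 2))
  cat("  cell error rates:\n")
  print(round(plogis(x$beta_err), 3))
  cat(sprintf("  sigma = %.2f, tau_rt = %.2f, tau_err = %.2f, censor = %g s\n",
              x$sigma, x$tau_rt, x$tau_err, x$censor_time))
  invisible(x)
}
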