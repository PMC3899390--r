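#' Fit a random-intercept mixed model to cell summaries
#'
#' The inferential models mirror the two response types of the analysis:
#' \describe{
#'   \item{normal_mean_rt}{the censored-corrected cell mean detection
#'     times are modelled with normal error (the raw times are skewed,
#'     but the estimated means are not), fixed effects drawn from square
#'     size, treatment and their interaction, and a per-subject random
#'     intercept. Fitted by maximum likelihood (not REML), so deviances
#'     are comparable across fixed-effect structures.}
#'   \item{binomial_errors}{wrong-side error counts per cell are
#'     modelled as binomial with logit link over the trials on which a
#'     response was made, with the same fixed-effect structure and a
#'     per-subject random intercept. The marginal likelihood is
#'     approximated by adaptive Gauss-Hermite quadrature
#'     (`nAGQ` nodes; 5 by default, enough that deviance tests on
#'     balanced designs are stable across quadrature orders).}
#' }
#' With a single subject there is no between-subject information: the
#' model degrades to an ordinary least-squares / logistic fit with the
#' intercept variance pinned at zero, with a warning.
#'
#' Treatment levels whose error count is zero in every cell have no
#' within-level variance; the fit is still returned but contrasts
#' involving such levels are flagged non-estimable downstream.
#'
#' @param data Cell table from [estimate_cells()] (or equivalent).
#' @param response_kind `"normal_mean_rt"` or `"binomial_errors"`.
#' @param fixed_terms Character subset of
#'   `c("square_size", "treatment", "square_size:treatment")`; use
#'   `character(0)` for the intercept-only model.
#' @param nAGQ Quadrature nodes for the binomial fit (>= 1; 1 = Laplace).
#' @return Object of class `camo_mixed`: the underlying fit plus
#'   `response_kind`, `fixed_terms`, `deviance` (-2 log-likelihood),
#'   `n_obs`, `subject_variance`, `coefficients`, `zero_error_levels` and
#'   the model data.
#' @export
fit_mixed <- function(data,
                      response_kind = c("normal_mean_rt", "binomial_errors"),
                      fixed_terms = c("square_size", "treatment",
                                      "square_size:treatment"),
                      nAGQ = 5) {
  response_kind <- match.arg(response_kind)
  stopifnot(all(c("subject", "treatment", "square_size") %in% names(data)))
  data <- as.data.frame(data)
  data$subject <- factor(data$subject)
  data$treatment <- as_treatment(data$treatment)
  data$square_size <- as_size(data$square_size)
  ok_terms <- c("square_size", "treatment", "square_size:treatment")
  if (!all(fixed_terms %in% ok_terms))
    stop("`fixed_terms` must be a subset of: ", paste(ok_terms, collapse = ", "))
  if ("square_size:treatment" %in% fixed_terms &&
      !all(c("square_size", "treatment") %in% fixed_terms))
    stop("the interaction requires both main effects (hierarchical models only)")
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"

  zero_err <- character(0)
  if (response_kind == "normal_mean_rt") {
    stopifnot("mean_hat" %in% names(data))
    if ("converged" %in% names(data) && any(!data$converged)) {
      warning(sum(!data$converged), " non-estimable cell(s) dropped from the RT model")
      data <- data[data$converged, ]
    }
    lhs <- "mean_hat"
  } else {
    stopifnot(all(c("n_errors", "n_responded") %in% names(data)))
    lhs <- "cbind(n_errors, n_responded - n_errors)"
    tot <- tapply(data$n_errors, data$treatment, sum)
    zero_err <- names(tot)[!is.na(tot) & tot == 0]
  }

  single_subject <- nlevels(droplevels(data$subject)) < 2L
  if (single_subject) {
    warning("single subject: fitting a fixed-effects model (intercept variance 0)")
    form <- as.formula(paste(lhs, "~", rhs))
    fit <- if (response_kind == "normal_mean_rt") lm(form, data = data)
           else glm(form, family = binomial, data = data)
    ll <- as.numeric(logLik(fit))
    beta <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    subj_var <- 0
  } else {
    form <- as.formula(paste(lhs, "~", rhs, "+ (1 | subject)"))
    fit <- if (response_kind == "normal_mean_rt") {
      suppressMessages(lme4::lmer(
        form, data = data, REML = FALSE,
        control = lme4::lmerControl(check.conv.singular = "ignore")))
    } else {
      suppressMessages(lme4::glmer(
        form, data = data, family = binomial, nAGQ = nAGQ,
        control = lme4::glmerControl(optimizer = "bobyqa",
                                     check.conv.singular = "ignore")))
    }
    ll <- as.numeric(logLik(fit))
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    vc <- lme4::VarCorr(fit)
    subj_var <- as.numeric(vc$subject[1, 1])
  }
  structure(list(fit = fit, response_kind = response_kind,
                 fixed_terms = fixed_terms,
                 deviance = -2 * ll, log_likelihood = ll,
                 n_obs = nrow(data), n_fixed = length(beta),
                 subject_variance = subj_var,
                 coefficients = data.frame(estimate = beta, se = se),
                 zero_error_levels = zero_err, data = data),
            class = "camo_mixed")
}

#' @export
print.camo_mixed <- function(x, digits = 4, ...) {
  cat("<camo_mixed>", x$response_kind, "\n")
  cat("  fixed: ~", if (length(x$fixed_terms))
    paste(x$fixed_terms, collapse = " + ") else "1", "\n")
  cat(sprintf("  n = %d, subject intercept variance = %.4g, deviance = %.3f\n",
              x$n_obs, x$subject_variance, x$deviance))
  print(round(x$coefficients, digits))
  if (length(x$zero_error_levels))
    cat("  zero-error treatment level(s):",
        paste(x$zero_error_levels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.camo_mixed <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))
}

#' @export
logLik.camo_mixed <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_fixed + 2L,
            nobs = object$n_obs, class = "logLik")
}

#' @export
summary.camo_mixed <- function(object, ...) print(object)

#' Likelihood-ratio (deviance) test between nested mixed models
#'
#' Significance of a fixed-effect term is judged by the change in
#' deviance between maximum-likelihood fits with and without the term,
#' referred to a chi-square distribution with degrees of freedom equal to
#' the difference in fixed-effect parameter count.
#'
#' @param full,reduced `camo_mixed` fits of the same response kind on the
#'   same data, `reduced` nested in `full`.
#' @return Object of class `camo_lrt`: list with `term`, `chi2`, `df`,
#'   `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "camo_mixed"), inherits(reduced, "camo_mixed"))
  if (full$response_kind != reduced$response_kind)
    stop("models have different response kinds")
  if (full$n_obs != reduced$n_obs)
    stop("models were fitted to different numbers of observations")
  if (!all(reduced$fixed_terms %in% full$fixed_terms))
    stop("`reduced` is not nested in `full`")
  df <- full$n_fixed - reduced$n_fixed
  if (df < 0) stop("`full` has fewer fixed-effect parameters than `reduced`")
  chi2 <- reduced$deviance - full$deviance
  if (chi2 < 0) {
    if (chi2 < -1e-4) warning("negative deviance change (", signif(chi2, 3),
                              "); check convergence")
    chi2 <- 0
  }
  term <- setdiff(full$fixed_terms, reduced$fixed_terms)
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  structure(list(term = paste(term, collapse = " + "), chi2 = chi2,
                 df = df, p = p),
            class = "camo_lrt")
}

#' @export
print.camo_lrt <- function(x, ...) {
  cat(sprintf("LRT [%s]: X2 = %.3f, df = %d, p = %.4g\n",
              x$term, x$chi2, x$df, x$p))
  invisible(x)
}

#' @keywords internal
#' @noRd
glht_table <- function(fit, linfct, adjustment, seed = 636413622L) {
  gh <- multcomp::glht(fit$fit, linfct = linfct)
  raw <- summary(gh, test = multcomp::adjusted("none"))$test
  adj <- if (adjustment == "tukey_single_step") {
    # single-step max-|t| adjustment; the multivariate normal/t integral
    # uses quasi-Monte-Carlo, so fix the seed for reproducibility
    tryCatch(
      with_seed(seed,
                summary(gh, test = multcomp::adjusted("single-step"))$test),
      error = function(e) {
        warning("single-step adjustment unavailable (", conditionMessage(e),
                "); reporting raw p-values")
        raw
      })
  } else raw
  pair <- names(raw$coefficients)
  tab <- data.frame(pair = pair,
                    estimate = as.numeric(raw$coefficients),
                    se = as.numeric(raw$sigma),
                    t = as.numeric(raw$tstat),
                    p_raw = as.numeric(raw$pvalues),
                    p_adjusted = as.numeric(adj$pvalues),
                    adjustment = adjustment)
  # the single-step p can undercut the raw p only by quadrature error
  tab$p_adjusted <- pmax(tab$p_adjusted, tab$p_raw)
  bad <- fit$zero_error_levels
  tab$estimable <- !vapply(pair, function(p) {
    lv <- trimws(strsplit(p, " - ", fixed = TRUE)[[1]])
    any(lv %in% bad)
  }, logical(1))
  tab$estimable <- tab$estimable & is.finite(tab$se) &
    is.finite(tab$p_adjusted)
  class(tab) <- c("camo_contrasts", "data.frame")
  tab
}

#' Simple contrasts against the reference treatment
#'
#' The a priori comparisons of the design are each treatment against the
#' Border reference; they are tested simultaneously from one fitted model
#' but deliberately without multiplicity correction.
#'
#' @param fit A `camo_mixed` with `treatment` among its fixed terms
#'   (contrasts are cleanest on the additive model).
#' @param reference Reference level, default `"Border"`.
#' @return `camo_contrasts` data frame with one row per non-reference
#'   treatment: estimate, SE, t, raw and adjusted p (equal here), and an
#'   `estimable` flag (false for zero-error levels in binomial fits).
#' @export
contrasts_vs_reference <- function(fit, reference = "Border") {
  stopifnot(inherits(fit, "camo_mixed"))
  if (!"treatment" %in% fit$fixed_terms)
    stop("`treatment` is not among the model's fixed terms")
  if (!reference %in% TREATMENTS) stop("unknown reference level")
  others <- setdiff(TREATMENTS, reference)
  spec <- paste(others, "-", reference, "= 0")
  glht_table(fit, multcomp::mcp(treatment = spec),
             adjustment = "none_simple_vs_reference")
}

#' Tukey-type all-pairwise treatment comparisons
#'
#' Secondary comparisons among all 10 treatment pairs, corrected for
#' simultaneous multiple comparison by the single-step max-|t| procedure
#' (the joint multivariate normal/t distribution of the contrast
#' statistics under the fitted correlation; the integral is evaluated by
#' quasi-Monte-Carlo under a fixed seed).
#'
#' @inheritParams contrasts_vs_reference
#' @return `camo_contrasts` data frame with 10 rows.
#' @export
tukey_pairwise <- function(fit) {
  stopifnot(inherits(fit, "camo_mixed"))
  if (!"treatment" %in% fit$fixed_terms)
    stop("`treatment` is not among the model's fixed terms")
  glht_table(fit, multcomp::mcp(treatment = "Tukey"),
             adjustment = "tukey_single_step")
}

#' @export
print.camo_contrasts <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$estimate <- round(y$estimate, digits); y$se <- round(y$se, digits)
  y$t <- round(y$t, 3)
  y$p_raw <- signif(y$p_raw, 3); y$p_adjusted <- signif(y$p_adjusted, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Estimated marginal treatment means
#'
#' Population-level predictions per treatment, averaged over the square
#' sizes (on the response scale for the normal model, the logit scale for
#' the binomial model; only the ordering is used downstream).
#'
#' @param fit A `camo_mixed`.
#' @return Named numeric vector over the treatment levels.
#' @export
treatment_means <- function(fit) {
  stopifnot(inherits(fit, "camo_mixed"))
  nd <- expand.grid(treatment = as_treatment(TREATMENTS),
                    square_size = as_size(SIZES))
  pr <- if (inherits(fit$fit, "merMod")) {
    predict(fit$fit, newdata = nd, re.form = NA)
  } else {
    predict(fit$fit, newdata = nd)
  }
  tapply(pr, nd$treatment, mean)[TREATMENTS]
}

#' Summarise pairwise results as a treatment ordering
#'
#' Groups treatments that are not significantly different (adjusted p >=
#' alpha in the pairwise table), orders groups by their estimated means,
#' and renders a string such as
#' `"Border>(Square = Stripe)>(Dark = Light)"`. Grouping is greedy down
#' the mean-ordered levels; if the significance pattern is
#' non-transitive (a pair split across groups is itself non-significant,
#' or a within-group pair significant) the rendering is kept but a
#' warning marks the overlap, and `clean` is `FALSE`. Non-estimable pairs
#' are treated as undecidable (grouped together) with a warning.
#'
#' @param pairwise A `camo_contrasts` table with all 10 treatment pairs.
#' @param means Named vector of treatment means, as from
#'   [treatment_means()].
#' @param alpha Significance level for grouping (default 0.05).
#' @return Object of class `camo_ordering`: list with `string`, `groups`
#'   (list of level vectors, fastest-detected group last), `means`,
#'   `clean`.
#' @export
ordering_summary <- function(pairwise, means, alpha = 0.05) {
  stopifnot(inherits(pairwise, "data.frame"),
            all(TREATMENTS %in% names(means)))
  if (any(!pairwise$estimable))
    warning("non-estimable pair(s) treated as undecidable: ",
            paste(pairwise$pair[!pairwise$estimable], collapse = ", "))
  sig <- function(a, b) {
    i <- match(TRUE, (grepl(a, pairwise$pair, fixed = TRUE) &
                      grepl(b, pairwise$pair, fixed = TRUE)))
    if (is.na(i)) stop("pairwise table lacks the ", a, "-", b, " comparison")
    isTRUE(pairwise$estimable[i] && pairwise$p_adjusted[i] < alpha)
  }
  lev <- names(sort(means, decreasing = TRUE))
  groups <- list(lev[1])
  for (l in lev[-1]) {
    g <- groups[[length(groups)]]
    if (all(!vapply(g, sig, logical(1), b = l))) {
      groups[[length(groups)]] <- c(g, l)
    } else {
      groups <- c(groups, list(l))
    }
  }
  clean <- TRUE
  for (i in seq_along(lev)) for (j in seq_along(lev)) if (i < j) {
    same <- any(vapply(groups, function(g)
      all(c(lev[i], lev[j]) %in% g), logical(1)))
    if (same == sig(lev[i], lev[j])) clean <- FALSE
  }
  if (!clean)
    warning("non-transitive significance pattern; groups overlap")
  render <- function(g) if (length(g) == 1) g else
    paste0("(", paste(g, collapse = " = "), ")")
  structure(list(string = paste(vapply(groups, render, character(1)),
                                collapse = ">"),
                 groups = groups, means = means[lev], clean = clean),
            class = "camo_ordering")
}

#' @export
print.camo_ordering <- function(x, ...) {
  cat(x$string, if (!x$clean) " [overlapping groups]", "\n", sep = "")
  invisible(x)
}

#' Classical repeated-measures ANOVA cross-check
#'
#' The mixed-model conclusions are cross-checked with classical
#' univariate ANOVA: mean response time, and arc-sine-square-root
#' transformed error proportions, each modelled with subject as a random
#' (error) stratum and square size, treatment and their interaction as
#' fixed effects, with no model simplification.
#'
#' @param cells Balanced cell table from [estimate_cells()].
#' @return Data frame with one row per response x term: `response`,
#'   `term`, `df`, `df_error`, `F`, `p`.
#' @export
anova_crosscheck <- function(cells) {
  cells <- as.data.frame(cells)
  cells$subject <- factor(cells$subject)
  cells$treatment <- as_treatment(cells$treatment)
  cells$square_size <- as_size(cells$square_size)
  counts <- table(cells$subject, cells$treatment, cells$square_size)
  if (any(counts != 1L))
    stop("unbalanced cell table: classical ANOVA requires one row per ",
         "subject x treatment x size cell")
  cells$prop_asin <- asin(sqrt(cells$n_errors / cells$n_responded))
  one <- function(response, label) {
    f <- as.formula(paste(response,
                          "~ square_size * treatment + Error(subject)"))
    sm <- summary(aov(f, data = cells))
    within <- sm[["Error: Within"]][[1]]
    terms <- trimws(rownames(within))
    keep <- terms != "Residuals"
    data.frame(response = label, term = terms[keep],
               df = within$Df[keep],
               df_error = within$Df[terms == "Residuals"],
               F = within$`F value`[keep],
               p = within$`Pr(>F)`[keep])
  }
  out <- rbind(one("mean_hat", "mean_rt"),
               one("prop_asin", "error_prop_asinsqrt"))
  rownames(out) <- NULL
  out
}
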