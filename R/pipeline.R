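#' Run the full analysis chain on a trial table
#'
#' From a trial table to treatment-ordering conclusions:
#' \enumerate{
#'   \item censored-corrected cell estimates ([estimate_cells()]);
#'   \item for each response (mean RT, error proportion): ML mixed-model
#'     fits with interaction, additive, size-only and treatment-only
#'     fixed structures; deviance chi-square tests of the interaction
#'     (df 4), the treatment main effect (df 4) and the size main effect
#'     (df 1);
#'   \item simple contrasts of every treatment against Border (no
#'     multiplicity correction) and Tukey-type all-pairwise comparisons,
#'     both from the additive fit;
#'   \item a marginal ordering summary from the pairwise table; when the
#'     interaction is significant at `alpha`, additional per-size
#'     orderings from single-size treatment fits;
#'   \item the classical repeated-measures ANOVA cross-check.
#' }
#' The marginal ordering is always reported (it is the average pattern
#' over sizes); the per-size orderings qualify it when the interaction
#' matters.
#'
#' @param trials Trial table (see [simulate_experiment()]).
#' @param alpha Significance level for orderings (default 0.05).
#' @param nAGQ Quadrature nodes for binomial fits.
#' @return Object of class `camo_analysis`: list with `cells`, and per
#'   response (`rt`, `errors`) the fits, `lrts`, `contrasts_border`,
#'   `tukey`, `means`, `ordering` (+ `ordering_by_size` when the
#'   interaction is significant), plus `anova` and `alpha`.
#' @export
analyse_trials <- function(trials, alpha = 0.05, nAGQ = 5) {
  cells <- estimate_cells(trials)
  one_response <- function(kind) {
    full <- fit_mixed(cells, kind,
                      c("square_size", "treatment", "square_size:treatment"),
                      nAGQ = nAGQ)
    additive <- fit_mixed(cells, kind, c("square_size", "treatment"),
                          nAGQ = nAGQ)
    size_only <- fit_mixed(cells, kind, "square_size", nAGQ = nAGQ)
    trt_only <- fit_mixed(cells, kind, "treatment", nAGQ = nAGQ)
    lrts <- list(interaction = lrt(full, additive),
                 treatment = lrt(additive, size_only),
                 square_size = lrt(additive, trt_only))
    cb <- contrasts_vs_reference(additive)
    tk <- tukey_pairwise(additive)
    mn <- treatment_means(additive)
    ord <- ordering_summary(tk, mn, alpha = alpha)
    res <- list(fits = list(full = full, additive = additive,
                            size_only = size_only, treatment_only = trt_only),
                lrts = lrts, contrasts_border = cb, tukey = tk,
                means = mn, ordering = ord)
    if (lrts$interaction$p < alpha) {
      res$ordering_by_size <- lapply(stats::setNames(SIZES, SIZES),
        function(s) {
          sub <- cells[cells$square_size == s, ]
          f <- fit_mixed(sub, kind, "treatment", nAGQ = nAGQ)
          ordering_summary(tukey_pairwise(f), treatment_means(f),
                           alpha = alpha)
        })
    }
    res
  }
  rt <- one_response("normal_mean_rt")
  errors <- one_response("binomial_errors")
  anova <- tryCatch(anova_crosscheck(cells), error = function(e) {
    warning("ANOVA cross-check skipped: ", conditionMessage(e))
    NULL
  })
  structure(list(cells = cells, rt = rt, errors = errors, anova = anova,
                 alpha = alpha),
            class = "camo_analysis")
}

#' Run a complete simulated experiment end to end
#'
#' Design, simulation, censored estimation and inference as one
#' reproducible run. Every stage is seeded from `seed`, so reruns with
#' the same configuration are identical. If `out_dir` is given, the trial
#' table, cell estimates, contrast tables, a plain-text report and a
#' provenance manifest (configuration, seed, package and R versions) are
#' written there.
#'
#' @param profile Observer preset name (see [preset_effect_profiles()]),
#'   ignored when `observer` is supplied.
#' @param n_subjects Number of simulated subjects (reference design: 25).
#' @param seed Integer master seed.
#' @param observer Optional explicit `camo_observer`.
#' @param n_blocks Main blocks per subject (default 4, i.e. 200 main
#'   trials).
#' @param alpha Significance level.
#' @param nAGQ Quadrature nodes for binomial fits.
#' @param out_dir Optional output directory.
#' @return Object of class `camo_run`: list with `config`, `observer`,
#'   `trials`, `analysis`.
#' @examples
#' \donttest{
#' run <- run_experiment("chromatic_like", n_subjects = 6, seed = 1)
#' print(run)
#' }
#' @export
run_experiment <- function(profile = "chromatic_like", n_subjects = 25,
                           seed = 1, observer = NULL, n_blocks = 4,
                           alpha = 0.05, nAGQ = 5, out_dir = NULL) {
  if (is.null(observer)) observer <- preset_effect_profiles(profile)
  config <- list(profile = if (is.null(attr(observer, "profile"))) "custom"
                 else attr(observer, "profile"),
                 n_subjects = n_subjects, n_blocks = n_blocks,
                 seed = seed, alpha = alpha, nAGQ = nAGQ)
  trials <- simulate_experiment(observer, n_subjects, master_seed = seed,
                                n_blocks = n_blocks)
  analysis <- analyse_trials(trials, alpha = alpha, nAGQ = nAGQ)
  run <- structure(list(config = config, observer = observer,
                        trials = trials, analysis = analysis),
                   class = "camo_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @keywords internal
#' @noRd
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(run$analysis$cells, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  for (resp in c("rt", "errors")) {
    utils::write.csv(run$analysis[[resp]]$tukey,
                     file.path(out_dir, paste0("tukey_", resp, ".csv")),
                     row.names = FALSE)
    utils::write.csv(run$analysis[[resp]]$contrasts_border,
                     file.path(out_dir, paste0("contrasts_border_", resp, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(config = run$config,
                   observer_profile = attr(run$observer, "profile"),
                   package_version = as.character(utils::packageVersion("camobreak")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  report <- utils::capture.output(print(run))
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.camo_run <- function(x, ...) {
  cfg <- x$config
  cat("Camouflage search experiment run\n")
  cat(sprintf("  profile %s | %d subjects x %d main trials | seed %s\n",
              cfg$profile, cfg$n_subjects, 50 * cfg$n_blocks,
              format(cfg$seed)))
  main <- x$trials[!x$trials$practice, ]
  cat(sprintf("  %d main trials, %.2f%% censored (time-outs)\n",
              nrow(main), 100 * mean(main$censored)))
  for (resp in c("rt", "errors")) {
    r <- x$analysis[[resp]]
    cat(if (resp == "rt") "\n  Detection time (censored-corrected means):\n"
        else "\n  Wrong-side errors (binomial, logit link):\n")
    for (nm in names(r$lrts)) {
      l <- r$lrts[[nm]]
      cat(sprintf("    %-12s X2 = %7.2f, df = %d, p = %.4g\n",
                  nm, l$chi2, l$df, l$p))
    }
    cat("    ordering: ", r$ordering$string, "\n")
    if (!is.null(r$ordering_by_size)) {
      for (s in names(r$ordering_by_size))
        cat(sprintf("    ordering (%s): %s\n", s,
                    r$ordering_by_size[[s]]$string))
    }
  }
  invisible(x)
}

#' @export
summary.camo_run <- function(object, ...) {
  print(object)
  cat("\n  Contrasts vs Border (detection time):\n")
  print(object$analysis$rt$contrasts_border)
  cat("\n  Contrasts vs Border (errors):\n")
  print(object$analysis$errors$contrasts_border)
  if (!is.null(object$analysis$anova)) {
    cat("\n  Classical ANOVA cross-check:\n")
    print(object$analysis$anova, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.camo_run <- function(x, ...) {
  cells <- x$analysis$cells
  agg <- function(v) tapply(v, list(cells$treatment, cells$square_size),
                            mean, na.rm = TRUE)
  se <- function(v) tapply(v, list(cells$treatment, cells$square_size),
                           function(z) sd(z, na.rm = TRUE) / sqrt(sum(!is.na(z))))
  old <- par(mfrow = c(1, 2), mar = c(6, 4, 2, 1))
  on.exit(par(old))
  panel <- function(m, s, ylab) {
    xs <- seq_len(nrow(m))
    matplot(xs, m, type = "b", pch = c(19, 1), lty = 1, col = c(1, 2),
            xaxt = "n", xlab = "", ylab = ylab,
            ylim = range(c(m - s, m + s), na.rm = TRUE))
    axis(1, at = xs, labels = rownames(m), las = 2)
    for (k in 1:2) {
      ok <- is.finite(s[, k]) & s[, k] > 0
      if (any(ok))
        arrows(xs[ok], m[ok, k] - s[ok, k], xs[ok], m[ok, k] + s[ok, k],
               angle = 90, code = 3, length = 0.03, col = k)
    }
    legend("topleft", legend = colnames(m), pch = c(19, 1), col = c(1, 2),
           bty = "n")
  }
  panel(agg(cells$mean_hat), se(cells$mean_hat), "mean detection time (s)")
  p <- cells$n_errors / cells$n_responded
  panel(agg(p), se(p), "error proportion")
  invisible(x)
}

#' Deterministic miniature dataset for tests and examples
#'
#' Simulates 3 subjects through a single block (150 main trials) under
#' the chromatic-like profile, exercising all 10 treatment x size cells.
#'
#' @param seed Integer seed (default 42).
#' @return Trial table of 150 main trials.
#' @export
make_fixtures <- function(seed = 42) {
  simulate_experiment(preset_effect_profiles("chromatic_like"),
                      n_subjects = 3, master_seed = seed, n_blocks = 1,
                      include_practice = FALSE)
}
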