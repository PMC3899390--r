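test_that("balanced normal mixed model matches GLS and OLS oracles", {
  fit <- fit_mixed(fx_cells, "normal_mean_rt", c("square_size", "treatment"))
  d <- fit$data
  X <- model.matrix(~ square_size + treatment, d)
  # on balanced data the GLS fixed effects collapse to OLS
  ols <- coef(lm(mean_hat ~ square_size + treatment, data = d))
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-6)
  # explicit GLS with the fitted variance components
  vc <- lme4::VarCorr(fit$fit)
  gls <- gls_oracle(d$mean_hat, X, d$subject,
                    var_subj = as.numeric(vc$subject[1, 1]),
                    var_resid = attr(vc, "sc")^2)
  expect_equal(unname(coef(fit)), unname(gls), tolerance = 1e-8)
})

test_that("single-subject data degrade to ordinary fixed-effect fits", {
  one <- fx_cells[fx_cells$subject == "S01", ]
  expect_warning(f_norm <- fit_mixed(one, "normal_mean_rt",
                                     c("square_size", "treatment")),
                 "single subject")
  expect_equal(f_norm$subject_variance, 0)
  expect_warning(f_bin <- fit_mixed(one, "binomial_errors",
                                    c("square_size", "treatment")),
                 "single subject")
  ref <- glm(cbind(n_errors, n_responded - n_errors) ~
               square_size + treatment, binomial, data = one)
  expect_equal(unname(coef(f_bin)), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(f_bin$deviance, -2 * as.numeric(logLik(ref)))
})

test_that("deviance tests behave like likelihood-ratio chi-squares", {
  kinds <- c("normal_mean_rt", "binomial_errors")
  for (kind in kinds) {
    full <- fit_mixed(fx_cells, kind,
                      c("square_size", "treatment", "square_size:treatment"))
    add <- fit_mixed(fx_cells, kind, c("square_size", "treatment"))
    so <- fit_mixed(fx_cells, kind, "square_size")
    nul <- fit_mixed(fx_cells, kind, character(0))

    inter <- lrt(full, add)
    expect_equal(inter$df, 4L)
    expect_gte(inter$chi2, 0)
    trt <- lrt(add, so)
    expect_equal(trt$df, 4L)
    expect_lt(trt$p, 1e-6)  # planted treatment effect is strong

    # chi2 additivity along the nested chain
    expect_equal(lrt(full, nul)$chi2,
                 lrt(full, add)$chi2 + lrt(add, so)$chi2 + lrt(so, nul)$chi2,
                 tolerance = 1e-6)

    same <- lrt(add, add)
    expect_equal(same$chi2, 0)
    expect_equal(same$p, 1)
    expect_error(lrt(so, add), "not nested")
  }
})

test_that("binomial deviance tests are stable across quadrature orders", {
  chi <- vapply(c(5, 10, 15), function(q) {
    add <- fit_mixed(fx_cells, "binomial_errors",
                     c("square_size", "treatment"), nAGQ = q)
    so <- fit_mixed(fx_cells, "binomial_errors", "square_size", nAGQ = q)
    lrt(add, so)$chi2
  }, numeric(1))
  expect_lt(max(abs(chi / chi[1] - 1)), 1e-3)
})

test_that("contrasts vs Border carry the planted signs, unadjusted", {
  add <- fit_mixed(fx_cells, "normal_mean_rt", c("square_size", "treatment"))
  cb <- contrasts_vs_reference(add)
  expect_equal(nrow(cb), 4L)
  expect_true(all(cb$estimate < 0))  # Border is slowest in the profile
  expect_equal(cb$p_raw, cb$p_adjusted)
  expect_true(all(cb$estimable))
  expect_error(contrasts_vs_reference(add, reference = "Nope"))
  so <- fit_mixed(fx_cells, "normal_mean_rt", "square_size")
  expect_error(contrasts_vs_reference(so), "not among")
})

test_that("Tukey adjustment lies between the raw and Bonferroni p-values", {
  for (kind in c("normal_mean_rt", "binomial_errors")) {
    add <- fit_mixed(fx_cells, kind, c("square_size", "treatment"))
    tk <- tukey_pairwise(add)
    expect_equal(nrow(tk), 10L)
    expect_true(all(tk$p_adjusted >= tk$p_raw))
    expect_true(all(tk$p_adjusted <= pmin(1, 10 * tk$p_raw) + 0.005))
    tk2 <- tukey_pairwise(add)
    expect_equal(tk$p_adjusted, tk2$p_adjusted)  # fixed integration seed
  }
})

test_that("zero-error treatments are flagged non-estimable", {
  cells <- fx_cells
  cells$n_errors[cells$treatment == "Dark"] <- 0L
  fit <- fit_mixed(cells, "binomial_errors", c("square_size", "treatment"))
  expect_identical(fit$zero_error_levels, "Dark")
  tk <- tukey_pairwise(fit)
  bad <- grepl("Dark", tk$pair)
  expect_true(all(!tk$estimable[bad]))
  expect_true(all(tk$estimable[!bad]))
  expect_warning(ordering_summary(tk, treatment_means(fit)),
                 "non-estimable")
})

test_that("ordering summaries group and render correctly", {
  lev <- c("Dark", "Light", "Stripe", "Square", "Border")
  mk <- function(p) {
    pairs <- combn(lev, 2)
    data.frame(pair = paste(pairs[1, ], "-", pairs[2, ]),
               estimate = 0, se = 1, t = 0,
               p_raw = p, p_adjusted = p,
               adjustment = "tukey_single_step", estimable = TRUE)
  }
  # all pairs significant, means a < b < c ... -> strict chain
  tab <- mk(0.001)
  means <- setNames(1:5, lev)
  o <- ordering_summary(tab, means)
  expect_identical(o$string, "Border>Square>Stripe>Light>Dark")
  expect_true(o$clean)
  # nothing significant -> one group
  o2 <- ordering_summary(mk(0.9), means)
  expect_length(o2$groups, 1L)
  expect_true(o2$clean)
  # planted pattern: Border alone, Square=Stripe, Dark=Light
  tab3 <- mk(0.001)
  eq <- function(a, b) tab3$pair %in% paste(a, "-", b) |
                       tab3$pair %in% paste(b, "-", a)
  tab3$p_adjusted[eq("Square", "Stripe") | eq("Dark", "Light")] <- 0.6
  means3 <- setNames(c(1.6, 1.61, 3.0, 3.01, 4.2), lev)
  o3 <- ordering_summary(tab3, means3)
  expect_identical(o3$string, "Border>(Square = Stripe)>(Light = Dark)")
  expect_true(o3$clean)
  # non-transitive pattern warns
  tab4 <- mk(0.001)
  tab4$p_adjusted[eq("Dark", "Light") | eq("Light", "Stripe")] <- 0.6
  expect_warning(o4 <- ordering_summary(tab4, means), "non-transitive")
  expect_false(o4$clean)
})

test_that("classical ANOVA cross-check concurs with the deviance tests", {
  av <- anova_crosscheck(fx_cells)
  expect_equal(nrow(av), 6L)
  expect_true(all(av$F >= 0))
  expect_setequal(unique(av$term),
                  c("square_size", "treatment", "square_size:treatment"))
  # planted strong treatment effect: both routes call it significant
  add <- fit_mixed(fx_cells, "normal_mean_rt", c("square_size", "treatment"))
  so <- fit_mixed(fx_cells, "normal_mean_rt", "square_size")
  expect_lt(lrt(add, so)$p, 0.001)
  expect_lt(av$p[av$response == "mean_rt" & av$term == "treatment"], 0.001)
  # unbalanced input is rejected
  expect_error(anova_crosscheck(fx_cells[-1, ]), "unbalanced")
})

test_that("arc-sine-square-root endpoints transform to 0 and pi/2", {
  cells <- fx_cells[fx_cells$subject %in% c("S01", "S02"), ]
  cells$n_errors <- 0L
  cells$n_errors[cells$subject == "S02"] <- cells$n_responded[cells$subject == "S02"]
  expect_silent(av <- anova_crosscheck(cells))
  expect_true(is.data.frame(av))
  p <- cells$n_errors / cells$n_responded
  expect_equal(range(asin(sqrt(p))), c(0, pi / 2))
})
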