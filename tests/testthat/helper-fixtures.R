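# Shared fixtures, built once per test run.

# Miniature trial set: 3 subjects x 1 block under the chromatic-like
# profile (150 main trials, all 10 cells present).
fx_trials <- make_fixtures(seed = 42)

# A medium simulated experiment with clear planted effects, for the
# inference tests: 8 subjects through the full 4-block design.
fx_obs <- preset_effect_profiles("chromatic_like")
fx_exp <- simulate_experiment(fx_obs, n_subjects = 8, master_seed = 99,
                              include_practice = FALSE)
fx_cells <- suppressMessages(estimate_cells(fx_exp))

# Grid-search oracle for the censored log-normal MLE: brute force over a
# (mu, log sigma) grid, independent of the optimiser under test.
grid_mle_censored <- function(times, censored, mu_range, sigma_range,
                              n_grid = 201) {
  mus <- seq(mu_range[1], mu_range[2], length.out = n_grid)
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_grid))
  best <- c(NA, NA, -Inf)
  t_unc <- times[!censored]
  t_cen <- times[censored]
  for (m in mus) for (s in sigmas) {
    ll <- sum(dlnorm(t_unc, m, s, log = TRUE))
    if (length(t_cen))
      ll <- ll + sum(plnorm(t_cen, m, s, lower.tail = FALSE, log.p = TRUE))
    if (ll > best[3]) best <- c(m, s, ll)
  }
  list(mu = best[1], sigma = best[2], loglik = best[3])
}

# Closed-form GLS for a one-way random-intercept model with known
# variance components: beta = (X' V^-1 X)^-1 X' V^-1 y.
gls_oracle <- function(y, X, subject, var_subj, var_resid) {
  Z <- model.matrix(~ 0 + factor(subject))
  V <- var_subj * tcrossprod(Z) + diag(var_resid, length(y))
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}
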