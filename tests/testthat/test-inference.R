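test_that("log_posterior decomposes and matches exponential/gamma conjugacy", {
  d <- conjugate_data()
  con <- single_expert_constraint(
    elicited_density("normal", c(0.5, 0.2), timepoint = 1))
  pr <- list(prior_gamma(2, 3))
  m <- surv_model("exponential", 0.6)
  lp <- log_posterior(m, d, list(con), pr)
  expect_equal(as.numeric(lp),
               attr(lp, "loglik") + attr(lp, "logpen") +
                 dgamma(0.6, 2, 3, log = TRUE) + log(0.6),
               tolerance = 1e-12)

  # flat prior, no constraints: equals loglik up to an additive constant
  flat <- list(prior_uniform(-20, 20))
  m2 <- surv_model("exponential", 1.1)
  diff_lp <- as.numeric(log_posterior(m2, d, prior = flat)) -
    as.numeric(log_posterior(m, d, prior = flat))
  expect_equal(diff_lp, log_likelihood(d, m2) - log_likelihood(d, m),
               tolerance = 1e-12)

  # gamma prior, no constraints: matches the conjugate posterior kernel
  # (transformed scale, so the Jacobian log(theta) rides along)
  posts <- vapply(c(0.4, 0.9, 1.7), function(th) {
    as.numeric(log_posterior(surv_model("exponential", th), d, prior = pr)) -
      (dgamma(th, 2 + 10, 3 + 7, log = TRUE) + log(th))
  }, numeric(1))
  expect_lt(max(posts) - min(posts), 1e-10)
})

test_that("conjugate_exponential_posterior adds sufficient statistics", {
  d <- conjugate_data()
  expect_equal(conjugate_exponential_posterior(c(8, 10), d),
               c(shape = 18, rate = 17))
  lp <- pool_opinions(fig1_components(), method = "log")
  expect_equal(conjugate_exponential_posterior(lp, d),
               c(shape = 24, rate = 17))
  expect_equal(conjugate_exponential_posterior(c(8, 10), NULL),
               c(shape = 8, rate = 10))
  expect_error(conjugate_exponential_posterior(
    pool_opinions(fig1_components(), method = "linear"), d), "logarithmic")
  expect_error(conjugate_exponential_posterior(
    elicited_density("normal", c(0.5, 0.1)), d), "gamma")
})

test_that("penalized ML recovers the exponential MLE and diffuse limit", {
  d <- surv_data(c(1, 2, 3), c(1, 1, 0))
  f <- fit_penalized_ml(d, "exponential", seed = 3)
  expect_equal(unname(f$estimate), 2 / 6, tolerance = 1e-6)
  expect_true(f$converged)

  con <- single_expert_constraint(
    elicited_density("normal", c(0.5, 1e6), timepoint = 4))
  f2 <- fit_penalized_ml(d, "exponential", list(con), seed = 3)
  expect_equal(unname(f2$estimate), 2 / 6, tolerance = 1e-4)

  # near-degenerate opinion pins the fitted survival at t*
  dat <- simulate_survival_data(surv_model("exponential", 0.3), 20, seed = 4)
  tight <- single_expert_constraint(
    elicited_density("normal", c(0.5, 0.005), timepoint = 4))
  f3 <- fit_penalized_ml(dat, "exponential", list(tight), seed = 3)
  expect_lt(abs(psurv(f3$model, 4) - 0.5), 0.02)
})

test_that("MCMC matches the conjugate gamma posterior", {
  d <- conjugate_data()
  fit <- fit_mcmc(d, "exponential", prior = list(prior_gamma(1, 1)),
                  chains = 2, iter = 4000, seed = 11)
  th <- fit$draws[, 1]
  mcse <- sd(th) / sqrt(ess(th))
  expect_lt(abs(mean(th) - 11 / 8), 3 * mcse)
  expect_lt(ks_distance(th, function(q) pgamma(q, 11, 8)), 0.05)
  expect_true(all(fit$diagnostics$rhat < 1.05))

  # reproducibility
  fit2 <- fit_mcmc(d, "exponential", prior = list(prior_gamma(1, 1)),
                   chains = 2, iter = 4000, seed = 11)
  expect_identical(fit$draws, fit2$draws)
})

test_that("near-empty data recovers the prior", {
  d <- surv_data(1e-8, 0)
  expect_warning(
    fit <- fit_mcmc(d, "exponential", prior = list(prior_gamma(2, 2)),
                    chains = 2, iter = 4000, seed = 9),
    "zero events")
  th <- fit$draws[, 1]
  # Gamma(2, 2): mean 1, sd 1/sqrt(2)
  expect_lt(abs(mean(th) - 1), 3 * sd(th) / sqrt(ess(th)) + 0.05)
  expect_lt(abs(sd(th) - 1 / sqrt(2)), 0.1)
})

test_that("tight opinion dominates the posterior survival at t*", {
  dat <- simulate_survival_data(surv_model("exponential", 0.3), 20, seed = 4)
  tight <- single_expert_constraint(
    elicited_density("normal", c(0.5, 0.005), timepoint = 4))
  fit <- fit_mcmc(dat, "exponential", list(tight), chains = 2, iter = 3000,
                  seed = 5)
  s4 <- exp(-4 * fit$draws[, 1])
  expect_lt(abs(median(s4) - 0.5), 0.02)
})

test_that("posterior survival curves: ordering, t = 0, conjugate quantiles", {
  d <- conjugate_data()
  fit <- fit_mcmc(d, "exponential", prior = list(prior_gamma(1, 1)),
                  chains = 2, iter = 5000, seed = 2)
  tab <- posterior_survival_curve(fit, c(0, 0.5, 1, 2, 4))
  expect_equal(unlist(tab[1, -1]), c(q2.5 = 1, q50 = 1, q97.5 = 1))
  expect_true(all(tab$q2.5 <= tab$q50 & tab$q50 <= tab$q97.5))
  expect_true(all(diff(tab$q50) <= 0))
  # S(t) is a monotone transform of theta ~ G(11, 8)
  for (i in 2:nrow(tab)) {
    t <- tab$time[i]
    expect_lt(abs(tab$q50[i] - exp(-qgamma(0.5, 11, 8) * t)), 0.02)
    expect_lt(abs(tab$q97.5[i] - exp(-qgamma(0.025, 11, 8) * t)), 0.03)
  }
})

test_that("MCMC mode agrees with penalized ML on a matched problem", {
  dat <- simulate_survival_data(surv_model("weibull_aft", c(1.3, 4)), 80,
                                censoring = list(type = "admin", time = 3),
                                seed = 6)
  con <- list(simulate_expert_opinion(surv_model("weibull_aft", c(1.3, 4)),
                                      6, rel_bias = 0))
  pml <- fit_penalized_ml(dat, "weibull_aft", con, seed = 6)
  fit <- fit_mcmc(dat, "weibull_aft", con,
                  prior = preset_priors("weibull_aft", "uniform"),
                  chains = 2, iter = 3000, seed = 6)
  for (j in 1:2) {
    dens <- density(fit$draws_z[, j])
    mode_j <- dens$x[which.max(dens$y)]
    expect_lt(abs(mode_j - pml$z_hat[j]), 2 * sd(fit$draws_z[, j]))
  }
})

test_that("draws export CSV has parameter, chain and iter columns", {
  d <- conjugate_data()
  fit <- fit_mcmc(d, "exponential", chains = 2, iter = 400, seed = 1)
  path <- tempfile(fileext = ".csv")
  export_draws(fit, path)
  df <- read.csv(path)
  expect_named(df, c("rate", "chain", "iter"))
  expect_equal(nrow(df), nrow(fit$draws))
})
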