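test_that("exponential closed forms and Weibull nesting", {
  m <- surv_model("exponential", 0.5)
  expect_identical(psurv(m, 0), 1)
  expect_equal(psurv(m, 2), exp(-1), tolerance = 1e-12)
  expect_equal(hsurv(m, c(0.1, 1, 7)), rep(0.5, 3), tolerance = 1e-12)

  w <- surv_model("weibull_aft", c(1, 2))  # shape 1 == exponential rate 1/2
  tt <- c(0.2, 1, 2, 5)
  expect_equal(psurv(w, tt), psurv(m, tt), tolerance = 1e-12)
  expect_equal(hsurv(w, 1), 0.5, tolerance = 1e-12)

  # Gompertz hazard b * exp(a t) tends to b as a -> 0
  g <- surv_model("gompertz", c(1e-13, 0.3))
  expect_equal(hsurv(g, 5), 0.3, tolerance = 1e-9)
  g2 <- surv_model("gompertz", c(1e-6, 0.3))
  expect_equal(hsurv(g2, 5), 0.3, tolerance = 1e-4)
})

test_that("right-censored log-likelihood matches closed forms", {
  d <- surv_data(c(1, 2, 3), c(1, 1, 0))
  m <- surv_model("exponential", 0.5)
  expect_equal(log_likelihood(d, m), 2 * log(0.5) - 0.5 * 6,
               tolerance = 1e-12)
  expect_equal(log_likelihood(surv_data(2, 0), m), -1, tolerance = 1e-12)
  expect_equal(log_likelihood(d, surv_model("weibull_aft", c(1, 2))),
               2 * log(0.5) - 3, tolerance = 1e-10)

  # h^v * S form agrees with the f^v * S^(1-v) form
  for (mod in family_examples()) {
    alt <- sum(d$status * log(hsurv(mod, d$time)) +
                 log(psurv(mod, d$time)))
    expect_equal(log_likelihood(d, mod), alt, tolerance = 1e-10)
  }

  # additivity over single-row subsets
  for (mod in family_examples()) {
    per_row <- vapply(seq_along(d$time), function(i)
      log_likelihood(surv_data(d$time[i], d$status[i]), mod), numeric(1))
    expect_equal(log_likelihood(d, mod), sum(per_row), tolerance = 1e-10)
  }

  # zero density at an event -> -Inf, not an error (decreasing spline)
  bad <- surv_model("royston_parmar", c(0, -1), knots = c(0, 1))
  expect_identical(log_likelihood(d, bad), -Inf)
})

test_that("summary quantities: median and mean", {
  m <- surv_model("exponential", 0.5)
  expect_equal(summary_survival(m, "median"), log(2) / 0.5, tolerance = 1e-10)
  expect_equal(summary_survival(m, "mean"), 2, tolerance = 1e-10)
  expect_equal(summary_survival(surv_model("lognormal", c(0, 1)), "median"),
               1, tolerance = 1e-10)

  # improper Gompertz: plateau exp(b/a) = exp(-0.4) > 0.5
  gneg <- surv_model("gompertz", c(-0.5, 0.2))
  expect_error(summary_survival(gneg, "median"), "plateau")
  expect_error(summary_survival(gneg, "mean"), "horizon")
  expect_gt(summary_survival(gneg, "mean", horizon = 100), 0)

  # median solves S(t) = 0.5 for every family
  for (mod in family_examples()) {
    med <- summary_survival(mod, "median")
    expect_equal(psurv(mod, med), 0.5, tolerance = 1e-7)
  }
})

test_that("family properties: S(0)=1, monotone S, f = h*S, proper density", {
  grid <- seq(1e-6, 40, length.out = 1000)
  for (nm in names(family_examples())) {
    mod <- family_examples()[[nm]]
    expect_identical(psurv(mod, 0), 1)
    S <- psurv(mod, grid)
    expect_true(all(diff(S) <= 1e-12), info = nm)
    expect_true(all(hsurv(mod, grid[S > 1e-12]) >= 0), info = nm)
    tot <- integrate(function(x) dsurv(mod, x), 0, Inf,
                     rel.tol = 1e-9)$value
    expect_true(tot >= 0.99 && tot <= 1 + 1e-6, info = nm)
    tpts <- c(0.3, 1.7, 6.2)
    expect_equal(dsurv(mod, tpts), hsurv(mod, tpts) * psurv(mod, tpts),
                 tolerance = 1e-10, info = nm)
  }
})

test_that("generalized gamma nests Weibull and log-normal", {
  tt <- seq(0, 12, by = 0.5)
  gg1 <- surv_model("gengamma", c(log(2), 1 / 1.3, 1))
  wb <- surv_model("weibull_aft", c(1.3, 2))
  expect_equal(psurv(gg1, tt), psurv(wb, tt), tolerance = 1e-6)
  gg0 <- surv_model("gengamma", c(0.5, 0.8, 0))
  ln <- surv_model("lognormal", c(0.5, 0.8))
  expect_equal(psurv(gg0, tt), psurv(ln, tt), tolerance = 1e-6)
})

test_that("parameter validation", {
  expect_error(surv_model("exponential", c(1, 2)), "parameter")
  expect_error(surv_model("weibull_aft", c(-1, 2)), "> 0")
  expect_error(surv_model("nonsense", 1))
  expect_error(surv_model("royston_parmar", c(0, 1)), "knots")
  expect_error(surv_model("royston_parmar", c(0, 1, 0), knots = c(1, 0, 2)),
               "increasing")
  expect_error(psurv(surv_model("exponential", 1), -1), ">= 0")
  expect_error(hsurv(surv_model("exponential", 1), 0), "t > 0")
})

test_that("binary covariate: PH and AFT scales", {
  # exponential is PH: S(t | arm = 1) = S0(t)^exp(beta)
  m <- surv_model("exponential", 0.4, coef = 0.7)
  tt <- c(0.5, 2, 6)
  expect_equal(psurv(m, tt, arm = 1), psurv(m, tt, arm = 0)^exp(0.7),
               tolerance = 1e-12)
  expect_equal(hsurv(m, 1, arm = 1), 0.4 * exp(0.7), tolerance = 1e-12)

  # weibull is AFT: S(t | arm = 1) = S0(t * exp(-beta))
  w <- surv_model("weibull_aft", c(1.4, 3), coef = 0.5)
  expect_equal(psurv(w, tt, arm = 1), psurv(w, tt * exp(-0.5), arm = 0),
               tolerance = 1e-12)
  # density still integrates to 1 in the adjusted arm
  expect_equal(integrate(function(x) dsurv(w, x, arm = 1), 0, Inf)$value,
               1, tolerance = 1e-6)
  # log-likelihood uses the arm column
  d <- surv_data(c(1, 2, 3), c(1, 1, 0), arm = c(0, 1, 1))
  manual <- sum(log(dsurv(w, c(1, 2), arm = c(0, 1)))) +
    log(psurv(w, 3, arm = 1))
  expect_equal(log_likelihood(d, w), manual, tolerance = 1e-12)
})

test_that("inverse survival round-trips and supports simulation", {
  for (nm in names(family_examples())) {
    mod <- family_examples()[[nm]]
    p <- c(0.9, 0.5, 0.1)
    expect_equal(psurv(mod, qsurv(mod, p)), p, tolerance = 1e-7, info = nm)
  }
  # improper Gompertz: survival never reaches small p
  gneg <- surv_model("gompertz", c(-0.5, 0.2))
  expect_identical(qsurv(gneg, 0.5), Inf)
})
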