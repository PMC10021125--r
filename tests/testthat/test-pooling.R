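test_that("logarithmic pool of gammas is the averaged-parameter gamma", {
  lp <- pool_opinions(fig1_components(), method = "log")
  grid <- seq(0.05, 4, length.out = 1000)
  expect_lt(max(abs(dpool(lp, grid) - dgamma(grid, 14, 10))), 1e-8)
  # normalized
  expect_equal(integrate(function(x) dpool(lp, x), lp$support[1],
                         lp$support[2])$value, 1, tolerance = 1e-4)
})

test_that("identity and idempotence pools", {
  g <- elicited_density("gamma", c(8, 10), quantity = "median")
  x <- seq(0.1, 3, length.out = 50)
  for (method in c("linear", "log")) {
    one <- pool_opinions(list(g), method = method)
    expect_lt(max(abs(dpool(one, x) - dgamma(x, 8, 10))), 1e-8)
    three <- pool_opinions(list(g, g, g), method = method)
    expect_lt(max(abs(dpool(three, x) - dgamma(x, 8, 10))), 1e-8)
  }
})

test_that("linear pool is the mixture and is bimodal on the gamma example", {
  li <- pool_opinions(fig1_components(), method = "linear")
  expect_equal(dpool(li, 1), 0.5 * dgamma(1, 8, 10) + 0.5 * dgamma(1, 20, 10),
               tolerance = 1e-12)
  grid <- seq(0.01, 3, length.out = 600)
  dens <- dpool(li, grid)
  interior <- 2:(length(dens) - 1)
  n_max <- sum(dens[interior] > dens[interior - 1] &
                 dens[interior] > dens[interior + 1])
  expect_identical(n_max, 2L)
  # CDF is the weighted mean of component CDFs (marginalization-compatible)
  expect_equal(ppool(li, grid),
               0.5 * pgamma(grid, 8, 10) + 0.5 * pgamma(grid, 20, 10),
               tolerance = 1e-12)
  # ... which the logarithmic pool violates
  lp <- pool_opinions(fig1_components(), method = "log")
  mix_cdf <- 0.5 * pgamma(c(0.8, 1.2), 8, 10) + 0.5 * pgamma(c(0.8, 1.2), 20, 10)
  expect_gt(max(abs(ppool(lp, c(0.8, 1.2)) - mix_cdf)), 0.01)
})

test_that("pooled 95% intervals match the printed gamma example", {
  lp <- pool_opinions(fig1_components(), method = "log")
  expect_equal(round(pooled_quantile(lp, c(0.025, 0.975)), 2), c(0.77, 2.22))
  li <- pool_opinions(fig1_components(), method = "linear")
  expect_equal(round(pooled_quantile(li, c(0.025, 0.975)), 2), c(0.40, 2.79))
  # symmetric single-component pool: median is the location
  one <- pool_opinions(list(elicited_density("normal", c(0.4, 0.04))),
                       method = "log")
  expect_equal(pooled_quantile(one, 0.5), 0.4, tolerance = 1e-7)
  # with visible mass below 0, the [0,1] clipping shifts the median a hair
  wide <- pool_opinions(list(elicited_density("normal", c(0.4, 0.1))),
                        method = "log")
  expect_equal(pooled_quantile(wide, 0.5), 0.4, tolerance = 1e-4)
})

test_that("pooled_quantile inverts the pooled CDF", {
  ps <- seq(0.01, 0.99, length.out = 21)
  for (method in c("linear", "log")) {
    pool <- pool_opinions(fig1_components(), method = method)
    expect_equal(ppool(pool, pooled_quantile(pool, ps)), ps,
                 tolerance = 1e-6)
  }
})

test_that("externally Bayesian: log-pool-then-update = update-then-log-pool", {
  dat <- conjugate_data()  # sum v = 10, sum t = 7
  lp_prior <- pool_opinions(fig1_components(), method = "log")
  post_pooled <- conjugate_exponential_posterior(lp_prior, dat)
  expect_equal(post_pooled, c(shape = 24, rate = 17))
  # update each expert, then pool the posteriors
  posts <- list(elicited_density("gamma", c(18, 17), quantity = "median"),
                elicited_density("gamma", c(30, 17), quantity = "median"))
  pool_posts <- pool_opinions(posts, method = "log")
  grid <- seq(0.3, 3, length.out = 400)
  expect_lt(max(abs(dpool(pool_posts, grid) - dgamma(grid, 24, 17))), 1e-8)
})

test_that("linear pooling is order dependent (prior pool vs posterior pool)", {
  # posterior from the linearly pooled prior, by direct normalization
  lik <- function(th) th^10 * exp(-7 * th)
  li <- pool_opinions(fig1_components(), method = "linear")
  unnorm <- function(th) dpool(li, th) * lik(th)
  Z <- integrate(unnorm, 0, 10, rel.tol = 1e-10)$value
  grid <- seq(0.3, 3, length.out = 300)
  post_from_pooled_prior <- unnorm(grid) / Z
  # equal-weight linear pool of the two conjugate posteriors
  pool_of_posts <- 0.5 * dgamma(grid, 18, 17) + 0.5 * dgamma(grid, 30, 17)
  expect_gt(max(abs(post_from_pooled_prior - pool_of_posts)), 0.05)
  # sanity: the mixture posterior reweights the components by their
  # marginal likelihoods; check our numeric posterior against that form
  logm <- function(a, b) lgamma(a + 10) - lgamma(a) + a * log(b) -
    (a + 10) * log(b + 7)
  w1 <- 1 / (1 + exp(logm(20, 10) - logm(8, 10)))
  expect_equal(post_from_pooled_prior,
               w1 * dgamma(grid, 18, 17) + (1 - w1) * dgamma(grid, 30, 17),
               tolerance = 1e-6)
})

test_that("degenerate logarithmic pool raises an error", {
  a <- elicited_density("normal", c(0, 1e-4))
  b <- elicited_density("normal", c(1, 1e-4))
  expect_error(pool_opinions(list(a, b), method = "log"), "degenerate")
})

test_that("pooling validation", {
  g <- fig1_components()
  expect_error(pool_opinions(list(g[[1]],
    elicited_density("normal", c(0.5, 0.1), quantity = "survival_prob"))),
    "same quantity")
  expect_error(pool_opinions(g, weights = c(1, 2, 3)))
})
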