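#' Prior specifications
#'
#' Sampling and optimization run on an unconstrained transformed scale
#' (log for positive parameters, identity otherwise). Priors are
#' declared per parameter:
#' \itemize{
#'   \item `prior_uniform(lo, hi)` and `prior_normal(mean, sd)` apply on
#'     the transformed scale;
#'   \item `prior_gamma(shape, rate)` applies on the natural (positive)
#'     scale of a log-transformed parameter; the log-Jacobian is
#'     included automatically.
#' }
#' `preset_priors()` builds a full prior list for a family: `"uniform"`
#' gives Uniform(-20, 20) on every transformed parameter; `"vague"`
#' gives Gamma(1, 0.1) on positive parameters and Normal(0, 2.5) on real
#' ones — deliberately more informative than the flat default, for
#' prior-sensitivity checks.
#'
#' @name priors
NULL

#' @rdname priors
#' @param lo,hi finite uniform bounds (transformed scale).
#' @export
prior_uniform <- function(lo, hi) {
  stopifnot(is.finite(lo), is.finite(hi), lo < hi)
  structure(list(dist = "uniform", lo = lo, hi = hi), class = "prior_1d")
}

#' @rdname priors
#' @param mean,sd normal hyperparameters (transformed scale), `sd > 0`.
#' @export
prior_normal <- function(mean, sd) {
  stopifnot(is.finite(mean), sd > 0)
  structure(list(dist = "normal", mean = mean, sd = sd), class = "prior_1d")
}

#' @rdname priors
#' @param shape,rate gamma hyperparameters (natural scale), both > 0.
#' @export
prior_gamma <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  structure(list(dist = "gamma", shape = shape, rate = rate),
            class = "prior_1d")
}

#' @rdname priors
#' @param family family name (see [survival-families]).
#' @param kind `"uniform"` or `"vague"`.
#' @param knots Royston-Parmar knots, if applicable.
#' @param has_arm whether a covariate coefficient is included.
#' @export
preset_priors <- function(family, kind = c("uniform", "vague"),
                          knots = NULL, has_arm = FALSE) {
  kind <- match.arg(kind)
  skel <- .par_skeleton(family, knots, has_arm)
  lapply(seq_along(skel$transform), function(i) {
    if (kind == "uniform") return(prior_uniform(-20, 20))
    if (skel$transform[i] == "log") prior_gamma(1, 0.1)
    else prior_normal(0, 2.5)
  })
}

# weakly informative defaults: Normal(0, 5) on the transformed scale,
# except the generalized-gamma shape Q, where Normal(0, 2.5) still
# covers every practically relevant shape (|Q| <= 5 at 2 sd) but keeps
# the sampler off the unidentified large-|Q| ridge, whose degenerate
# geometry yields negative DIC p_D
.default_prior <- function(skel) {
  lapply(seq_along(skel$transform), function(i) {
    if (skel$par_names[i] == "Q") prior_normal(0, 2.5)
    else prior_normal(0, 5)
  })
}

## ---- transformed-scale plumbing ------------------------------------------

.par_skeleton <- function(family, knots = NULL, has_arm = FALSE) {
  info <- family_info(family, knots)
  names <- info$par_names
  transform <- info$transform
  if (has_arm) {
    names <- c(names, "coef")
    transform <- c(transform, "identity")
  }
  list(family = family, knots = knots, has_arm = has_arm,
       par_names = names, transform = transform, npar_family = info$npar,
       n = length(names))
}

.to_natural <- function(z, transform) {
  out <- z
  idx <- transform == "log"
  out[idx] <- exp(z[idx])
  out
}

.to_transformed <- function(par, transform) {
  out <- par
  idx <- transform == "log"
  out[idx] <- log(par[idx])
  out
}

.build_model <- function(skel, z) {
  nat <- .to_natural(z, skel$transform)
  coef <- if (skel$has_arm) nat[skel$n] else NULL
  surv_model(skel$family, nat[seq_len(skel$npar_family)],
             knots = skel$knots, coef = coef)
}

.log_prior_z <- function(z, skel, priors) {
  lp <- 0
  for (i in seq_along(z)) {
    pr <- priors[[i]]
    lp <- lp + switch(pr$dist,
      uniform = stats::dunif(z[i], pr$lo, pr$hi, log = TRUE),
      normal = stats::dnorm(z[i], pr$mean, pr$sd, log = TRUE),
      gamma = {
        if (skel$transform[i] != "log")
          stop("gamma priors apply only to positive (log-transformed) parameters")
        # density of theta = exp(z), plus log-Jacobian d theta / d z = theta
        stats::dgamma(exp(z[i]), pr$shape, pr$rate, log = TRUE) + z[i]
      })
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

#' Log posterior (or penalized log-likelihood plus prior)
#'
#' `log_likelihood + total_log_penalty + log prior`, with the prior
#' evaluated on the transformed scale (Jacobian included for
#' natural-scale gamma priors). Returns `-Inf`, never `NaN`, on
#' constraint violations.
#'
#' @param model a [surv_model].
#' @param data a [surv_data].
#' @param constraints list of [opinion_constraint].
#' @param prior list of per-parameter priors (see [priors]); `NULL`
#'   means the weakly informative default, Normal(0, 5) on each
#'   transformed parameter.
#' @return scalar log posterior with attributes `loglik` and `logpen`.
#' @export
log_posterior <- function(model, data, constraints = list(), prior = NULL) {
  stopifnot(inherits(model, "surv_model"))
  skel <- .par_skeleton(model$family, model$knots, !is.null(model$coef))
  if (is.null(prior)) prior <- .default_prior(skel)
  nat <- c(unname(model$params), if (skel$has_arm) model$coef)
  z <- .to_transformed(nat, skel$transform)
  ll <- log_likelihood(data, model)
  pen <- total_log_penalty(model, constraints)
  lpr <- .log_prior_z(z, skel, prior)
  val <- ll + pen + lpr
  if (is.nan(val)) val <- -Inf
  attr(val, "loglik") <- ll
  attr(val, "logpen") <- pen
  val
}

# target on the transformed scale; returns list(lp, ll, pen)
.make_target <- function(data, skel, constraints, prior, use_prior = TRUE) {
  force(data); force(skel); force(constraints); force(prior)
  function(z) {
    model <- tryCatch(.build_model(skel, z), error = function(e) NULL)
    if (is.null(model)) return(list(lp = -Inf, ll = -Inf, pen = -Inf))
    ll <- log_likelihood(data, model)
    if (!is.finite(ll)) return(list(lp = -Inf, ll = ll, pen = NA_real_))
    pen <- total_log_penalty(model, constraints)
    lp <- ll + pen
    if (use_prior) lp <- lp + .log_prior_z(z, skel, prior)
    if (is.nan(lp)) lp <- -Inf
    list(lp = lp, ll = ll, pen = pen)
  }
}

# crude moment-based initial values on the transformed scale
.init_z <- function(skel, data) {
  t <- data$time; v <- data$status
  r <- max(sum(v), 0.5) / sum(t)
  lt <- log(t[v == 1])
  if (length(lt) < 2) lt <- log(t)
  mu <- mean(lt); sig <- max(stats::sd(lt), 0.2)
  if (!is.finite(sig)) sig <- 0.5
  nat <- switch(skel$family,
    exponential = r,
    weibull_aft = c(1, 1 / r),
    gamma = c(1, r),
    gompertz = c(0, r),
    lognormal = c(mu, sig),
    loglogistic = c(1.2, exp(mu)),
    gengamma = c(mu, sig, 1),
    royston_parmar = c(log(r), 1, rep(0, skel$npar_family - 2)))
  if (skel$has_arm) nat <- c(nat, 0)
  .to_transformed(nat, skel$transform)
}

## ---- penalized maximum likelihood ---------------------------------------

#' Penalized maximum-likelihood fit
#'
#' Maximizes `log_likelihood + total_log_penalty` by multi-start
#' quasi-Newton optimization on the transformed scale (Nelder-Mead
#' exploration followed by BFGS polish). The covariance of the
#' transformed estimate comes from the numeric curvature at the optimum.
#'
#' @param data a [surv_data].
#' @param family family name.
#' @param constraints list of [opinion_constraint] (default none: plain
#'   maximum likelihood).
#' @param knots Royston-Parmar knots; default [rp_default_knots] with
#'   one internal knot.
#' @param starts number of optimizer starts (first from moment-based
#'   initials, the rest jittered).
#' @param seed RNG seed for the jitter.
#' @param init optional starting values on the transformed scale.
#' @return object of class `fit_result` with `mode = "penalized_ml"`.
#' @export
fit_penalized_ml <- function(data, family, constraints = list(),
                             knots = NULL, starts = 3, seed = 1,
                             init = NULL) {
  stopifnot(inherits(data, "surv_data"))
  if (sum(data$status) == 0)
    warning("dataset has zero events; likelihood is driven by censoring only")
  if (family == "royston_parmar" && is.null(knots))
    knots <- rp_default_knots(data)
  skel <- .par_skeleton(family, knots, !is.null(data$arm))
  target <- .make_target(data, skel, constraints, prior = NULL,
                         use_prior = FALSE)
  neg <- function(z) {
    v <- target(z)$lp
    if (!is.finite(v)) 1e12 else -v
  }
  z0 <- if (is.null(init)) .init_z(skel, data) else init
  set.seed(seed)
  trace <- list()
  best <- NULL
  for (s in seq_len(starts)) {
    zs <- if (s == 1) z0 else z0 + stats::rnorm(skel$n, 0, 0.4)
    op <- tryCatch({
      o1 <- if (skel$n > 1)
        stats::optim(zs, neg, method = "Nelder-Mead",
                     control = list(maxit = 1000, reltol = 1e-10))
      else list(par = zs)
      stats::optim(o1$par, neg, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12))
    }, error = function(e) NULL)
    trace[[s]] <- if (is.null(op)) "failed" else op$value
    if (!is.null(op) && op$value < 1e11 &&
        (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best))
    stop("penalized-ML optimization failed for every start; trace: ",
         paste(unlist(trace), collapse = ", "))
  z_hat <- best$par
  cov_z <- tryCatch({
    H <- stats::optimHess(z_hat, neg)
    solve(H)
  }, error = function(e) matrix(NA_real_, skel$n, skel$n))
  parts <- target(z_hat)
  model <- .build_model(skel, z_hat)
  structure(list(
    mode = "penalized_ml", family = family, skel = skel,
    model = model,
    estimate = stats::setNames(.to_natural(z_hat, skel$transform),
                               skel$par_names),
    z_hat = stats::setNames(z_hat, skel$par_names), cov_z = cov_z,
    loglik = parts$ll, logpen = parts$pen,
    converged = (best$convergence == 0),
    data = data, constraints = constraints, knots = knots,
    settings = list(starts = starts, seed = seed)),
    class = "fit_result")
}

## ---- adaptive random-walk Metropolis MCMC --------------------------------

#' Bayesian fit by adaptive random-walk Metropolis
#'
#' Samples the posterior `likelihood x opinion loss x prior` on the
#' transformed scale with a Gaussian random-walk proposal whose
#' covariance adapts during burn-in (scaled empirical covariance,
#' 2.38^2/d). Chains initialize at the penalized-ML estimate, jittered;
#' if that fails, at prior-ish random draws. Defaults mirror common
#' practice for this class of model: 3 chains of 10,000 iterations with
#' the first half discarded as burn-in.
#'
#' @inheritParams fit_penalized_ml
#' @param prior list of per-parameter priors (see [priors]); default
#'   Normal(0, 5) on each transformed parameter.
#' @param chains number of chains.
#' @param iter iterations per chain (including burn-in).
#' @param burn_in iterations discarded per chain (default `iter / 2`).
#' @param seed RNG seed; the fit is reproducible given the seed.
#' @return object of class `fit_result` with `mode = "bayes"`: retained
#'   draws on both scales, per-draw log-likelihood and log-penalty, and
#'   split-R-hat diagnostics (a warning is raised above 1.05).
#' @export
fit_mcmc <- function(data, family, constraints = list(), prior = NULL,
                     knots = NULL, chains = 3, iter = 10000,
                     burn_in = floor(iter / 2), seed = 1, init = NULL) {
  stopifnot(inherits(data, "surv_data"), chains >= 1, iter > burn_in,
            burn_in >= 0)
  if (sum(data$status) == 0)
    warning("dataset has zero events; likelihood is driven by censoring only")
  if (family == "royston_parmar" && is.null(knots))
    knots <- rp_default_knots(data)
  skel <- .par_skeleton(family, knots, !is.null(data$arm))
  if (is.null(prior)) prior <- .default_prior(skel)
  if (length(prior) != skel$n)
    stop("prior list must have one entry per parameter (", skel$n, ")")
  target <- .make_target(data, skel, constraints, prior, use_prior = TRUE)

  set.seed(seed)
  z_center <- init
  if (is.null(z_center)) {
    pml <- tryCatch(suppressWarnings(
      fit_penalized_ml(data, family, constraints, knots = knots,
                       starts = 2, seed = seed)),
      error = function(e) NULL)
    z_center <- if (!is.null(pml)) unname(pml$z_hat) else .init_z(skel, data)
  }

  d <- skel$n
  keep <- iter - burn_in
  draws_z <- matrix(NA_real_, chains * keep, d)
  ll_keep <- pen_keep <- numeric(chains * keep)
  chain_id <- rep(seq_len(chains), each = keep)
  iter_id <- rep(seq_len(keep), chains)
  accept <- numeric(chains)

  for (ch in seq_len(chains)) {
    z <- z_center + stats::rnorm(d, 0, 0.1)
    cur <- target(z)
    tries <- 0
    while (!is.finite(cur$lp) && tries < 50) {
      z <- .init_z(skel, data) + stats::rnorm(d, 0, 0.5)
      cur <- target(z)
      tries <- tries + 1
    }
    if (!is.finite(cur$lp))
      stop("initialization failed: non-finite log-posterior at every attempt")
    prop_chol <- diag(0.1 / sqrt(d), d)
    hist_z <- matrix(NA_real_, iter, d)
    n_acc <- 0
    for (it in seq_len(iter)) {
      z_prop <- z + drop(stats::rnorm(d) %*% prop_chol)
      prop <- target(z_prop)
      if (is.finite(prop$lp) &&
          log(stats::runif(1)) < prop$lp - cur$lp) {
        z <- z_prop; cur <- prop; n_acc <- n_acc + 1
      }
      hist_z[it, ] <- z
      # Haario-style covariance adaptation during burn-in
      if (it <= burn_in && it >= 200 && it %% 100 == 0) {
        S <- stats::cov(hist_z[seq_len(it), , drop = FALSE]) *
          (2.38^2 / d) + diag(1e-9, d)
        pc <- tryCatch(chol(S), error = function(e) NULL)
        if (!is.null(pc)) prop_chol <- pc
      }
      if (it > burn_in) {
        k <- (ch - 1) * keep + (it - burn_in)
        draws_z[k, ] <- z
        ll_keep[k] <- cur$ll
        pen_keep[k] <- cur$pen
      }
    }
    accept[ch] <- n_acc / iter
  }

  rhat <- .split_rhat(draws_z, chains, keep)
  if (any(is.finite(rhat) & rhat > 1.05))
    warning("split-R-hat > 1.05 for parameter(s): ",
            paste(skel$par_names[which(rhat > 1.05)], collapse = ", "),
            "; treat downstream summaries with caution")

  draws_nat <- draws_z
  for (j in seq_len(d))
    if (skel$transform[j] == "log") draws_nat[, j] <- exp(draws_z[, j])
  colnames(draws_z) <- colnames(draws_nat) <- skel$par_names

  structure(list(
    mode = "bayes", family = family, skel = skel,
    draws = draws_nat, draws_z = draws_z,
    chain = chain_id, iter = iter_id,
    loglik = ll_keep, logpen = pen_keep,
    diagnostics = list(chains = chains, iter = iter, burn_in = burn_in,
                       rhat = stats::setNames(rhat, skel$par_names),
                       accept = accept),
    prior = prior, data = data, constraints = constraints, knots = knots,
    settings = list(chains = chains, iter = iter, burn_in = burn_in,
                    seed = seed)),
    class = "fit_result")
}

.split_rhat <- function(draws, chains, keep) {
  half <- floor(keep / 2)
  if (half < 2) return(rep(NA_real_, ncol(draws)))
  vapply(seq_len(ncol(draws)), function(j) {
    splits <- lapply(seq_len(chains), function(ch) {
      x <- draws[((ch - 1) * keep + 1):(ch * keep), j]
      list(x[seq_len(half)], x[(keep - half + 1):keep])
    })
    xs <- unlist(splits, recursive = FALSE)
    m <- length(xs); n <- half
    means <- vapply(xs, mean, numeric(1))
    vars <- vapply(xs, stats::var, numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$mode, "fit of", x$family, "\n")
  if (x$mode == "bayes") {
    cat("retained draws:", nrow(x$draws), "over",
        x$diagnostics$chains, "chain(s)\n")
    cat("posterior means:\n")
    print(colMeans(x$draws))
    cat("split-R-hat:", format(x$diagnostics$rhat, digits = 3), "\n")
  } else {
    cat("estimate:\n"); print(x$estimate)
    cat("log-likelihood:", x$loglik, " log-penalty:", x$logpen, "\n")
  }
  invisible(x)
}

## ---- conjugate oracle -----------------------------------------------------

#' Closed-form exponential/gamma posterior
#'
#' For an exponential likelihood with a gamma prior G(a, b) the
#' posterior is G(a + sum(status), b + sum(time)). A logarithmic pool of
#' gamma priors is itself gamma with weight-averaged shape and rate, so
#' the same update applies — the externally-Bayesian property in closed
#' form.
#'
#' @param prior a gamma [elicited_density], a logarithmic
#'   [pool_opinions] of gamma components, or a numeric `c(shape, rate)`.
#' @param data a [surv_data] (or `NULL` for no data).
#' @return named numeric `c(shape, rate)` of the posterior.
#' @export
conjugate_exponential_posterior <- function(prior, data = NULL) {
  pr <- .as_gamma_params(prior)
  sv <- if (is.null(data)) 0 else sum(data$status)
  st <- if (is.null(data)) 0 else sum(data$time)
  c(shape = pr[1] + sv, rate = pr[2] + st)
}

.as_gamma_params <- function(prior) {
  if (is.numeric(prior) && length(prior) == 2) return(unname(prior))
  if (inherits(prior, "elicited_density")) {
    if (prior$family != "gamma")
      stop("unsupported prior: conjugate update requires gamma prior(s)")
    return(prior$params)
  }
  if (inherits(prior, "pooled_opinion")) {
    if (prior$method != "log")
      stop("only the logarithmic pool of gamma priors is conjugate")
    fams <- vapply(prior$components, `[[`, character(1), "family")
    if (any(fams != "gamma"))
      stop("unsupported prior: conjugate update requires gamma prior(s)")
    a <- sum(prior$weights * vapply(prior$components,
                                    function(ed) ed$params[1], numeric(1)))
    b <- sum(prior$weights * vapply(prior$components,
                                    function(ed) ed$params[2], numeric(1)))
    return(c(a, b))
  }
  stop("unsupported prior type for conjugate update")
}

## ---- posterior survival curves -------------------------------------------

#' Pointwise posterior survival-curve quantiles
#'
#' For a Bayesian fit, evaluates S(t) for every retained draw and
#' returns pointwise quantiles. For a penalized-ML fit, draws from the
#' Gaussian curvature approximation on the transformed scale.
#'
#' @param fit a [fit_result].
#' @param times nonnegative time grid.
#' @param probs quantile levels (default 2.5%, 50%, 97.5%).
#' @param arm optional binary covariate level.
#' @param max_draws cap on the number of draws used (subsampled evenly).
#' @return data.frame with column `time` and one `q<level>` column per
#'   quantile.
#' @export
posterior_survival_curve <- function(fit, times,
                                     probs = c(0.025, 0.5, 0.975),
                                     arm = NULL, max_draws = Inf) {
  stopifnot(inherits(fit, "fit_result"))
  zs <- .fit_draws_z(fit, n = 4000)
  if (nrow(zs) > max_draws)
    zs <- zs[round(seq(1, nrow(zs), length.out = max_draws)), , drop = FALSE]
  S <- matrix(NA_real_, nrow(zs), length(times))
  for (i in seq_len(nrow(zs))) {
    model <- tryCatch(.build_model(fit$skel, zs[i, ]), error = function(e) NULL)
    S[i, ] <- if (is.null(model)) NA_real_ else psurv(model, times, arm = arm)
  }
  qs <- apply(S, 2, stats::quantile, probs = probs, na.rm = TRUE)
  if (length(probs) == 1) qs <- matrix(qs, nrow = 1)
  out <- data.frame(time = times)
  for (k in seq_along(probs))
    out[[paste0("q", format(100 * probs[k], trim = TRUE))]] <- qs[k, ]
  out
}

# draws on the transformed scale, for either fit mode
.fit_draws_z <- function(fit, n = 4000) {
  if (fit$mode == "bayes") return(fit$draws_z)
  if (!all(is.finite(fit$cov_z)))
    return(matrix(fit$z_hat, 1, length(fit$z_hat)))
  L <- tryCatch(chol(fit$cov_z), error = function(e) NULL)
  if (is.null(L)) return(matrix(fit$z_hat, 1, length(fit$z_hat)))
  d <- length(fit$z_hat)
  sweep(matrix(stats::rnorm(n * d), n, d) %*% L, 2, fit$z_hat, `+`)
}
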