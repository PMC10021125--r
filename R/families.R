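#' Parametric survival families
#'
#' Eight parametric time-to-event families on their standard
#' parameterizations, with closed-form density, survival, hazard,
#' summary quantities, and right-censored log-likelihood.
#'
#' Parameterizations:
#' \describe{
#'   \item{exponential}{\code{rate} theta; S(t) = exp(-theta t).}
#'   \item{weibull_aft}{\code{shape} a, \code{scale} b as in
#'     [stats::dweibull]; S(t) = exp(-(t/b)^a).}
#'   \item{gamma}{\code{shape}, \code{rate} as in [stats::dgamma].}
#'   \item{gompertz}{\code{shape} a (any real) and \code{rate} b > 0 with
#'     hazard h(t) = b exp(a t). Negative a gives an improper survival
#'     function with plateau exp(b/a).}
#'   \item{lognormal}{\code{meanlog}, \code{sdlog} as in [stats::dlnorm].}
#'   \item{loglogistic}{\code{shape} a, \code{scale} b;
#'     S(t) = 1 / (1 + (t/b)^a).}
#'   \item{gengamma}{generalized gamma in the (mu, sigma, Q) form;
#'     Q = 0 is log-normal, Q = 1 is Weibull with shape 1/sigma and
#'     scale exp(mu).}
#'   \item{royston_parmar}{restricted cubic spline for log cumulative
#'     hazard against log time; parameters are the spline coefficients
#'     gamma0..gamma_{m+1} for m internal knots, with \code{knots} the
#'     full ordered knot vector (boundary + internal) on log time.
#'     Zero internal knots reduces to a Weibull proportional-hazards
#'     model.}
#' }
#'
#' A single binary covariate is supported through \code{coef}: a
#' proportional-hazards effect for hazard-parameterized families
#' (exponential, Gompertz, Royston-Parmar) and an accelerated-failure-time
#' effect for time-scale families (Weibull, gamma, log-normal,
#' log-logistic, generalized gamma).
#'
#' @name survival-families
NULL

.FAMILIES <- c("exponential", "weibull_aft", "gamma", "gompertz",
               "lognormal", "loglogistic", "gengamma", "royston_parmar")

#' Family metadata: parameter names, transforms and covariate scale
#'
#' @param family family name.
#' @param knots full knot vector (royston_parmar only).
#' @return list with `par_names`, `transform` ("log" or "identity" per
#'   parameter), `npar`, and `coef_scale` ("PH" or "AFT").
#' @keywords internal
family_info <- function(family, knots = NULL) {
  family <- match.arg(family, .FAMILIES)
  info <- switch(family,
    exponential = list(par_names = "rate", transform = "log"),
    weibull_aft = list(par_names = c("shape", "scale"),
                       transform = c("log", "log")),
    gamma = list(par_names = c("shape", "rate"),
                 transform = c("log", "log")),
    gompertz = list(par_names = c("shape", "rate"),
                    transform = c("identity", "log")),
    lognormal = list(par_names = c("meanlog", "sdlog"),
                     transform = c("identity", "log")),
    loglogistic = list(par_names = c("shape", "scale"),
                       transform = c("log", "log")),
    gengamma = list(par_names = c("mu", "sigma", "Q"),
                    transform = c("identity", "log", "identity")),
    royston_parmar = {
      if (is.null(knots)) stop("royston_parmar requires `knots`")
      k <- length(knots)
      if (k < 2) stop("royston_parmar needs at least 2 (boundary) knots")
      list(par_names = paste0("gamma", seq_len(k) - 1L),
           transform = rep("identity", k))
    })
  info$npar <- length(info$par_names)
  info$coef_scale <- if (family %in% c("exponential", "gompertz",
                                       "royston_parmar")) "PH" else "AFT"
  info$family <- family
  info
}

#' Construct a parametric survival model
#'
#' @param family one of `"exponential"`, `"weibull_aft"`, `"gamma"`,
#'   `"gompertz"`, `"lognormal"`, `"loglogistic"`, `"gengamma"`,
#'   `"royston_parmar"`.
#' @param params numeric vector of parameters on the natural scale, in
#'   the order documented in [survival-families].
#' @param knots for `royston_parmar`, strictly increasing knot locations
#'   on log time (boundary knots first and last).
#' @param coef optional scalar effect of a binary covariate; applied on
#'   the family's covariate scale (PH or AFT, see [survival-families]).
#' @return object of class `surv_model`.
#' @export
#' @examples
#' m <- surv_model("exponential", 0.5)
#' psurv(m, 2)          # exp(-1)
#' summary_survival(m, "median")
surv_model <- function(family, params, knots = NULL, coef = NULL) {
  family <- match.arg(family, .FAMILIES)
  info <- family_info(family, knots)
  params <- as.numeric(params)
  if (length(params) != info$npar)
    stop(sprintf("family '%s' needs %d parameter(s), got %d",
                 family, info$npar, length(params)))
  if (any(!is.finite(params)))
    stop("parameters must be finite")
  pos <- info$transform == "log"
  if (any(params[pos] <= 0))
    stop(sprintf("parameter(s) %s must be > 0 for family '%s'",
                 paste(info$par_names[pos][params[pos] <= 0],
                       collapse = ", "), family))
  if (!is.null(knots)) {
    knots <- as.numeric(knots)
    if (is.unsorted(knots, strictly = TRUE))
      stop("knots must be strictly increasing")
  }
  if (!is.null(coef)) {
    coef <- as.numeric(coef)
    stopifnot(length(coef) == 1L, is.finite(coef))
  }
  structure(list(family = family, params = stats::setNames(params, info$par_names),
                 knots = knots, coef = coef, coef_scale = info$coef_scale),
            class = "surv_model")
}

#' @export
print.surv_model <- function(x, ...) {
  cat("<surv_model>", x$family, "\n")
  print(x$params)
  if (!is.null(x$knots)) cat("knots (log time):", format(x$knots), "\n")
  if (!is.null(x$coef))
    cat("covariate effect (", x$coef_scale, "): ", x$coef, "\n", sep = "")
  invisible(x)
}

## ---- Royston-Parmar restricted cubic spline basis -----------------------

rp_basis <- function(x, knots, deriv = FALSE) {
  kmin <- knots[1L]
  kmax <- knots[length(knots)]
  n <- length(x)
  if (deriv) {
    B <- cbind(rep(0, n), rep(1, n))
  } else {
    B <- cbind(rep(1, n), x)
  }
  internal <- knots[-c(1L, length(knots))]
  for (k in internal) {
    lam <- (kmax - k) / (kmax - kmin)
    if (deriv) {
      v <- 3 * pmax(x - k, 0)^2 - 3 * lam * pmax(x - kmin, 0)^2 -
        3 * (1 - lam) * pmax(x - kmax, 0)^2
    } else {
      v <- pmax(x - k, 0)^3 - lam * pmax(x - kmin, 0)^3 -
        (1 - lam) * pmax(x - kmax, 0)^3
    }
    B <- cbind(B, v)
  }
  B
}

rp_log_cumhaz <- function(t, gamma, knots) {
  x <- log(t)
  drop(rp_basis(x, knots) %*% gamma)
}

rp_dlogH_dx <- function(t, gamma, knots) {
  x <- log(t)
  drop(rp_basis(x, knots, deriv = TRUE) %*% gamma)
}

#' Default Royston-Parmar knots from a dataset
#'
#' Boundary knots at the min and max uncensored log event times, internal
#' knots at quantiles of the uncensored log event times (the median for
#' one internal knot).
#'
#' @param data a `surv_data` object (see [surv_data]).
#' @param n_internal number of internal knots (default 1).
#' @return numeric knot vector on log time.
#' @export
rp_default_knots <- function(data, n_internal = 1) {
  ev <- log(data$time[data$status == 1])
  if (length(unique(ev)) < 2)
    stop("need at least 2 distinct uncensored event times to place knots")
  probs <- seq(0, 1, length.out = n_internal + 2)
  kn <- unname(stats::quantile(ev, probs = probs, type = 7))
  if (is.unsorted(kn, strictly = TRUE))
    stop("degenerate knot placement: event times too concentrated")
  kn
}

## ---- baseline (no covariate) functions, vectorized in t -----------------

# log survival, baseline
.base_logsurv <- function(model, t) {
  p <- model$params
  out <- switch(model$family,
    exponential = -p[["rate"]] * t,
    weibull_aft = stats::pweibull(t, p[["shape"]], p[["scale"]],
                                  lower.tail = FALSE, log.p = TRUE),
    gamma = stats::pgamma(t, p[["shape"]], p[["rate"]],
                          lower.tail = FALSE, log.p = TRUE),
    gompertz = {
      a <- p[["shape"]]; b <- p[["rate"]]
      if (abs(a) < 1e-12) -b * t else -b * expm1(a * t) / a
    },
    lognormal = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]],
                              lower.tail = FALSE, log.p = TRUE),
    loglogistic = {
      a <- p[["shape"]]; b <- p[["scale"]]
      -log1p(exp(a * (log(t) - log(b))))
    },
    gengamma = .gengamma_logsurv(t, p[["mu"]], p[["sigma"]], p[["Q"]]),
    royston_parmar = {
      ls <- rep(0, length(t))
      pos <- t > 0
      ls[pos] <- -exp(rp_log_cumhaz(t[pos], p, model$knots))
      ls
    })
  # t = 0 (or t < smallest support) must give S = 1
  out[t == 0] <- 0
  out
}

# log density, baseline; -Inf where density is 0 or undefined
.base_logdens <- function(model, t) {
  p <- model$params
  out <- switch(model$family,
    exponential = stats::dexp(t, p[["rate"]], log = TRUE),
    weibull_aft = stats::dweibull(t, p[["shape"]], p[["scale"]], log = TRUE),
    gamma = stats::dgamma(t, p[["shape"]], p[["rate"]], log = TRUE),
    gompertz = {
      a <- p[["shape"]]; b <- p[["rate"]]
      log(b) + a * t + .base_logsurv(model, t)
    },
    lognormal = stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]], log = TRUE),
    loglogistic = {
      a <- p[["shape"]]; b <- p[["scale"]]
      z <- a * (log(t) - log(b))
      log(a) - log(t) + z - 2 * log1p(exp(z))
    },
    gengamma = .gengamma_logdens(t, p[["mu"]], p[["sigma"]], p[["Q"]]),
    royston_parmar = {
      ld <- rep(-Inf, length(t))
      pos <- t > 0
      if (any(pos)) {
        logH <- rp_log_cumhaz(t[pos], p, model$knots)
        ds <- rp_dlogH_dx(t[pos], p, model$knots)
        lh <- ifelse(ds > 0, logH + log(ds) - log(t[pos]), -Inf)
        ld[pos] <- lh - exp(logH)
      }
      ld
    })
  out[!is.finite(t) | t < 0] <- -Inf
  out[is.nan(out)] <- -Inf
  out
}

# below this |Q| the q2 = Q^-2 terms lose all precision to cancellation;
# the log-normal limit is exact to ~1e-10 there
.GG_Q_EPS <- 1e-5

.gengamma_logdens <- function(t, mu, sigma, Q) {
  if (abs(Q) < .GG_Q_EPS) return(stats::dlnorm(t, mu, sigma, log = TRUE))
  out <- rep(-Inf, length(t))
  pos <- is.finite(t) & t > 0
  w <- (log(t[pos]) - mu) / sigma
  q2 <- Q^-2
  out[pos] <- log(abs(Q)) - log(sigma * t[pos]) + q2 * log(q2) +
    q2 * (Q * w - exp(Q * w)) - lgamma(q2)
  out
}

.gengamma_logsurv <- function(t, mu, sigma, Q) {
  if (abs(Q) < .GG_Q_EPS)
    return(stats::plnorm(t, mu, sigma, lower.tail = FALSE, log.p = TRUE))
  out <- rep(0, length(t))
  pos <- is.finite(t) & t > 0
  w <- (log(t[pos]) - mu) / sigma
  q2 <- Q^-2
  u <- q2 * exp(Q * w)
  out[pos] <- stats::pgamma(u, shape = q2, lower.tail = Q < 0, log.p = TRUE)
  out
}

## ---- covariate adjustment -----------------------------------------------

# effect multiplier: NULL coef or NULL/0 arm -> identity
.cov_eff <- function(model, arm) {
  if (is.null(model$coef) || is.null(arm)) return(NULL)
  exp(model$coef * arm)
}

.logsurv <- function(model, t, arm = NULL) {
  eff <- .cov_eff(model, arm)
  if (is.null(eff)) return(.base_logsurv(model, t))
  if (model$coef_scale == "PH") {
    eff * .base_logsurv(model, t)
  } else {
    .base_logsurv(model, t / eff)
  }
}

.logdens <- function(model, t, arm = NULL) {
  eff <- .cov_eff(model, arm)
  if (is.null(eff)) return(.base_logdens(model, t))
  if (model$coef_scale == "PH") {
    # f = h0 * eff * S0^eff = f0/S0 * eff * S0^eff
    .base_logdens(model, t) - .base_logsurv(model, t) + log(eff) +
      eff * .base_logsurv(model, t)
  } else {
    .base_logdens(model, t / eff) - log(eff)
  }
}

## ---- exported operations ------------------------------------------------

#' Survival function S(t)
#'
#' @param model a [surv_model].
#' @param t nonnegative time(s).
#' @param arm optional binary covariate value(s) (0/1); requires
#'   `model$coef`.
#' @return survival probabilities in `[0, 1]`; `S(0) = 1`.
#' @export
psurv <- function(model, t, arm = NULL) {
  stopifnot(inherits(model, "surv_model"))
  if (any(t < 0)) stop("t must be >= 0")
  exp(.logsurv(model, t, arm))
}

#' Density f(t)
#'
#' @inheritParams psurv
#' @return density values (0 outside the support).
#' @export
dsurv <- function(model, t, arm = NULL) {
  stopifnot(inherits(model, "surv_model"))
  exp(.logdens(model, t, arm))
}

#' Hazard function h(t) = f(t) / S(t)
#'
#' @inheritParams psurv
#' @param t strictly positive time(s).
#' @return nonnegative hazard values.
#' @export
hsurv <- function(model, t, arm = NULL) {
  stopifnot(inherits(model, "surv_model"))
  if (any(t <= 0)) stop("hazard requires t > 0")
  ls <- .logsurv(model, t, arm)
  if (any(ls == -Inf))
    stop("S(t) underflowed to 0; hazard not computable at t = ",
         paste(t[ls == -Inf], collapse = ", "))
  exp(.logdens(model, t, arm) - ls)
}

#' Inverse survival function
#'
#' Time t such that S(t) = p. Used for inverse-CDF simulation. Returns
#' `Inf` when an improper survival function plateaus above `p`.
#'
#' @inheritParams psurv
#' @param p survival probabilities in (0, 1).
#' @export
qsurv <- function(model, p, arm = NULL) {
  stopifnot(inherits(model, "surv_model"))
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  eff <- .cov_eff(model, arm)
  if (!is.null(eff) && model$coef_scale == "PH") {
    # S0(t)^eff = p  =>  S0(t) = p^(1/eff)
    return(.base_qsurv(model, p^(1 / eff)))
  }
  t0 <- .base_qsurv(model, p)
  if (!is.null(eff)) t0 * eff else t0
}

.base_qsurv <- function(model, p) {
  pp <- model$params
  switch(model$family,
    exponential = stats::qexp(p, pp[["rate"]], lower.tail = FALSE),
    weibull_aft = stats::qweibull(p, pp[["shape"]], pp[["scale"]],
                                  lower.tail = FALSE),
    gamma = stats::qgamma(p, pp[["shape"]], pp[["rate"]],
                          lower.tail = FALSE),
    gompertz = {
      a <- pp[["shape"]]; b <- pp[["rate"]]
      if (abs(a) < 1e-12) return(-log(p) / b)
      arg <- 1 + a * (-log(p)) / b
      out <- rep(Inf, length(arg))
      out[arg > 0] <- log(arg[arg > 0]) / a
      out
    },
    lognormal = stats::qlnorm(p, pp[["meanlog"]], pp[["sdlog"]],
                              lower.tail = FALSE),
    loglogistic = pp[["scale"]] * ((1 - p) / p)^(1 / pp[["shape"]]),
    gengamma = {
      mu <- pp[["mu"]]; sigma <- pp[["sigma"]]; Q <- pp[["Q"]]
      if (abs(Q) < .GG_Q_EPS)
        return(stats::qlnorm(p, mu, sigma, lower.tail = FALSE))
      q2 <- Q^-2
      u <- stats::qgamma(p, shape = q2, lower.tail = Q < 0)
      exp(mu + sigma * log(u / q2) / Q)
    },
    royston_parmar = {
      vapply(p, function(pi) {
        target <- log(-log(pi))
        f <- function(x) rp_log_cumhaz(exp(x), model$params, model$knots) - target
        lo <- model$knots[1] - 20; hi <- model$knots[length(model$knots)] + 20
        if (f(lo) > 0 || f(hi) < 0) return(if (f(hi) < 0) Inf else 0)
        exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
      }, numeric(1))
    })
}

#' Right-censored log-likelihood
#'
#' Sum over subjects of `status * log f(t) + (1 - status) * log S(t)`.
#' Returns `-Inf` (not an error) when any event time has zero density.
#'
#' @param data a [surv_data].
#' @param model a [surv_model]; if `data` has an `arm` column the model
#'   must carry a `coef`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(data, model) {
  stopifnot(inherits(data, "surv_data"), inherits(model, "surv_model"))
  arm <- data$arm
  if (!is.null(arm) && is.null(model$coef))
    arm <- NULL  # covariate present but model unadjusted: pooled fit
  ld <- .logdens(model, data$time, arm)
  ls <- .logsurv(model, data$time, arm)
  ll <- sum(ifelse(data$status == 1, ld, ls))
  if (is.nan(ll)) -Inf else ll
}

#' Median or (restricted) mean survival
#'
#' The median solves S(t) = 0.5, in closed form where available and by
#' bracketed root-finding otherwise. The mean is computed in closed form
#' where available, else by adaptive quadrature of S(t) on
#' `[0, horizon]`; improper survival functions (e.g. Gompertz with
#' negative shape) require a finite `horizon`.
#'
#' @param model a [surv_model].
#' @param quantity `"median"` or `"mean"`.
#' @param horizon optional finite upper limit for the mean integral.
#' @param arm optional binary covariate value.
#' @return positive scalar.
#' @export
summary_survival <- function(model, quantity = c("median", "mean"),
                             horizon = NULL, arm = NULL) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(model, "surv_model"))
  p <- model$params
  if (quantity == "median") {
    plateau <- .surv_plateau(model, arm)
    if (plateau > 0.5)
      stop("median undefined: survival plateaus at ",
           format(plateau, digits = 4), " > 0.5")
    return(qsurv(model, 0.5, arm))
  }
  ## mean
  if (is.null(arm) || is.null(model$coef)) {
    cl <- switch(model$family,
      exponential = 1 / p[["rate"]],
      weibull_aft = p[["scale"]] * gamma(1 + 1 / p[["shape"]]),
      gamma = p[["shape"]] / p[["rate"]],
      lognormal = exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2),
      loglogistic = if (p[["shape"]] > 1) {
        b <- pi / p[["shape"]]
        p[["scale"]] * b / sin(b)
      } else NULL,
      NULL)
    if (!is.null(cl) && is.null(horizon)) return(unname(cl))
  }
  if (is.null(horizon)) {
    if (.surv_plateau(model, arm) > 1e-8)
      stop("improper survival function: supply a finite `horizon` for the mean")
    horizon <- Inf
  }
  val <- stats::integrate(function(tt) psurv(model, tt, arm), 0, horizon,
                          rel.tol = 1e-8, subdivisions = 500L)
  val$value
}

# limiting survival probability (0 for proper families)
.surv_plateau <- function(model, arm = NULL) {
  p <- model$params
  base <- switch(model$family,
    gompertz = if (p[["shape"]] < 0) exp(p[["rate"]] / p[["shape"]]) else 0,
    loglogistic = 0,
    royston_parmar = psurv_noarm_limit_rp(model),
    0)
  eff <- .cov_eff(model, arm)
  if (is.null(eff)) return(base)
  if (model$coef_scale == "PH") base^eff else base
}

psurv_noarm_limit_rp <- function(model) {
  # spline is linear beyond the boundary knots: improper iff slope <= 0
  hi <- exp(model$knots[length(model$knots)] + 30)
  s <- rp_dlogH_dx(hi, model$params, model$knots)
  if (s <= 0) exp(-exp(rp_log_cumhaz(hi, model$params, model$knots))) else 0
}
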