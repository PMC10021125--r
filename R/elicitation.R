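#' Raw expert judgement
#'
#' An expert's elicited interval for a survival quantity at a landmark
#' time: lower plausible limit (LPL), most likely value (MLV) and upper
#' plausible limit (UPL), together with the coverage the expert attaches
#' to the (LPL, UPL) interval (by default 99%: the expert is 99% sure
#' the true value lies inside).
#'
#' @param timepoint positive landmark time (study time units).
#' @param lpl,mlv,upl lower plausible limit, most likely value, upper
#'   plausible limit; must satisfy `lpl < mlv < upl`. For
#'   `quantity = "survival_prob"` all three must lie in (0, 1).
#' @param coverage central coverage of (lpl, upl), in (0.5, 1);
#'   default 0.99.
#' @param quantity what was elicited: `"survival_prob"`, `"median"` or
#'   `"mean"`.
#' @return object of class `expert_judgement`.
#' @export
expert_judgement <- function(timepoint, lpl, mlv, upl, coverage = 0.99,
                             quantity = c("survival_prob", "median", "mean")) {
  quantity <- match.arg(quantity)
  stopifnot(timepoint > 0, coverage > 0.5, coverage < 1)
  if (!(lpl < mlv && mlv < upl))
    stop("need lpl < mlv < upl, got (", lpl, ", ", mlv, ", ", upl, ")")
  if (quantity == "survival_prob" && (lpl <= 0 || upl >= 1))
    stop("survival probabilities must lie in (0, 1)")
  if (quantity != "survival_prob" && lpl <= 0)
    stop("elicited times must be positive")
  structure(list(timepoint = timepoint, lpl = lpl, mlv = mlv, upl = upl,
                 coverage = coverage, quantity = quantity),
            class = "expert_judgement")
}

.ELICIT_FAMILIES <- c("normal", "t3", "lognormal", "gamma", "beta")

#' A fitted probability distribution over an elicited quantity
#'
#' @param family `"normal"` (mean, sd), `"t3"` (location, scale; Student
#'   t with 3 degrees of freedom), `"lognormal"` (meanlog, sdlog),
#'   `"gamma"` (shape, rate) or `"beta"` (shape1, shape2). The beta
#'   family is only valid for survival probabilities.
#' @param params numeric parameter vector (length 2).
#' @param timepoint landmark time the opinion refers to.
#' @param quantity `"survival_prob"`, `"median"` or `"mean"`.
#' @param weight nonnegative pooling weight (relative; defaults to 1).
#' @return object of class `elicited_density`.
#' @export
elicited_density <- function(family, params, timepoint = 1,
                             quantity = c("survival_prob", "median", "mean"),
                             weight = 1) {
  family <- match.arg(family, .ELICIT_FAMILIES)
  quantity <- match.arg(quantity)
  params <- as.numeric(params)
  stopifnot(length(params) == 2L, all(is.finite(params)), weight >= 0)
  if (family %in% c("normal", "t3") && params[2] <= 0)
    stop("scale parameter must be > 0")
  if (family == "lognormal" && params[2] <= 0)
    stop("sdlog must be > 0")
  if (family %in% c("gamma", "beta") && any(params <= 0))
    stop("gamma/beta parameters must be > 0")
  if (family == "beta" && quantity != "survival_prob")
    stop("beta family is only supported for survival probabilities")
  structure(list(family = family, params = params, timepoint = timepoint,
                 quantity = quantity, weight = weight),
            class = "elicited_density")
}

#' @export
print.elicited_density <- function(x, ...) {
  cat("<elicited_density>", x$family, "(", paste(format(x$params, digits = 4),
      collapse = ", "), ") at t* =", x$timepoint, "for", x$quantity, "\n")
  invisible(x)
}

# density / cdf / quantile / analytic mode for the candidate families
.elic_dens <- function(ed, x, log = FALSE) {
  p <- ed$params
  switch(ed$family,
    normal = stats::dnorm(x, p[1], p[2], log = log),
    t3 = {
      ld <- stats::dt((x - p[1]) / p[2], df = 3, log = TRUE) - log(p[2])
      if (log) ld else exp(ld)
    },
    lognormal = stats::dlnorm(x, p[1], p[2], log = log),
    gamma = stats::dgamma(x, p[1], p[2], log = log),
    beta = stats::dbeta(x, p[1], p[2], log = log))
}

.elic_cdf <- function(ed, x) {
  p <- ed$params
  switch(ed$family,
    normal = stats::pnorm(x, p[1], p[2]),
    t3 = stats::pt((x - p[1]) / p[2], df = 3),
    lognormal = stats::plnorm(x, p[1], p[2]),
    gamma = stats::pgamma(x, p[1], p[2]),
    beta = stats::pbeta(x, p[1], p[2]))
}

.elic_quantile <- function(ed, q) {
  p <- ed$params
  switch(ed$family,
    normal = stats::qnorm(q, p[1], p[2]),
    t3 = p[1] + p[2] * stats::qt(q, df = 3),
    lognormal = stats::qlnorm(q, p[1], p[2]),
    gamma = stats::qgamma(q, p[1], p[2]),
    beta = stats::qbeta(q, p[1], p[2]))
}

.elic_mode <- function(ed) {
  p <- ed$params
  switch(ed$family,
    normal = p[1],
    t3 = p[1],
    lognormal = exp(p[1] - p[2]^2),
    gamma = if (p[1] > 1) (p[1] - 1) / p[2] else 0,
    beta = {
      if (p[1] > 1 && p[2] > 1) (p[1] - 1) / (p[1] + p[2] - 2)
      else if (p[1] <= 1 && p[2] > 1) 0
      else if (p[1] > 1 && p[2] <= 1) 1
      else 0.5
    })
}

.elic_sd <- function(ed) {
  p <- ed$params
  switch(ed$family,
    normal = p[2],
    t3 = p[2] * sqrt(3),                 # var of t3 is 3 scale^2
    lognormal = sqrt((exp(p[2]^2) - 1) * exp(2 * p[1] + p[2]^2)),
    gamma = sqrt(p[1]) / p[2],
    beta = sqrt(p[1] * p[2] / ((p[1] + p[2])^2 * (p[1] + p[2] + 1))))
}

#' Fit a probability distribution to an expert judgement
#'
#' Least-squares fit in the spirit of the SHELF quantile-matching
#' routines, modified so that the most likely value (MLV) is treated as
#' the mode of the fitted distribution. For each candidate family the
#' objective is
#' \deqn{(q(\alpha) - LPL)^2 + (q(1 - \alpha) - UPL)^2 +
#'       (mode - MLV)^2,}
#' with \eqn{\alpha = (1 - coverage)/2} (a central-interval reading of
#' "coverage% sure"), all three terms equally weighted on the value
#' scale of the elicited quantity so they are commensurable. (Measuring
#' the limit errors in probability space instead is degenerate here:
#' with extreme limits every family can nail the mode and one limit and
#' lose only \eqn{\alpha^2} on the other by collapsing its scale.) The
#' family with the smallest minimized objective wins.
#'
#' @param judgement an [expert_judgement].
#' @param candidate_families subset of `c("normal", "t3", "lognormal",
#'   "gamma", "beta")`; beta is silently dropped unless the quantity is
#'   a survival probability.
#' @return the best-fitting [elicited_density], with attributes
#'   `objective` (achieved value) and `diagnostics` (per-family
#'   objectives).
#' @export
#' @examples
#' j <- expert_judgement(4, lpl = 0.2, mlv = 0.4, upl = 0.6)
#' fit_elicited_distribution(j, "normal")
fit_elicited_distribution <- function(judgement,
                                      candidate_families = .ELICIT_FAMILIES) {
  stopifnot(inherits(judgement, "expert_judgement"))
  candidate_families <- match.arg(candidate_families, .ELICIT_FAMILIES,
                                  several.ok = TRUE)
  if (judgement$quantity != "survival_prob")
    candidate_families <- setdiff(candidate_families, "beta")
  if (!length(candidate_families)) stop("no admissible candidate family")
  alpha <- (1 - judgement$coverage) / 2
  lpl <- judgement$lpl; mlv <- judgement$mlv; upl <- judgement$upl

  obj_for <- function(family) {
    mk <- function(th) {
      par <- switch(family,
        normal = c(th[1], exp(th[2])),
        t3 = c(th[1], exp(th[2])),
        lognormal = c(th[1], exp(th[2])),
        gamma = exp(th),
        beta = exp(th))
      elicited_density(family, par, timepoint = judgement$timepoint,
                       quantity = judgement$quantity)
    }
    f <- function(th) {
      ed <- tryCatch(mk(th), error = function(e) NULL)
      if (is.null(ed)) return(1e10)
      v <- (.elic_quantile(ed, alpha) - lpl)^2 +
        (.elic_quantile(ed, 1 - alpha) - upl)^2 +
        (.elic_mode(ed) - mlv)^2
      if (!is.finite(v)) 1e10 else v
    }
    # moment-flavored starts from a normal reading of the interval
    s0 <- (upl - lpl) / (2 * stats::qnorm(1 - alpha))
    th0 <- switch(family,
      normal = c(mlv, log(s0)),
      t3 = c(mlv, log(s0 / sqrt(3))),
      lognormal = c(log(mlv) + (s0 / mlv)^2, log(max(s0 / mlv, 1e-3))),
      gamma = log(c((mlv / s0)^2 + 2, ((mlv / s0)^2 + 1) / max(mlv, 1e-8))),
      beta = {
        m <- min(max(mlv, 1e-3), 1 - 1e-3)
        v <- min(s0^2, m * (1 - m) * 0.45)
        k <- m * (1 - m) / v - 1
        log(pmax(c(m * k, (1 - m) * k), 1e-3))
      })
    best <- NULL
    for (start in list(th0, th0 + c(0, 0.5), th0 - c(0, 0.5))) {
      op <- tryCatch(
        stats::optim(start, f, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    if (is.null(best)) return(NULL)
    list(ed = mk(best$par), value = best$value)
  }

  fits <- lapply(candidate_families, obj_for)
  names(fits) <- candidate_families
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("distribution fitting failed for every candidate family: ",
         paste(candidate_families, collapse = ", "))
  vals <- vapply(fits[ok], `[[`, numeric(1), "value")
  best <- fits[ok][[which.min(vals)]]
  out <- best$ed
  attr(out, "objective") <- best$value
  attr(out, "diagnostics") <- vals
  out
}

#' Kaplan-Meier estimate with Greenwood confidence interval
#'
#' Product-limit survival estimate at time `t` with a log-transformed
#' Greenwood-variance confidence interval (the [survival::survfit]
#' default).
#'
#' @param data a [surv_data].
#' @param t positive time within follow-up.
#' @param level confidence level (default 0.95).
#' @return named vector `(lower, estimate, upper)`.
#' @export
km_interval <- function(data, t, level = 0.95) {
  stopifnot(inherits(data, "surv_data"), t > 0)
  if (t > max(data$time))
    stop("t = ", t, " is beyond the last observed time ", max(data$time))
  fit <- survival::survfit(
    survival::Surv(data$time, data$status) ~ 1,
    conf.type = "log", conf.int = level)
  s <- summary(fit, times = t, extend = TRUE)
  c(lower = unname(s$lower), estimate = unname(s$surv),
    upper = unname(s$upper))
}
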