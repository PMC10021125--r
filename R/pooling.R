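#' Pool multiple expert opinions
#'
#' Combines elicited densities over the same quantity and landmark time
#' by linear pooling (the weighted arithmetic mean of the densities — a
#' mixture) or logarithmic pooling (the weighted geometric mean,
#' renormalized numerically). Logarithmic pooling is externally
#' Bayesian — pooling then updating equals updating then pooling — but
#' does not satisfy the marginalization property; linear pooling is the
#' reverse.
#'
#' @param components list of [elicited_density] objects sharing a
#'   quantity (and, ordinarily, a timepoint).
#' @param weights nonnegative pooling weights; normalized to sum to 1.
#'   Default: the components' own `weight` fields (equal weights 1/m if
#'   unset).
#' @param method `"linear"` or `"log"`.
#' @return object of class `pooled_opinion` with fields `components`,
#'   `weights`, `method`, `support` (numeric quadrature bracket) and,
#'   for the logarithmic pool, `normalizer` (the geometric-mean
#'   density's integral, cached).
#' @export
#' @examples
#' g1 <- elicited_density("gamma", c(8, 10), quantity = "median")
#' g2 <- elicited_density("gamma", c(20, 10), quantity = "median")
#' lp <- pool_opinions(list(g1, g2), method = "log")
#' pooled_quantile(lp, c(0.025, 0.975))   # (0.77, 2.22)
pool_opinions <- function(components, weights = NULL,
                          method = c("linear", "log")) {
  method <- match.arg(method)
  stopifnot(is.list(components), length(components) >= 1)
  for (ed in components) stopifnot(inherits(ed, "elicited_density"))
  qty <- unique(vapply(components, `[[`, character(1), "quantity"))
  if (length(qty) != 1)
    stop("all components must concern the same quantity")
  if (is.null(weights))
    weights <- vapply(components, `[[`, numeric(1), "weight")
  stopifnot(length(weights) == length(components), all(weights >= 0),
            sum(weights) > 0)
  weights <- weights / sum(weights)

  support <- .pool_support(components, qty)
  normalizer <- NULL
  if (method == "log") {
    raw <- function(x) .log_pool_raw(components, weights, x)
    z <- stats::integrate(raw, support[1], support[2],
                          rel.tol = 1e-10, subdivisions = 1000L)
    if (!is.finite(z$value) || z$value <= 1e-300)
      stop("degenerate logarithmic pool: component supports do not overlap")
    normalizer <- z$value
  }
  structure(list(components = components, weights = weights, method = method,
                 quantity = qty,
                 timepoint = components[[1]]$timepoint,
                 support = support, normalizer = normalizer),
            class = "pooled_opinion")
}

# quadrature bracket: union of component 1e-9 tail bounds, clipped to the
# quantity's support ([0,1] for probabilities, [0,Inf) for times); the
# truncated mass (< 2e-9) is far below the 1e-8 accuracy the pooled
# density is held to
.pool_support <- function(components, quantity) {
  lo <- min(vapply(components, .elic_quantile, numeric(1), q = 1e-9))
  hi <- max(vapply(components, .elic_quantile, numeric(1), q = 1 - 1e-9))
  if (quantity == "survival_prob") {
    lo <- max(lo, 1e-9); hi <- min(hi, 1 - 1e-9)
  } else {
    lo <- max(lo, 0)
  }
  if (!(hi > lo)) stop("degenerate pool support")
  c(lo, hi)
}

.log_pool_raw <- function(components, weights, x) {
  lg <- rep(0, length(x))
  for (j in seq_along(components)) {
    if (weights[j] == 0) next
    lg <- lg + weights[j] * .elic_dens(components[[j]], x, log = TRUE)
  }
  exp(lg)
}

#' Pooled density
#'
#' @param pool a [pool_opinions] result.
#' @param x evaluation points.
#' @param log return the log density.
#' @return density of the pooled opinion at `x`.
#' @export
dpool <- function(pool, x, log = FALSE) {
  stopifnot(inherits(pool, "pooled_opinion"))
  d <- if (pool$method == "linear") {
    out <- rep(0, length(x))
    for (j in seq_along(pool$components))
      out <- out + pool$weights[j] * .elic_dens(pool$components[[j]], x)
    out
  } else {
    .log_pool_raw(pool$components, pool$weights, x) / pool$normalizer
  }
  if (log) base::log(d) else d
}

#' Pooled cumulative distribution function
#'
#' Linear pools use the exact mixture CDF; logarithmic pools integrate
#' the normalized pooled density from the lower support bound.
#'
#' @inheritParams dpool
#' @export
ppool <- function(pool, x) {
  stopifnot(inherits(pool, "pooled_opinion"))
  if (pool$method == "linear") {
    out <- rep(0, length(x))
    for (j in seq_along(pool$components))
      out <- out + pool$weights[j] * .elic_cdf(pool$components[[j]], x)
    return(out)
  }
  vapply(x, function(xi) {
    if (xi <= pool$support[1]) return(0)
    hi <- min(xi, pool$support[2])
    v <- stats::integrate(function(z) dpool(pool, z),
                          pool$support[1], hi,
                          rel.tol = 1e-10, subdivisions = 1000L)$value
    min(v, 1)
  }, numeric(1))
}

#' Pooled quantile
#'
#' Solves `CDF(x) = p` by bracketed root-finding on the pool's support.
#'
#' @param pool a [pool_opinions] result.
#' @param p probabilities in (0, 1).
#' @return quantiles of the pooled opinion.
#' @export
pooled_quantile <- function(pool, p) {
  stopifnot(inherits(pool, "pooled_opinion"))
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  lo <- pool$support[1]; hi <- pool$support[2]
  if (pool$method == "linear") {
    # mixture tails extend beyond the quadrature bracket; widen if needed
    while (ppool(pool, lo) > min(p) && lo > -1e12)
      lo <- lo - (hi - lo)
    while (ppool(pool, hi) < max(p) && hi < 1e12)
      hi <- hi + (hi - lo)
  }
  vapply(p, function(pi) {
    stats::uniroot(function(x) ppool(pool, x) - pi, c(lo, hi),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' @export
print.pooled_opinion <- function(x, ...) {
  cat("<pooled_opinion>", x$method, "pool of", length(x$components),
      "component(s) on", x$quantity, "\n")
  cat("weights:", format(x$weights, digits = 3), "\n")
  invisible(x)
}
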