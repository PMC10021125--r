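#' Expert-opinion constraint
#'
#' Wraps a pooled opinion as a constraint on a survival model: the
#' model-implied quantity (survival probability at the landmark time,
#' or median/mean survival) is scored against the pooled density. The
#' log of that density is the "loss" added to the log-likelihood — a
#' penalized likelihood in the frequentist reading, a
#' loss-function-based posterior update in the Bayesian one.
#'
#' @param pooled a [pool_opinions] result (a single expert is a pool of
#'   one component).
#' @param timepoint landmark time; defaults to the pool's timepoint.
#'   Ignored for median/mean opinions.
#' @param quantity defaults to the pool's quantity.
#' @param arm optional binary covariate level the opinion applies to.
#' @return object of class `opinion_constraint`.
#' @export
opinion_constraint <- function(pooled, timepoint = NULL, quantity = NULL,
                               arm = NULL) {
  stopifnot(inherits(pooled, "pooled_opinion"))
  if (is.null(timepoint)) timepoint <- pooled$timepoint
  if (is.null(quantity)) quantity <- pooled$quantity
  quantity <- match.arg(quantity, c("survival_prob", "median", "mean"))
  if (quantity == "survival_prob") stopifnot(timepoint > 0)
  if (!is.null(arm)) stopifnot(arm %in% c(0, 1))
  structure(list(pooled = pooled, timepoint = timepoint,
                 quantity = quantity, arm = arm),
            class = "opinion_constraint")
}

#' Convenience: constraint from a single expert density
#'
#' @param density an [elicited_density].
#' @inheritParams opinion_constraint
#' @export
single_expert_constraint <- function(density, timepoint = NULL, arm = NULL) {
  opinion_constraint(pool_opinions(list(density), method = "linear"),
                     timepoint = timepoint, arm = arm)
}

# model-implied value of the constrained quantity
.implied_quantity <- function(model, constraint) {
  switch(constraint$quantity,
    survival_prob = psurv(model, constraint$timepoint, arm = constraint$arm),
    median = summary_survival(model, "median", arm = constraint$arm),
    mean = summary_survival(model, "mean", arm = constraint$arm))
}

#' Log penalty of one opinion constraint
#'
#' The log pooled density evaluated at the model-implied quantity.
#' For a single normal expert about S(t*) this is
#' `-0.5 * ((S(t*) - mu) / sigma)^2 - log(sigma * sqrt(2*pi))`.
#' Returns `-Inf` (not an error) where the pooled density is zero, so
#' samplers and optimizers reject the parameter value.
#'
#' @param model a [surv_model].
#' @param constraint an [opinion_constraint].
#' @return scalar log penalty.
#' @export
constraint_log_penalty <- function(model, constraint) {
  stopifnot(inherits(model, "surv_model"),
            inherits(constraint, "opinion_constraint"))
  q <- tryCatch(.implied_quantity(model, constraint),
                error = function(e) NA_real_)
  if (!is.finite(q)) return(-Inf)
  lp <- dpool(constraint$pooled, q, log = TRUE)
  if (is.nan(lp)) -Inf else lp
}

#' Total log penalty over a list of constraints
#'
#' Sum of per-constraint log penalties; an empty list contributes 0, so
#' the no-opinion analysis recovers the plain likelihood.
#'
#' @param model a [surv_model].
#' @param constraints list of [opinion_constraint] (possibly empty).
#' @return scalar; `-Inf` propagates.
#' @export
total_log_penalty <- function(model, constraints = list()) {
  if (length(constraints) == 0) return(0)
  sum(vapply(constraints, function(con) constraint_log_penalty(model, con),
             numeric(1)))
}
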