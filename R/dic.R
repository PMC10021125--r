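#' Deviance information criterion for a Bayesian fit
#'
#' The deviance is `D(theta) = -2 * (log-likelihood + expert
#' log-penalty)`, so DIC assesses goodness of fit to both the observed
#' data and the expert opinion. `DIC = Dbar + p_D` with
#' `p_D = Dbar - D(theta_bar)`, where `theta_bar` is the posterior mean
#' taken on the transformed (unconstrained) scale and back-transformed —
#' natural-scale means of constrained parameters can be invalid. Set
#' `include_penalty = FALSE` for a data-only deviance (sensitivity
#' check).
#'
#' @param fit a Bayesian [fit_result] (from [fit_mcmc]).
#' @param include_penalty include the expert log-penalty in the deviance
#'   (default `TRUE`).
#' @return object of class `model_score`: a list with `family`, `dic`,
#'   `p_d`, `mean_deviance` and `deviance_at_mean`.
#' @export
dic <- function(fit, include_penalty = TRUE) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$mode != "bayes")
    stop("DIC requires a Bayesian fit with posterior draws; ",
         "for penalized ML consider an AIC-style criterion instead")
  per_draw <- fit$loglik + if (include_penalty) fit$logpen else 0
  dbar <- mean(-2 * per_draw)
  z_bar <- colMeans(fit$draws_z)
  model_bar <- .build_model(fit$skel, z_bar)
  ll_bar <- log_likelihood(fit$data, model_bar)
  pen_bar <- if (include_penalty) total_log_penalty(model_bar, fit$constraints) else 0
  d_at_mean <- -2 * (ll_bar + pen_bar)
  p_d <- dbar - d_at_mean
  structure(list(family = fit$family, dic = dbar + p_d, p_d = p_d,
                 mean_deviance = dbar, deviance_at_mean = d_at_mean,
                 include_penalty = include_penalty),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("<model_score> %s: DIC = %.2f (Dbar = %.2f, p_D = %.2f)\n",
              x$family, x$dic, x$mean_deviance, x$p_d))
  invisible(x)
}

#' Rank fitted models by DIC
#'
#' @param scores list of `model_score` objects (from [dic]).
#' @return data.frame with columns `family`, `dic`, `p_d`,
#'   `mean_deviance`, sorted by ascending DIC (lower is better), ties
#'   broken alphabetically by family for determinism.
#' @export
rank_models <- function(scores) {
  stopifnot(length(scores) >= 1)
  df <- do.call(rbind, lapply(scores, function(s) {
    stopifnot(inherits(s, "model_score"))
    data.frame(family = s$family, dic = s$dic, p_d = s$p_d,
               mean_deviance = s$mean_deviance)
  }))
  df <- df[order(df$dic, df$family), , drop = FALSE]
  rownames(df) <- NULL
  df
}
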