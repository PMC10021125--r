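# shared fixtures, built in code

# the two-gamma pooling example: experts G(8,10) and G(20,10) about an
# exponential rate, updated with data whose sufficient statistics are
# sum(status) = 10, sum(time) = 7
fig1_components <- function() {
  list(elicited_density("gamma", c(8, 10), quantity = "median"),
       elicited_density("gamma", c(20, 10), quantity = "median"))
}

# dataset with sum(status) = 10, sum(time) = 7
conjugate_data <- function() surv_data(rep(0.7, 10), rep(1, 10))

# a representative valid model per family, for property sweeps
family_examples <- function() {
  list(
    exponential = surv_model("exponential", 0.4),
    weibull_aft = surv_model("weibull_aft", c(1.3, 3)),
    gamma = surv_model("gamma", c(1.5, 0.5)),
    gompertz = surv_model("gompertz", c(0.1, 0.3)),
    lognormal = surv_model("lognormal", c(0.5, 0.8)),
    loglogistic = surv_model("loglogistic", c(1.6, 2.5)),
    gengamma = surv_model("gengamma", c(0.5, 0.8, 0.6)),
    royston_parmar = surv_model("royston_parmar", c(-1, 1.2, 0.05),
                                knots = c(log(0.3), log(2), log(10))))
}

# maximum |ECDF - F| over the sample, without ks.test's ties warning
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# effective sample size from the initial positive sequence of
# autocorrelations (Geyer-style truncation)
ess <- function(x) {
  n <- length(x)
  ac <- stats::acf(x, lag.max = min(1000, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.01)
  k <- if (length(pos)) pos[1] - 1 else length(ac)
  n / (1 + 2 * sum(ac[seq_len(k)]))
}
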