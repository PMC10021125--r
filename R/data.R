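#' Right-censored survival dataset
#'
#' A validated container for right-censored time-to-event data: observed
#' times (event or censoring, whichever came first), an event indicator
#' (1 = event observed, 0 = right-censored) and an optional binary
#' treatment-arm covariate.
#'
#' @param time positive observed times.
#' @param status event indicators, each 0 or 1.
#' @param arm optional binary covariate (0/1), same length.
#' @return object of class `surv_data` (a list with elements `time`,
#'   `status`, and optionally `arm`).
#' @export
#' @examples
#' d <- surv_data(c(1, 2, 3), c(1, 1, 0))
#' log_likelihood(d, surv_model("exponential", 0.5))
surv_data <- function(time, status, arm = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (length(time) == 0) stop("dataset must be nonempty")
  if (length(time) != length(status))
    stop("time and status must have equal length")
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad))
    stop("all times must be positive and finite; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!status %in% c(0, 1))
  if (length(bad))
    stop("status must be 0 or 1; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  out <- list(time = time, status = status)
  if (!is.null(arm)) {
    arm <- as.numeric(arm)
    if (length(arm) != length(time))
      stop("arm must have the same length as time")
    bad <- which(!arm %in% c(0, 1))
    if (length(bad))
      stop("arm must be 0 or 1; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    out$arm <- arm
  }
  structure(out, class = "surv_data")
}

#' @export
print.surv_data <- function(x, ...) {
  cat("<surv_data> n =", length(x$time),
      "| events =", sum(x$status),
      "| censored =", sum(1 - x$status), "\n")
  if (!is.null(x$arm)) cat("arms: 0 =", sum(x$arm == 0), ", 1 =", sum(x$arm == 1), "\n")
  invisible(x)
}

#' @export
length.surv_data <- function(x) length(x$time)

#' @export
as.data.frame.surv_data <- function(x, ...) {
  d <- data.frame(time = x$time, status = x$status)
  if (!is.null(x$arm)) d$arm <- x$arm
  d
}

#' Load a survival dataset from CSV
#'
#' Expects a header with columns `time` (positive float), `status`
#' (0/1) and optionally `arm` (0/1); no missing values.
#'
#' @param path path to a CSV file.
#' @return a [surv_data].
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in intersect(c("time", "status", "arm"), names(df))) {
    nas <- which(is.na(df[[col]]))
    if (length(nas))
      stop("missing values in column '", col, "' at row(s): ",
           paste(utils::head(nas, 5), collapse = ", "))
  }
  surv_data(df$time, df$status, arm = if ("arm" %in% names(df)) df$arm)
}

#' Write a survival dataset to CSV
#'
#' @param data a [surv_data].
#' @param path output path.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "surv_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
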