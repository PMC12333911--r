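#' (Weighted) Aalen-Johansen estimator of cumulative incidence
#'
#' Nonparametric estimation of the cause-specific cumulative incidence
#' functions in the presence of competing risks. At each distinct event time
#' \eqn{t_j} the overall event-free survival is the product-limit
#' \eqn{\hat S(t_j) = \prod_{l \le j} (1 - d(t_l)/n(t_l))} over the
#' all-cause event count, the discrete cause-specific hazard is
#' \eqn{\hat\lambda_k(t_j) = d_k(t_j)/n(t_j)}, and the cumulative incidence
#' is \eqn{\hat I_k(t_j) = \sum_{l \le j} \hat S(t_l-)\hat\lambda_k(t_l)}.
#' With per-subject weights, the counts \eqn{d_k}, \eqn{d} and \eqn{n} are
#' weight sums, which gives the inverse-probability-weighted estimator when
#' the weights are IP weights; with unit weights the classical estimator is
#' recovered. The identity \eqn{\hat S + \sum_k \hat I_k = 1} holds exactly
#' at every event time.
#'
#' @param time numeric vector of observation times, or a [cr_data()] object
#'   (in which case `status` is taken from it and the sample is pooled over
#'   arms).
#' @param status integer vector in `0:K` (0 = censored).
#' @param weights optional non-negative per-subject weights (default 1).
#' @param K number of event types; inferred as `max(status, 1)` if `NULL`.
#'
#' @return An object of class `"aalen_johansen"`: a list with `times` (the
#'   distinct event times), `n_risk`, `d` (J x K event counts), `hazard`,
#'   `surv`, `surv_left` (the left-continuous \eqn{\hat S(t_j-)}), `cif`
#'   (J x K), `n`, `K`. Evaluate with [cif_at()] / [surv_at()].
#' @seealso [pseudo_values()], [adjcif()]
#' @examples
#' fit <- aalen_johansen(c(1, 2, 3, 4), c(1, 0, 2, 1))
#' cif_at(fit, c(1, 3, 4))
#' @export
aalen_johansen <- function(time, status = NULL, weights = NULL, K = NULL) {
  if (inherits(time, "cr_data")) {
    data <- time
    status <- data$status
    if (is.null(K)) K <- attr(data, "K")
    time <- data$time
  }
  n <- length(time)
  status <- as.integer(status)
  if (is.null(K)) K <- max(status, 1L)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights must have one entry per subject")
  if (any(weights < 0)) stop("negative weights are not allowed")
  if (all(weights == 0)) stop("weights must not all be zero")

  ut <- sort(unique(time[status > 0L]))
  J <- length(ut)
  if (J == 0L) {
    fit <- list(times = numeric(0), n_risk = numeric(0),
                d = matrix(0, 0, K), hazard = matrix(0, 0, K),
                surv = numeric(0), surv_left = numeric(0),
                cif = matrix(0, 0, K), n = n, K = K,
                total_weight = sum(weights))
    class(fit) <- "aalen_johansen"
    return(fit)
  }

  ord <- order(time)
  st <- time[ord]
  cw <- c(0, cumsum(weights[ord]))
  # weight of subjects with time < t_j, via strict findInterval
  n_lt <- cw[findInterval(ut, st, left.open = TRUE) + 1L]
  n_risk <- sum(weights) - n_lt

  d <- matrix(0, J, K)
  for (k in seq_len(K)) {
    sel <- status == k
    if (any(sel)) {
      agg <- rowsum(weights[sel], group = match(time[sel], ut))
      d[as.integer(rownames(agg)), k] <- agg[, 1]
    }
  }
  dall <- rowSums(d)
  haz_all <- dall / n_risk
  surv <- cumprod(1 - haz_all)
  surv_left <- c(1, surv[-J])
  hazard <- d / n_risk
  cif <- apply(surv_left * hazard, 2, cumsum)
  cif <- matrix(cif, J, K)

  fit <- list(times = ut, n_risk = n_risk, d = d, hazard = hazard,
              surv = surv, surv_left = surv_left, cif = cif, n = n, K = K,
              total_weight = sum(weights))
  class(fit) <- "aalen_johansen"
  fit
}

#' Evaluate Aalen-Johansen step functions
#'
#' Right-continuous step evaluation: the value at `t` is the value at the
#' largest event time `<= t` (0 for the CIF and 1 for survival before the
#' first event time).
#'
#' @param fit an `"aalen_johansen"` object.
#' @param times numeric evaluation times.
#' @param cause optional cause; when given, `cif_at()` returns a vector for
#'   that cause rather than a `length(times)` x K matrix.
#' @return `cif_at()`: matrix (times x causes) or vector; `surv_at()`:
#'   vector of event-free survival probabilities.
#' @export
cif_at <- function(fit, times, cause = NULL) {
  idx <- findInterval(times, fit$times)
  val <- rbind(rep(0, fit$K), fit$cif)[idx + 1L, , drop = FALSE]
  rownames(val) <- NULL
  if (!is.null(cause)) val[, cause] else val
}

#' @rdname cif_at
#' @export
surv_at <- function(fit, times) {
  idx <- findInterval(times, fit$times)
  c(1, fit$surv)[idx + 1L]
}

#' @export
print.aalen_johansen <- function(x, ...) {
  cat("Aalen-Johansen estimator:", x$n, "subjects,", x$K,
      "competing event types,", length(x$times), "event times\n")
  if (length(x$times)) {
    tmax <- max(x$times)
    cat(sprintf("  at t = %g: S = %.4f, %s\n", tmax, x$surv[length(x$surv)],
                paste(sprintf("I_%d = %.4f", seq_len(x$K),
                              x$cif[nrow(x$cif), ]), collapse = ", ")))
  }
  invisible(x)
}
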