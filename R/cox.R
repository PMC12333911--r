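#' Cause-specific Cox proportional-hazards models
#'
#' Fits one Cox model per event type, with treatment and all covariates as
#' main effects and competing events censored, and computes Breslow-form
#' baseline discrete hazard increments
#' \eqn{d\Lambda_{k,0}(t_j) = d_k(t_j) / \sum_{i: T^*_i \ge t_j}
#' \exp(X_i\beta_k + Z_i\theta_k)} at every distinct event time (of any
#' cause). The partial likelihood uses the Efron tie correction
#' (coefficients); the baseline uses the Breslow estimator so that the
#' null model (all coefficients zero) reproduces the pooled Aalen-Johansen
#' estimator exactly under the discrete product-integral prediction of
#' [predict_cif()].
#'
#' @param data a [cr_data()] object with covariates.
#' @return An object of class `"cs_cox"`: list with `coefficients` (per
#'   cause: named vector, treatment first), `baseline` (J x K increment
#'   matrix), `times` (the J distinct event times), `models` (the
#'   underlying `coxph` fits), `covariates`, `K`, `n`.
#' @seealso [predict_cif()], [standardized_cif()]
#' @export
cause_specific_cox <- function(data) {
  data <- as_cr_data(data)
  K <- attr(data, "K")
  X <- cov_matrix(data)
  if (ncol(X) == 0L) stop("outcome regression requires covariates")
  models <- vector("list", K)
  coefs <- vector("list", K)
  df <- data.frame(.time = data$time, treatment = data$treatment, X)
  rhs <- setdiff(names(df), ".time")
  fml <- as.formula(paste("survival::Surv(.time, .ev) ~",
                          paste(rhs, collapse = " + ")))
  for (k in seq_len(K)) {
    if (sum(data$status == k) == 0L)
      stop("no events of cause ", k, "; cannot fit a cause-specific model")
    df$.ev <- as.integer(data$status == k)
    fit <- survival::coxph(fml, data = df, ties = "efron")
    if (any(is.na(coef(fit))))
      stop("cause-", k, " Cox model did not yield full-rank estimates")
    models[[k]] <- fit
    coefs[[k]] <- coef(fit)
  }
  ut <- sort(unique(data$time[data$status > 0L]))
  base <- breslow_increments(data, coefs, ut)
  structure(list(coefficients = coefs, baseline = base, times = ut,
                 models = models, covariates = attr(data, "covariates"),
                 K = K, n = nrow(data)),
            class = "cs_cox")
}

# Breslow baseline increments at the times `ut` for each cause, given
# per-cause coefficient vectors (treatment first, then covariates) on the
# uncentered design.
breslow_increments <- function(data, coefs, ut) {
  K <- attr(data, "K")
  X <- cbind(treatment = data$treatment, cov_matrix(data))
  J <- length(ut)
  base <- matrix(0, J, K)
  ord <- order(data$time)
  st <- data$time[ord]
  for (k in seq_len(K)) {
    r <- exp(as.numeric(X %*% coefs[[k]]))[ord]
    # sum of risk scores over subjects with time >= t_j
    csum <- c(0, cumsum(r))
    denom <- sum(r) - csum[findInterval(ut, st, left.open = TRUE) + 1L]
    dk <- numeric(J)
    sel <- data$status == k
    if (any(sel)) {
      agg <- rowsum(rep(1, sum(sel)), group = match(data$time[sel], ut))
      dk[as.integer(rownames(agg))] <- agg[, 1]
    }
    base[, k] <- ifelse(denom > 0, dk / denom, 0)
  }
  base
}

# Zero-coefficient fit on the same scaffolding; the predicted curves then
# coincide with the pooled Aalen-Johansen estimator. Used for degenerate
# reductions and testing.
cs_cox_zero <- function(data) {
  data <- as_cr_data(data)
  K <- attr(data, "K")
  p <- 1L + length(attr(data, "covariates"))
  coefs <- replicate(K, {
    cf <- rep(0, p)
    names(cf) <- c("treatment", attr(data, "covariates"))
    cf
  }, simplify = FALSE)
  ut <- sort(unique(data$time[data$status > 0L]))
  base <- breslow_increments(data, coefs, ut)
  structure(list(coefficients = coefs, baseline = base, times = ut,
                 models = NULL, covariates = attr(data, "covariates"),
                 K = K, n = nrow(data)),
            class = "cs_cox")
}

#' Predict individual cumulative incidence curves
#'
#' Builds subject-specific curves from a cause-specific Cox fit by the
#' discrete product-integral: with
#' \eqn{d\Lambda_k(t_j|x,z) = d\Lambda_{k,0}(t_j) e^{x\beta_k + z\theta_k}},
#' \eqn{S(t|x,z) = \prod_{t_j \le t}(1 - \sum_k d\Lambda_k(t_j|x,z))} and
#' \eqn{\hat I_k(t|x,z) = \sum_{t_j \le t} S(t_j-|x,z)
#' d\Lambda_k(t_j|x,z)}. If the total discrete hazard at some time exceeds
#' 1 the increments are rescaled so the curve is clipped to [0, 1] and a
#' warning is emitted. Beyond the last event time the curves freeze.
#'
#' @param fit a `"cs_cox"` object.
#' @param x covariate vector, or matrix with one row per subject.
#' @param z treatment arm (0 or 1) applied to every row of `x`.
#' @param times evaluation times.
#' @return List with `cif` (list of K matrices, subjects x times), `surv`
#'   (subjects x times), and `clipped` (number of rescaled increments).
#' @export
predict_cif <- function(fit, x, z, times) {
  if (!inherits(fit, "cs_cox")) stop("expected a 'cs_cox' fit")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  p <- length(fit$covariates)
  if (ncol(x) != p) stop("covariate layout mismatch: expected ", p,
                         " columns (", paste(fit$covariates, collapse = ", "),
                         ")")
  R <- sapply(seq_len(fit$K), function(k) {
    cf <- fit$coefficients[[k]]
    exp(as.numeric(x %*% cf[-1]) + z * cf[1])
  })
  R <- matrix(R, nrow(x), fit$K)
  ord <- order(times)
  gidx <- findInterval(times[ord], fit$times)
  # event times beyond the last grid point never contribute
  Jmax <- if (length(gidx)) max(gidx) else 0L
  res <- cif_predict_kernel(fit$baseline[seq_len(Jmax), , drop = FALSE],
                            R, as.integer(gidx))
  unsort <- order(ord)
  cifs <- lapply(res$cif, function(m) m[, unsort, drop = FALSE])
  if (res$clipped > 0)
    warning("discrete hazard sum exceeded 1 at ", res$clipped,
            " subject-time(s); curves clipped to [0,1]")
  list(cif = cifs, surv = res$surv[, unsort, drop = FALSE],
       clipped = res$clipped)
}

#' Standardized (g-formula) cumulative incidence
#'
#' Marginal curves by outcome regression: every subject's cumulative
#' incidence is predicted from the cause-specific Cox fit at their own
#' covariates with treatment set to z, and averaged over the full sample
#' (the empirical covariate distribution), for z = 0 and z = 1.
#'
#' @param fit a [cause_specific_cox()] fit.
#' @param data the [cr_data()] object to standardize over (normally the
#'   fitting data).
#' @param times evaluation times.
#' @param predictions optional list of precomputed [predict_cif()] results
#'   for arms 0 and 1 over the full sample (reused by [adjcif()] so the
#'   outcome-regression and doubly robust estimators share one prediction
#'   pass).
#' @return A `"cif_estimate"` object with method `"or"`.
#' @export
standardized_cif <- function(fit, data, times, predictions = NULL) {
  data <- as_cr_data(data)
  K <- fit$K
  X <- cov_matrix(data)
  est <- array(0, c(2, K, length(times)))
  clipped <- 0
  for (z in 0:1) {
    pr <- if (!is.null(predictions)) predictions[[z + 1]] else
      withCallingHandlers(
        predict_cif(fit, X, z, times),
        warning = function(w) invokeRestart("muffleWarning"))
    clipped <- clipped + pr$clipped
    for (k in seq_len(K)) est[z + 1, k, ] <- colMeans(pr$cif[[k]])
  }
  diag <- list()
  if (clipped > 0) {
    warning("discrete hazard sum exceeded 1 at ", clipped,
            " subject-time(s) during standardization")
    diag$clipped <- clipped
  }
  new_cif_estimate(times, est, "or", diag)
}

#' @export
print.cs_cox <- function(x, ...) {
  cat("Cause-specific Cox models (", x$n, " subjects, ", x$K,
      " causes)\n", sep = "")
  for (k in seq_len(x$K)) {
    cat("  cause ", k, ": ", sep = "")
    print(round(x$coefficients[[k]], 4))
  }
  invisible(x)
}

#' @export
coef.cs_cox <- function(object, ...) object$coefficients
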