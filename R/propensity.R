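#' Logistic propensity-score model and inverse-probability weights
#'
#' Fits the treatment-assignment model
#' \eqn{P(Z=1|X) = \mathrm{expit}(\gamma_0 + \gamma X)} by maximum
#' likelihood and forms the unstabilized inverse-probability-of-treatment
#' weights \eqn{w_i = 1 / [Z_i \hat P_i + (1-Z_i)(1-\hat P_i)]}. An
#' intercept is always included: the analyst does not know the true
#' assignment mechanism.
#'
#' @param data a [cr_data()] object with at least one covariate.
#' @param trim optional positivity trim: scores are clipped to
#'   `[trim, 1 - trim]` before weighting. Default `NULL` (no trimming).
#' @return An object of class `"propensity_fit"`: list with `intercept`,
#'   `coefficients` (named, covariates only), `scores` (fitted
#'   \eqn{\hat P(Z=1|X)}), `weights`, `vcov`, the underlying `glm` in
#'   `model`, and `n`.
#' @seealso [balance_table()], [ipw_cif()]
#' @export
fit_propensity <- function(data, trim = NULL) {
  data <- as_cr_data(data)
  X <- cov_matrix(data)
  if (ncol(X) == 0L) stop("propensity model requires covariates")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L)
    stop("covariate design matrix is rank deficient")
  df <- data.frame(.z = data$treatment, X)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.z ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  # glm warns only for probabilities within ~1e-15 of 0/1; a vanishing
  # residual deviance (perfect classification) is separation just the same
  if (!sep_warn && fit$deviance < 1e-6 && fit$null.deviance > 1e-3)
    sep_warn <- TRUE
  if (sep_warn) {
    cf <- coef(fit)[-1]
    worst <- names(sort(abs(cf), decreasing = TRUE))[seq_len(min(3, length(cf)))]
    stop("(quasi-)complete separation in the propensity model; ",
         "offending covariate(s), by coefficient magnitude: ",
         paste(worst, collapse = ", "))
  }
  p <- as.numeric(fit$fitted.values)
  if (!is.null(trim)) p <- pmin(pmax(p, trim), 1 - trim)
  z <- data$treatment
  w <- 1 / (z * p + (1 - z) * (1 - p))
  out <- list(intercept = unname(coef(fit)[1]),
              coefficients = coef(fit)[-1],
              scores = p, weights = w, vcov = vcov(fit),
              model = fit, n = nrow(data), trim = trim)
  class(out) <- "propensity_fit"
  out
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Logistic propensity model (", x$n, " subjects)\n", sep = "")
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  print(round(x$coefficients, 4))
  cat("  scores in [", format(min(x$scores), digits = 4), ", ",
      format(max(x$scores), digits = 4), "]; weights in [",
      format(min(x$weights), digits = 4), ", ",
      format(max(x$weights), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Covariate balance before and after weighting
#'
#' Standardized mean differences (SMD) per covariate: the treated-minus-
#' control difference in means divided by the pooled standard deviation
#' \eqn{\sqrt{(s^2_1 + s^2_0)/2}} from the unweighted sample, computed both
#' unweighted and with the inverse-probability weights of `fit`. Covariates
#' with |SMD| above 0.1 are flagged, the conventional imbalance threshold.
#'
#' @param data a [cr_data()] object.
#' @param fit a [fit_propensity()] object for the same data; when `NULL`,
#'   only the unweighted column is meaningful (weights default to 1).
#' @return Data frame with columns `covariate`, `smd_unweighted`,
#'   `smd_weighted`, `flag_unweighted`, `flag_weighted`, `degenerate`.
#' @export
balance_table <- function(data, fit = NULL) {
  data <- as_cr_data(data)
  X <- cov_matrix(data)
  if (ncol(X) == 0L) stop("no covariates to balance")
  w <- if (is.null(fit)) rep(1, nrow(data)) else fit$weights
  z <- data$treatment
  smd <- function(x, wt) {
    m1 <- weighted.mean(x[z == 1], wt[z == 1])
    m0 <- weighted.mean(x[z == 0], wt[z == 0])
    # pooled SD always from the unweighted sample so both columns share a scale
    s <- sqrt((var_unw(x[z == 1]) + var_unw(x[z == 0])) / 2)
    if (s == 0) return(c(0, TRUE))
    c((m1 - m0) / s, FALSE)
  }
  unw <- apply(X, 2, smd, wt = rep(1, nrow(data)))
  wgt <- apply(X, 2, smd, wt = w)
  data.frame(covariate = colnames(X),
             smd_unweighted = unw[1, ],
             smd_weighted = wgt[1, ],
             flag_unweighted = abs(unw[1, ]) > 0.1,
             flag_weighted = abs(wgt[1, ]) > 0.1,
             degenerate = as.logical(unw[2, ]),
             row.names = NULL)
}

var_unw <- function(x) if (length(x) < 2) 0 else stats::var(x)
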