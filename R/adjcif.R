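# Shared estimation engine: computes the requested point estimators once,
# reusing the nuisance fits across methods. Used by adjcif(), the
# bootstrap, and the study runner.
estimate_methods <- function(data, methods, times, trim = NULL) {
  need_prop <- any(c("ipw", "dr") %in% methods)
  need_cox <- any(c("or", "dr") %in% methods)
  prop <- if (need_prop) fit_propensity(data, trim = trim) else NULL
  cox <- if (need_cox) cause_specific_cox(data) else NULL
  preds <- if (need_cox) {
    X <- cov_matrix(data)
    lapply(0:1, function(z) withCallingHandlers(
      predict_cif(cox, X, z, times),
      warning = function(w) invokeRestart("muffleWarning")))
  }
  res <- list()
  for (m in methods)
    res[[m]] <- switch(m,
      crude = crude_cif(data, times),
      ipw = ipw_cif(data, prop, times),
      or = standardized_cif(cox, data, times, predictions = preds),
      dr = dr_cif(data, times, prop = prop, outcome = cox,
                  predictions = preds))
  attr(res, "prop") <- prop
  attr(res, "cox") <- cox
  res
}

#' Adjusted marginal cumulative incidence curves
#'
#' Fits treatment-specific marginal cumulative incidence curves for
#' competing-risks data by one or more of four estimators:
#'
#' * `"crude"` -- per-arm Aalen-Johansen, no adjustment;
#' * `"ipw"` -- per-arm Aalen-Johansen weighted by inverse probability of
#'   treatment from a logistic propensity model;
#' * `"or"` -- outcome regression: cause-specific Cox models with treatment
#'   and covariates, individual predictions standardized over the empirical
#'   covariate distribution;
#' * `"dr"` -- the doubly robust augmented-IPW estimator combining
#'   jackknife pseudo-values with both nuisance models; consistent if
#'   either the propensity or the outcome model is correct.
#'
#' Uncertainty is by nonparametric subject-level bootstrap: all nuisance
#' models (propensity, Cox, pseudo-values) are refit within each resample
#' and pointwise percentile bands are taken, so the bands reflect the
#' estimation of the propensity scores as well.
#'
#' @param formula a formula `Surv(time, status) ~ treat + x1 + ...` naming
#'   the observation-time and status columns on the left and the treatment
#'   plus confounders on the right. `status` is coded 0 = censored,
#'   1..K = event type. Factor covariates are expanded to indicators.
#' @param data a data frame, or a ready-made [cr_data()] object (then
#'   `formula`/`treatment` are ignored).
#' @param treatment name of the treatment column among the right-hand-side
#'   variables.
#' @param method character vector of estimators to compute.
#' @param times evaluation times; default 50 equally spaced times from 0 to
#'   the 90th percentile of observed event times.
#' @param boot number of bootstrap resamples (0 = no bands); 250 is a
#'   reasonable choice for a cohort analysis.
#' @param conf_level confidence level for the percentile bands.
#' @param seed integer seed for the bootstrap.
#' @param trim optional propensity-score trimming bound passed to
#'   [fit_propensity()].
#'
#' @return An object of class `"adjcif"`: list with `times`, `methods`,
#'   `estimates` (per method, a `"cif_estimate"` with `est[arm, cause,
#'   time]` and optional `lower`/`upper` bands), the nuisance fits
#'   `propensity` and `outcome`, `boot` (the [bootstrap_cif()] result),
#'   `K`, `n`, `call`. Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`, `coef`.
#'
#' @examples
#' d <- simulate_crisk(scenario_config(1, N = 800, seed = 42))
#' fit <- adjcif(Surv(time, status) ~ treatment + x1 + x2 + x3,
#'               data = d, treatment = "treatment",
#'               method = c("crude", "dr"), times = c(0.2, 0.5, 0.8))
#' summary(fit)
#' @export
adjcif <- function(formula, data, treatment = "treatment",
                   method = c("crude", "ipw", "or", "dr"), times = NULL,
                   boot = 0, conf_level = 0.95, seed = NULL, trim = NULL) {
  cl <- match.call()
  method <- match.arg(method, c("crude", "ipw", "or", "dr"),
                      several.ok = TRUE)
  if (inherits(data, "cr_data")) {
    crd <- data
  } else {
    if (missing(formula)) stop("a formula is required for plain data frames")
    lhs <- formula[[2]]
    if (!(is.call(lhs) && identical(as.character(lhs[[1]]), "Surv")))
      stop("left-hand side must be Surv(time, status)")
    tm <- eval(lhs[[2]], data, environment(formula))
    st <- eval(lhs[[3]], data, environment(formula))
    rhs <- attr(terms(formula[-2]), "term.labels")
    if (!treatment %in% rhs)
      stop("treatment variable '", treatment,
           "' not found on the right-hand side")
    covs <- setdiff(rhs, treatment)
    crd <- cr_data(time = tm, status = st, treatment = data[[treatment]],
                   covariates = if (length(covs)) data[covs] else NULL)
  }
  if (is.null(times)) {
    ev <- crd$time[crd$status > 0]
    times <- seq(0, quantile(ev, 0.9, names = FALSE), length.out = 50)[-1]
  }
  ests <- estimate_methods(crd, method, times, trim = trim)
  bt <- NULL
  if (boot > 0) {
    bt <- bootstrap_cif(crd, methods = method, times = times, B = boot,
                        conf_level = conf_level, seed = seed, trim = trim)
    for (m in method) {
      ests[[m]]$lower <- bt$lower[[m]]
      ests[[m]]$upper <- bt$upper[[m]]
    }
  }
  structure(list(call = cl, times = times, methods = method,
                 estimates = ests, propensity = attr(ests, "prop"),
                 outcome = attr(ests, "cox"), boot = bt,
                 conf_level = conf_level, K = attr(crd, "K"), n = nrow(crd),
                 data = crd),
            class = "adjcif")
}

#' @export
print.adjcif <- function(x, ...) {
  cat("Adjusted marginal cumulative incidence curves\n")
  cat("  n =", x$n, "subjects,", x$K, "event types; methods:",
      paste(x$methods, collapse = ", "), "\n")
  cat("  evaluation times:", length(x$times), "point(s) in [",
      format(min(x$times), digits = 4), ",",
      format(max(x$times), digits = 4), "]\n")
  if (!is.null(x$boot))
    cat("  bootstrap: B =", x$boot$B, "(", x$boot$discarded,
        "replicate(s) discarded )\n")
  tl <- length(x$times)
  for (m in x$methods) {
    e <- x$estimates[[m]]$est
    cat("  ", m, " at t = ", format(x$times[tl], digits = 4), ": ", sep = "")
    cat(paste(sprintf("I_%d^{z=%d} = %.4f",
                      rep(seq_len(x$K), each = 2), rep(0:1, x$K),
                      as.vector(e[, , tl])), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.adjcif <- function(object, times = NULL, ...) {
  df <- as.data.frame(object)
  if (!is.null(times)) df <- df[df$time %in% times, ]
  cat("Adjusted cumulative incidence estimates (n = ", object$n, ")\n",
      sep = "")
  print(df, row.names = FALSE, digits = 4)
  invisible(df)
}

#' @export
as.data.frame.adjcif <- function(x, ...) {
  rows <- list()
  for (m in x$methods) {
    e <- x$estimates[[m]]
    for (z in 1:2) for (k in seq_len(x$K)) {
      G <- length(x$times)
      rows[[length(rows) + 1L]] <- data.frame(
        method = rep(m, G), arm = rep(z - 1L, G), cause = rep(k, G),
        time = x$times, estimate = e$est[z, k, ],
        lower = if (is.null(e$lower)) rep(NA_real_, G) else e$lower[z, k, ],
        upper = if (is.null(e$upper)) rep(NA_real_, G) else e$upper[z, k, ])
    }
  }
  do.call(rbind, rows)
}

#' @export
coef.adjcif <- function(object, ...) {
  out <- list()
  if (!is.null(object$propensity))
    out$propensity <- c("(Intercept)" = object$propensity$intercept,
                        object$propensity$coefficients)
  if (!is.null(object$outcome))
    out$outcome <- object$outcome$coefficients
  out
}

#' Plot adjusted cumulative incidence curves
#'
#' Step-style curves per arm for one cause, one panel per requested
#' method, with shaded pointwise percentile bands when a bootstrap was run.
#'
#' @param x an [adjcif()] object.
#' @param cause which event type to plot.
#' @param methods methods to show (default all fitted).
#' @param col two colours, control and treated.
#' @param ... passed to [plot()].
#' @export
plot.adjcif <- function(x, cause = 1, methods = x$methods,
                        col = c("#2c6b8f", "#d1902f"), ...) {
  op <- par(mfrow = c(1, length(methods)), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (m in methods) {
    e <- x$estimates[[m]]
    ylim <- c(0, max(e$est[, cause, ], e$upper[, cause, ], 0.05, na.rm = TRUE))
    plot(NA, xlim = range(0, x$times), ylim = ylim, xlab = "time",
         ylab = sprintf("cumulative incidence, cause %d", cause),
         main = m, ...)
    for (z in 1:2) {
      if (!is.null(e$lower))
        polygon(c(x$times, rev(x$times)),
                c(e$lower[z, cause, ], rev(e$upper[z, cause, ])),
                col = adjustcolor(col[z], alpha.f = 0.2), border = NA)
      lines(x$times, e$est[z, cause, ], type = "s", col = col[z], lwd = 2)
    }
    legend("topleft", c("control", "treated"), col = col, lwd = 2,
           bty = "n")
  }
  invisible(x)
}
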