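#' Nonparametric bootstrap bands for marginal CIF estimators
#'
#' Subject-level (pairs) bootstrap: whole rows `(T*, status, Z, X)` are
#' resampled with replacement, every nuisance model (propensity score,
#' cause-specific Cox models, pseudo-values) is refit inside each
#' replicate, and pointwise percentile intervals are taken at levels
#' `alpha/2` and `1 - alpha/2`. Refitting inside the replicate is what
#' makes the bands reflect the sampling variability of the nuisance
#' estimates, including the propensity scores. Per-replicate seeds are
#' derived deterministically from `seed`, so results do not depend on
#' execution order.
#'
#' Replicates in which an estimator cannot be computed (a single treatment
#' arm, or a cause with no events) are discarded and counted; more than
#' 10% discarded is an error.
#'
#' @param data a [cr_data()] object.
#' @param methods estimators to bootstrap (see [adjcif()]).
#' @param times evaluation times.
#' @param B number of resamples (e.g. 250 for a cohort analysis).
#' @param conf_level confidence level (percentile interval).
#' @param seed integer master seed.
#' @param trim optional propensity trimming bound.
#' @return List of class `"cif_boot"`: `B` (effective resamples),
#'   `discarded`, `lower`/`upper` (per method, arm x cause x time arrays),
#'   `draws` (per method, B x arm x cause x time array of replicate
#'   estimates), `se` (per method, pointwise bootstrap standard errors).
#' @export
bootstrap_cif <- function(data, methods, times, B = 250, conf_level = 0.95,
                          seed = NULL, trim = NULL) {
  data <- as_cr_data(data)
  if (B < 2) stop("B must be at least 2")
  alpha <- 1 - conf_level
  if (alpha <= 0 || alpha >= 1) stop("conf_level must be in (0,1)")
  K <- attr(data, "K")
  n <- nrow(data)
  G <- length(times)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  draws <- lapply(methods, function(m) array(NA_real_, c(B, 2, K, G)))
  names(draws) <- methods
  discarded <- 0L
  causes_needed <- if (any(c("or", "dr") %in% methods)) seq_len(K)
                   else integer(0)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    db <- data[idx, , drop = FALSE]
    attributes(db) <- c(attributes(db)[c("names", "row.names")],
                        list(K = K, covariates = attr(data, "covariates"),
                             class = class(data)))
    ok <- length(unique(db$treatment)) == 2L &&
      all(vapply(causes_needed, function(k) any(db$status == k), logical(1)))
    ests <- if (!ok) NULL else tryCatch(
      withCallingHandlers(estimate_methods(db, methods, times, trim = trim),
                          warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(ests)) {
      discarded <- discarded + 1L
      next
    }
    for (m in methods) draws[[m]][b, , , ] <- ests[[m]]$est
  }
  if (discarded > 0.1 * B)
    stop(discarded, " of ", B, " bootstrap replicates discarded (> 10%)")
  lower <- upper <- se <- list()
  for (m in methods) {
    d <- draws[[m]]
    lo <- hi <- s <- array(NA_real_, c(2, K, G))
    for (z in 1:2) for (k in seq_len(K)) for (g in seq_len(G)) {
      x <- d[, z, k, g]
      x <- x[!is.na(x)]
      q <- quantile(x, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      lo[z, k, g] <- q[1]
      hi[z, k, g] <- q[2]
      s[z, k, g] <- sd(x)
    }
    lower[[m]] <- lo
    upper[[m]] <- hi
    se[[m]] <- s
  }
  structure(list(B = B - discarded, discarded = discarded, times = times,
                 lower = lower, upper = upper, se = se, draws = draws,
                 conf_level = conf_level),
            class = "cif_boot")
}

#' @export
print.cif_boot <- function(x, ...) {
  cat("Bootstrap percentile bands: B =", x$B, "effective resamples (",
      x$discarded, "discarded ),", 100 * x$conf_level, "% level\n")
  invisible(x)
}
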