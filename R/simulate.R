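#' Simulation scenario configuration
#'
#' Bundles the parameters of the competing-risks data-generating process
#' used throughout the simulation study. Two competing events; covariates
#' are a three-category multinomial variable with equal probabilities,
#' represented by two reference-coded indicators `x1`, `x2`, plus a
#' standard-normal `x3`. Conditional on treatment and covariates, each
#' cause-specific hazard is constant in time:
#' \eqn{\lambda_k(z, x) = e^{\lambda_{k,0}} \exp(x\beta_k + z\theta_k)}
#' (Scenarios 3-4 add a nonlinear term \eqn{-4 \cdot 1\{x_3 < 1\}} to the
#' log hazard). Treatment assignment:
#' * Scenario 1: logistic, \eqn{P(Z=1|X) = \mathrm{expit}(X\omega)} with no
#'   intercept -- the analysis models are then both correctly specified.
#' * Scenario 2: the treated arm of a Scenario-1 draw is kept and controls
#'   are refilled from a reservoir randomized with probability 1/2, so
#'   treatment assignment no longer follows a logistic model
#'   (misspecified propensity model).
#' * Scenario 3: logistic assignment, nonlinear outcome hazard
#'   (misspecified outcome model).
#' * Scenario 4: both mechanisms of Scenarios 2 and 3 (both misspecified).
#'
#' Censoring is uniform between the 20th and 95th empirical percentiles of
#' the realized event times of the run, which censors roughly 25% of
#' subjects.
#'
#' @param scenario integer 1-4.
#' @param N sample size (default 4000, the study's size).
#' @param theta treatment log-hazard effects, per cause.
#' @param beta1,beta2 covariate log-hazard effects per cause (for
#'   `x1, x2, x3`).
#' @param omega treatment-model coefficients (no intercept).
#' @param log_baseline log baseline hazards per cause; default 0 (hazard
#'   multiplier 1) for Scenarios 1-2 and `log(2)` (multiplier 2) for
#'   Scenarios 3-4.
#' @param reservoir_factor size of the Scenario-2/4 randomized reservoir,
#'   as a multiple of `N`.
#' @param seed optional integer seed used by [simulate_crisk()].
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = 1, N = 4000,
                            theta = c(-1, -0.5),
                            beta1 = c(1, -1, 0.5),
                            beta2 = c(-1, 1, -0.5),
                            omega = c(1, -1, 1),
                            log_baseline = NULL,
                            reservoir_factor = 10,
                            seed = NULL) {
  if (!scenario %in% 1:4) stop("scenario must be 1, 2, 3 or 4")
  if (is.null(log_baseline))
    log_baseline <- if (scenario %in% c(1, 2)) c(0, 0) else c(log(2), log(2))
  structure(list(scenario = as.integer(scenario), N = as.integer(N),
                 theta = theta, beta = list(beta1, beta2), omega = omega,
                 log_baseline = log_baseline,
                 nonlinear = scenario %in% c(3, 4),
                 two_stage = scenario %in% c(2, 4),
                 reservoir_factor = reservoir_factor, seed = seed),
            class = "scenario_config")
}

draw_covariates <- function(n) {
  cat3 <- sample.int(3, n, replace = TRUE)
  cbind(x1 = as.numeric(cat3 == 2), x2 = as.numeric(cat3 == 3),
        x3 = rnorm(n))
}

# constant conditional cause-specific log hazard log lambda_k(z, x)
log_cond_hazard <- function(config, k, X, z) {
  lp <- as.numeric(X %*% config$beta[[k]]) + z * config$theta[k]
  if (config$nonlinear) lp <- lp - 4 * (X[, 3] < 1)
  config$log_baseline[k] + lp
}

cond_hazard <- function(config, k, X, z)
  exp(log_cond_hazard(config, k, X, z))

#' Simulate a competing-risks dataset
#'
#' Draws covariates, treatment, two latent exponential event times via the
#' inverse-probability-transform \eqn{T_{ik} = -\log(U_{ik}) /
#' \lambda_k(Z_i, X_i)}, takes the first event, and applies uniform
#' censoring between the 20th and 95th empirical percentiles of the
#' realized first-event times. See [scenario_config()] for the scenarios.
#'
#' @param config a [scenario_config()]; its `seed`, when non-`NULL`, makes
#'   the draw reproducible.
#' @return A [cr_data()] object with covariates `x1`, `x2`, `x3` and the
#'   configuration attached as attribute `"config"`.
#' @examples
#' d <- simulate_crisk(scenario_config(1, N = 1000, seed = 1))
#' mean(d$status == 0)  # roughly 25% censored
#' @export
simulate_crisk <- function(config) {
  if (!inherits(config, "scenario_config")) stop("expected a scenario_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$N
  if (!config$two_stage) {
    X <- draw_covariates(N)
    Z <- rbinom(N, 1, plogis(as.numeric(X %*% config$omega)))
  } else {
    X1 <- draw_covariates(N)
    Z1 <- rbinom(N, 1, plogis(as.numeric(X1 %*% config$omega)))
    keep <- Z1 == 1
    n1 <- sum(keep)
    nres <- ceiling(config$reservoir_factor * N)
    Xr <- draw_covariates(nres)
    Zr <- rbinom(nres, 1, 0.5)
    ctrl <- which(Zr == 0)
    if (length(ctrl) < N - n1)
      stop("reservoir too small; increase reservoir_factor")
    take <- ctrl[seq_len(N - n1)]
    X <- rbind(X1[keep, , drop = FALSE], Xr[take, , drop = FALSE])
    Z <- c(rep(1L, n1), rep(0L, N - n1))
  }
  lam1 <- cond_hazard(config, 1, X, Z)
  lam2 <- cond_hazard(config, 2, X, Z)
  T1 <- -log(runif(N)) / lam1
  T2 <- -log(runif(N)) / lam2
  Tev <- pmin(T1, T2)
  cause <- ifelse(T1 < T2, 1L, 2L)
  q <- quantile(Tev, c(0.20, 0.95), names = FALSE)
  C <- runif(N, q[1], q[2])
  obs <- pmin(Tev, C)
  status <- ifelse(Tev > C, 0L, cause)
  d <- cr_data(time = obs, status = status, treatment = Z,
               covariates = as.data.frame(X), K = 2L)
  attr(d, "config") <- config
  d
}

# closed-form conditional CIF for constant hazards:
# I_k(t | x, z) = lam_k / (lam1 + lam2) * (1 - exp(-(lam1 + lam2) t))
cond_cif <- function(config, k, X, z, t) {
  l1 <- log_cond_hazard(config, 1, X, z)
  l2 <- log_cond_hazard(config, 2, X, z)
  # lam_k / (lam_1 + lam_2) computed on the log scale for stability in the
  # quadrature tails
  frac <- plogis(if (k == 1) l1 - l2 else l2 - l1)
  tot <- exp(l1) + exp(l2)
  frac * (1 - exp(-outer(tot, t)))
}

#' True marginal cumulative incidence (oracle)
#'
#' Exact marginal counterfactual cumulative incidence for a simulation
#' scenario. Conditional on covariates and arm the hazards are constant in
#' time, so the conditional CIF has the closed form
#' \eqn{I_k(t|x,z) = \frac{\lambda_k}{\lambda_1+\lambda_2}
#' (1 - e^{-(\lambda_1+\lambda_2)t})}; the marginal truth integrates this
#' over the covariate law of the analysis population. For Scenarios 1 and 3
#' that law is the generating covariate distribution; for Scenarios 2 and 4
#' it is the mixture \eqn{\pi \cdot \mathcal{L}(X|Z=1) + (1-\pi) \cdot
#' \mathcal{L}(X)} induced by the two-stage sampling, with
#' \eqn{\pi = P(Z=1)} under the Scenario-1 logistic model. Integration over
#' `x3` uses adaptive quadrature (split at the nonlinearity knot
#' `x3 = 1` for Scenarios 3-4); the three multinomial categories are summed
#' exactly.
#'
#' @param config a [scenario_config()].
#' @param times evaluation times.
#' @return List of class `"scenario_truth"`: `times`, `cif` (array arm x
#'   cause x time), `surv` (matrix arm x time), `method = "quadrature"`.
#' @seealso [true_cif_mc()] for the independent Monte-Carlo oracle.
#' @export
true_cif <- function(config, times) {
  cats <- rbind(c(0, 0), c(1, 0), c(0, 1))
  integ <- function(f) {
    # E[f(X)] by category sum x adaptive quadrature over x3 ~ N(0,1)
    tot <- 0
    for (c in 1:3) {
      g <- function(x3) {
        X <- cbind(cats[c, 1], cats[c, 2], x3)
        f(X) * stats::dnorm(x3)
      }
      pieces <- if (config$nonlinear) list(c(-Inf, 1), c(1, Inf))
                else list(c(-Inf, Inf))
      for (p in pieces)
        tot <- tot + integrate(g, p[1], p[2], rel.tol = 1e-10,
                               abs.tol = 1e-12)$value / 3
    }
    tot
  }
  escore <- function(X) plogis(as.numeric(X %*% config$omega))
  pi1 <- if (config$two_stage) integ(escore) else NA_real_
  cif <- array(0, c(2, 2, length(times)))
  for (z in 0:1) for (k in 1:2) for (g in seq_along(times)) {
    t <- times[g]
    f <- function(X) cond_cif(config, k, X, z, t)[, 1]
    if (!config$two_stage) {
      cif[z + 1, k, g] <- integ(f)
    } else {
      # mixture: pi * E[f|Z=1] + (1-pi) * E[f] = E[f e] + (1-pi) E[f]
      cif[z + 1, k, g] <- integ(function(X) f(X) * escore(X)) +
        (1 - pi1) * integ(f)
    }
  }
  surv <- 1 - apply(cif, c(1, 3), sum)
  structure(list(times = times, cif = cif, surv = surv,
                 method = "quadrature", pi1 = pi1),
            class = "scenario_truth")
}

#' @rdname true_cif
#' @param mc_size number of covariate draws for the Monte-Carlo oracle.
#' @param seed integer seed for the Monte-Carlo oracle.
#' @param tol when `check = TRUE`, maximum tolerated absolute disagreement
#'   between the quadrature and Monte-Carlo oracles.
#' @param check if `TRUE`, [true_cif_mc()] also runs the quadrature oracle
#'   and errors if the two disagree beyond `tol` (a truth-oracle bug
#'   signal).
#' @export
true_cif_mc <- function(config, times, mc_size = 1e6, seed = 1,
                        tol = 1e-3, check = FALSE) {
  set.seed(seed)
  n <- as.integer(mc_size)
  if (!config$two_stage) {
    X <- draw_covariates(n)
  } else {
    # two-stage mechanism: keep treated of a logistic draw, refill controls
    # from the randomized reservoir (whose controls follow the base law)
    X0 <- draw_covariates(n)
    Z0 <- rbinom(n, 1, plogis(as.numeric(X0 %*% config$omega)))
    n1 <- sum(Z0 == 1)
    X <- rbind(X0[Z0 == 1, , drop = FALSE],
               draw_covariates(n - n1))
  }
  cif <- array(0, c(2, 2, length(times)))
  for (z in 0:1) for (k in 1:2)
    cif[z + 1, k, ] <- colMeans(cond_cif(config, k, X, z, times))
  out <- structure(list(times = times, cif = cif,
                        surv = 1 - apply(cif, c(1, 3), sum),
                        method = "monte-carlo"),
                   class = "scenario_truth")
  if (check) {
    quad <- true_cif(config, times)
    dev <- max(abs(quad$cif - cif))
    if (dev > tol)
      stop("truth oracles disagree: max |quadrature - MC| = ",
           format(dev, digits = 4), " > ", tol)
    attr(out, "oracle_deviation") <- dev
  }
  out
}

#' Run a bias/RMSE simulation study
#'
#' Repeats: simulate a dataset under the scenario, compute the requested
#' marginal CIF estimators on the evaluation times, and record the
#' deviation from the truth oracle. Reports, per method, arm, cause (and
#' event-free survival, computed as one minus the sum of the per-cause
#' estimates) and time: mean bias, RMSE, the 2.5th/97.5th percentiles of
#' the deviations, and the Monte-Carlo standard error of the bias.
#' Replications are independently seeded from `seed`; a replication in
#' which an estimator fails (e.g. a resampled arm empty) is excluded for
#' that method and counted.
#'
#' @param scenario integer 1-4, or a full [scenario_config()] via `config`.
#' @param M number of replications.
#' @param N per-replication sample size.
#' @param times evaluation times.
#' @param methods subset of `c("crude", "ipw", "or", "dr")`.
#' @param seed master seed.
#' @param config optional [scenario_config()] overriding `scenario`/`N`.
#' @return Data frame of class `"cif_study"` with columns `scenario`,
#'   `method`, `arm`, `cause` (`"1"`, `"2"`, `"efs"`), `time`, `bias`,
#'   `rmse`, `p2.5`, `p97.5`, `mc_se`, `M_used`; excluded-replication
#'   counts in `attr(, "excluded")`, the truth in `attr(, "truth")`.
#' @examples
#' \donttest{
#' run_study(1, M = 20, N = 1000, times = 0.8, methods = "crude", seed = 1)
#' }
#' @export
run_study <- function(scenario = 1, M = 200, N = 4000, times = 0.8,
                      methods = c("crude", "ipw", "or", "dr"),
                      seed = 1, config = NULL) {
  if (M < 2) stop("at least 2 replications required")
  methods <- match.arg(methods, c("crude", "ipw", "or", "dr"),
                       several.ok = TRUE)
  if (is.null(config)) config <- scenario_config(scenario, N = N)
  truth <- true_cif(config, times)
  G <- length(times)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, M)
  dev <- lapply(methods, function(m) array(NA_real_, c(M, 2, 3, G)))
  names(dev) <- methods
  excluded <- stats::setNames(integer(length(methods)), methods)
  for (m in seq_len(M)) {
    cfg <- config
    cfg$seed <- seeds[m]
    d <- simulate_crisk(cfg)
    ests <- tryCatch(
      withCallingHandlers(estimate_methods(d, methods, times),
                          warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(ests)) {
      excluded <- excluded + 1L
      next
    }
    for (meth in methods) {
      e <- ests[[meth]]$est                       # [arm, cause, time]
      efs <- 1 - apply(e, c(1, 3), sum)
      dev[[meth]][m, , 1:2, ] <- e - truth$cif
      dev[[meth]][m, , 3, ] <- efs - truth$surv
    }
  }
  rows <- list()
  for (meth in methods) for (z in 1:2) for (k in 1:3) for (g in seq_len(G)) {
    x <- dev[[meth]][, z, k, g]
    x <- x[!is.na(x)]
    q <- quantile(x, c(0.025, 0.975), names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = config$scenario, method = meth, arm = z - 1L,
      cause = c("1", "2", "efs")[k], time = times[g],
      bias = mean(x), rmse = sqrt(mean(x^2)),
      p2.5 = q[1], p97.5 = q[2],
      mc_se = sd(x) / sqrt(length(x)), M_used = length(x))
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  attr(out, "truth") <- truth
  class(out) <- c("cif_study", "data.frame")
  out
}

#' @export
print.cif_study <- function(x, digits = 5, ...) {
  cat("Simulation study: scenario", x$scenario[1], "-",
      max(x$M_used), "replications\n")
  df <- as.data.frame(x)
  df$bias <- round(df$bias, digits)
  df$rmse <- round(df$rmse, digits)
  df$p2.5 <- round(df$p2.5, digits)
  df$p97.5 <- round(df$p97.5, digits)
  df$mc_se <- round(df$mc_se, digits)
  print(df, row.names = FALSE)
  exc <- attr(x, "excluded")
  if (!is.null(exc) && any(exc > 0))
    cat("excluded replications:",
        paste(names(exc), exc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
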