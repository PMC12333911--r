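test_that("a zero-coefficient model reproduces the pooled Aalen-Johansen exactly", {
  d <- sim_data(300, seed = 4)
  fit0 <- drcif:::cs_cox_zero(d)
  pooled <- aalen_johansen(d)
  grid <- c(0.1, 0.3, 0.6, 1, 1.5)
  pr <- predict_cif(fit0, c(5, -3, 0.2), z = 1, times = grid)
  for (k in 1:2)
    expect_equal(as.numeric(pr$cif[[k]]), cif_at(pooled, grid, cause = k),
                 tolerance = 1e-12)
  st <- standardized_cif(fit0, d, grid)
  for (z in 1:2) for (k in 1:2)
    expect_equal(st$est[z, k, ], cif_at(pooled, grid, cause = k),
                 tolerance = 1e-12)
})

test_that("individual predictions conserve probability and freeze beyond follow-up", {
  d <- sim_data(400, seed = 8)
  fit <- cause_specific_cox(d)
  grid <- c(0.2, 0.5, 1, 2, 1e6)
  X <- drcif:::cov_matrix(d)[1:20, ]
  for (z in 0:1) {
    pr <- suppressWarnings(predict_cif(fit, X, z, grid))
    tot <- pr$surv + pr$cif[[1]] + pr$cif[[2]]
    expect_lt(max(abs(tot - 1)), 1e-12)
    # beyond the last event time the curve freezes
    expect_equal(pr$cif[[1]][, 5], pr$cif[[1]][, 4])
  }
})

test_that("log-hazard ratios are recovered in a single-covariate exponential model", {
  set.seed(12)
  n <- 8000
  x <- rbinom(n, 1, 0.5)
  z <- rbinom(n, 1, 0.5)
  tt <- rexp(n, rate = exp(0.7 * x + 0 * z))
  cens <- runif(n, 0, quantile(tt, 0.9))
  d <- cr_data(time = pmin(tt, cens), status = as.integer(tt <= cens),
               treatment = z, covariates = data.frame(x = x), K = 1)
  fit <- cause_specific_cox(d)
  cf <- fit$coefficients[[1]]
  se <- sqrt(diag(vcov(fit$models[[1]])))
  expect_lt(abs(cf[["x"]] - 0.7), 3 * se[["x"]])
  # a covariate permuted against the outcome has no effect
  d$x <- sample(d$x)
  fit2 <- cause_specific_cox(d)
  expect_lt(abs(fit2$coefficients[[1]][["x"]]),
            3 * sqrt(diag(vcov(fit2$models[[1]])))[["x"]])
})

test_that("predictions match the constant-hazard closed form at the reference covariates", {
  d <- sim_data(20000, seed = 23)
  fit <- cause_specific_cox(d)
  # at x = (0,0,0), z = 0 the true hazards are lambda_k = 1, so
  # I_1(t) = (1/2) (1 - exp(-2t))
  grid <- c(0.3, 0.8)
  pr <- predict_cif(fit, c(0, 0, 0), z = 0, times = grid)
  # sampling SD of the reference-point prediction is about 0.012 at this n
  expect_lt(max(abs(as.numeric(pr$cif[[1]]) - 0.5 * (1 - exp(-2 * grid)))),
            0.04)
})

test_that("standardization averages the individual curves", {
  # identical covariates for everyone: the average IS the individual curve
  set.seed(3)
  n <- 200
  d <- cr_data(time = rexp(n) + 0.05, status = sample(0:2, n, TRUE),
               treatment = rbinom(n, 1, 0.5),
               covariates = data.frame(x = rep(1.3, n), y = rnorm(n)))
  d$x <- rep(1.3, n)
  fit <- drcif:::cs_cox_zero(d)  # zero coefficients: x layout irrelevant
  grid <- c(0.2, 0.6)
  st <- suppressWarnings(standardized_cif(fit, d, grid))
  pr <- predict_cif(fit, as.matrix(d[, c("x", "y")]), 1, grid)
  expect_equal(st$est[2, 1, ], colMeans(pr$cif[[1]]))

  # monotone, bounded standardized curves on real fits
  d2 <- sim_data(600, seed = 14)
  grid2 <- seq(0.1, 1.5, by = 0.1)
  st2 <- suppressWarnings(standardized_cif(cause_specific_cox(d2), d2, grid2))
  expect_true(all(st2$est >= 0 & st2$est <= 1))
  expect_true(all(apply(st2$est, 1:2, function(v) all(diff(v) >= -1e-12))))
})

test_that("a cause without events is refused by name", {
  n <- 30
  d <- cr_data(time = rexp(n) + 0.1, status = sample(c(0L, 1L), n, TRUE),
               treatment = rep(0:1, n / 2),
               covariates = data.frame(x = rnorm(n)), K = 2)
  expect_error(cause_specific_cox(d), "cause 2")
})
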