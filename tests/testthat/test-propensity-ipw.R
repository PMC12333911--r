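test_that("randomized treatment yields a null propensity model", {
  set.seed(21)
  n <- 4000
  d <- cr_data(time = rexp(n), status = sample(0:2, n, TRUE),
               treatment = rbinom(n, 1, 0.6),
               covariates = data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5)))
  fit <- fit_propensity(d)
  se <- sqrt(diag(fit$vcov))[-1]
  expect_true(all(abs(fit$coefficients) < 3 * se))
  expect_lt(max(abs(fit$scores - mean(d$treatment))), 0.05)
})

test_that("IP weights follow the inverse assignment probability", {
  d <- sim_data(500, seed = 2)
  fit <- fit_propensity(d)
  p <- fit$scores
  z <- d$treatment
  expect_equal(fit$weights, 1 / (z * p + (1 - z) * (1 - p)))
  expect_true(all(fit$weights >= 1))
  # a control subject with score 0.2 would get weight 1/0.8 = 1.25
  i <- which.min(abs(p - 0.2))
  if (z[i] == 0) expect_equal(fit$weights[i], 1 / (1 - p[i]))
})

test_that("the treatment-model coefficients are recovered on confounded data", {
  d <- sim_data(20000, seed = 31)
  fit <- fit_propensity(d)
  cf <- c(fit$intercept, fit$coefficients)
  se <- sqrt(diag(fit$vcov))
  truth <- c(0, 1, -1, 1)  # generator uses logit P(Z=1|X) = x1 - x2 + x3
  expect_true(all(abs(cf - truth) < 3 * se))
})

test_that("perfect separation and rank deficiency are reported", {
  n <- 40
  z <- rep(0:1, each = n / 2)
  d <- cr_data(time = rexp(n) + 0.1, status = rep(1L, n), treatment = z,
               covariates = data.frame(xsep = z * 2 - 1, x2 = rnorm(n)))
  expect_error(fit_propensity(d), "separation")

  d2 <- cr_data(time = rexp(n) + 0.1, status = rep(1L, n),
                treatment = rbinom(n, 1, 0.5),
                covariates = data.frame(a = rnorm(n)))
  d2$b <- d2$a * 2
  attr(d2, "covariates") <- c("a", "b")
  expect_error(fit_propensity(d2), "rank deficient")
})

test_that("unit weights make the IPW estimator collapse to the crude one", {
  d <- sim_data(400, seed = 7)
  fit <- fit_propensity(d)
  fit$weights <- rep(1, nrow(d))
  times <- c(0.2, 0.5, 0.9)
  expect_equal(ipw_cif(d, fit, times)$est, crude_cif(d, times)$est,
               tolerance = 1e-14)
})

test_that("IPW estimates are consistent for the marginal truth at large n", {
  d <- sim_data(20000, seed = 13)
  truth <- true_cif(scenario_config(1), 0.8)
  est <- ipw_cif(d, fit_propensity(d), 0.8)
  # Monte-Carlo tolerance ~ 3 x the sampling SD of the weighted estimator
  expect_lt(max(abs(est$est[, , 1] - truth$cif[, , 1])), 0.02)
  # conservation/monotonicity inherited from the weighted product-limit
  grid <- seq(0.1, 1.2, by = 0.1)
  e <- ipw_cif(d, fit_propensity(d), grid)$est
  expect_true(all(apply(e, 1:2, function(x) all(diff(x) >= -1e-12))))
})

test_that("positivity violations warn but still return an estimate", {
  d <- sim_data(300, seed = 9)
  fit <- fit_propensity(d)
  fit$scores[1] <- 1e-9
  expect_warning(est <- ipw_cif(d, fit, 0.5), "positivity")
  expect_equal(est$diagnostics$positivity, 1)
})

test_that("balance tables flag confounding and weighting repairs it", {
  d <- sim_data(10000, seed = 17)
  fit <- fit_propensity(d)
  tab <- balance_table(d, fit)
  x1 <- tab[tab$covariate == "x1", ]
  expect_gt(abs(x1$smd_unweighted), 0.1)
  expect_true(all(abs(tab$smd_weighted) < 0.1))

  # unit weights reproduce the unweighted column
  fit$weights <- rep(1, nrow(d))
  tab1 <- balance_table(d, fit)
  expect_equal(tab1$smd_weighted, tab1$smd_unweighted)

  # a degenerate (constant) covariate reports SMD 0 with a flag
  n <- 50
  dc <- cr_data(time = rexp(n) + 0.1, status = sample(0:2, n, TRUE),
                treatment = rep(0:1, n / 2),
                covariates = data.frame(x = rnorm(n), cst = rep(2, n)))
  tabc <- balance_table(dc)
  expect_equal(tabc[tabc$covariate == "cst", "smd_unweighted"], 0)
  expect_true(tabc[tabc$covariate == "cst", "degenerate"])
})
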