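test_that("scenario configurations validate and carry the study defaults", {
  cfg <- scenario_config(1)
  expect_equal(cfg$theta, c(-1, -0.5))
  expect_equal(cfg$beta[[1]], c(1, -1, 0.5))
  expect_equal(cfg$beta[[2]], c(-1, 1, -0.5))
  expect_equal(cfg$omega, c(1, -1, 1))
  expect_equal(cfg$log_baseline, c(0, 0))
  expect_equal(scenario_config(3)$log_baseline, c(log(2), log(2)))
  expect_error(scenario_config(5), "scenario")
})

test_that("simulated datasets are reproducible and well formed", {
  d1 <- simulate_crisk(scenario_config(2, N = 500, seed = 77))
  d2 <- simulate_crisk(scenario_config(2, N = 500, seed = 77))
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 500)
  expect_identical(attr(d1, "K"), 2L)
  expect_setequal(unique(d1$status), 0:2)
  # roughly a quarter of observations are censored
  frac <- mean(vapply(1:10, function(s)
    mean(simulate_crisk(scenario_config(1, N = 2000, seed = s))$status == 0),
    numeric(1)))
  expect_gt(frac, 0.20)
  expect_lt(frac, 0.30)
})

test_that("with no covariate or treatment effects the arms are exchangeable", {
  cfg <- scenario_config(1, N = 4000, theta = c(0, 0),
                         beta1 = c(0, 0, 0), beta2 = c(0, 0, 0),
                         omega = c(0, 0, 0), seed = 5)
  d <- simulate_crisk(cfg)
  e <- crude_cif(d, 0.4)$est
  expect_lt(abs(e[1, 1, 1] - e[2, 1, 1]), 0.05)
})

test_that("the null-effect truth has the stated closed form", {
  cfg <- scenario_config(1, theta = c(0, 0), beta1 = c(0, 0, 0),
                         beta2 = c(0, 0, 0))
  tr <- true_cif(cfg, c(0.8, 1.5))
  # I_1(t) = (1/2)(1 - exp(-2t)); at t = 0.8 this is 0.3990517
  expect_equal(tr$cif[1, 1, 1], 0.3990517, tolerance = 1e-6)
  expect_equal(tr$cif[1, 1, ], 0.5 * (1 - exp(-2 * c(0.8, 1.5))),
               tolerance = 1e-9)
  expect_equal(tr$cif[1, , ], tr$cif[2, , ], tolerance = 1e-9)
})

test_that("protective treatment effects order the true incidence curves", {
  tr <- true_cif(scenario_config(1), c(0.2, 0.8, 2))
  expect_true(all(tr$cif[2, 1, ] < tr$cif[1, 1, ]))  # theta_1 = -1 < 0
  expect_true(all(tr$surv >= 0 & tr$surv <= 1))
  expect_lt(max(abs(apply(tr$cif, c(1, 3), sum) + tr$surv - 1)), 1e-9)
})

test_that("quadrature and Monte-Carlo truth oracles agree across scenarios", {
  for (sc in c(1, 2, 3)) {
    cfg <- scenario_config(sc)
    tt <- if (sc == 3) c(1, 5) else c(0.4, 0.8)
    mc <- true_cif_mc(cfg, tt, mc_size = 2e5, seed = 3, check = TRUE,
                      tol = 6e-3)
    expect_lt(attr(mc, "oracle_deviation"), 6e-3)
  }
})

test_that("a small study reports coherent bias/RMSE tables", {
  st <- run_study(1, M = 6, N = 600, times = c(0.4, 0.8),
                  methods = c("crude", "or"), seed = 9)
  df <- as.data.frame(st)
  expect_equal(nrow(df), 2 * 2 * 3 * 2)  # methods x arms x outcomes x times
  expect_true(all(df$rmse >= abs(df$bias) - 1e-12))
  expect_true(all(df$p2.5 <= df$p97.5))
  expect_equal(unname(attr(st, "excluded")), c(0L, 0L))
  # deterministic given the master seed
  st2 <- run_study(1, M = 6, N = 600, times = c(0.4, 0.8),
                   methods = c("crude", "or"), seed = 9)
  expect_equal(df$bias, as.data.frame(st2)$bias)
})

test_that("a crude-only study under randomization is unbiased", {
  cfg <- scenario_config(1, N = 1500, omega = c(0, 0, 0))
  st <- run_study(config = cfg, M = 30, times = 0.8, methods = "crude",
                  seed = 15)
  df <- as.data.frame(st)
  ci <- df[df$cause != "efs", ]
  expect_true(all(abs(ci$bias) < 3.5 * ci$mc_se))
})

test_that("misspecifying one nuisance model biases only its own estimator", {
  ratios <- function(st) {
    df <- as.data.frame(st)
    df <- df[df$cause != "efs", ]
    split(abs(df$bias) / df$mc_se, df$method)
  }
  # Scenario 2 (treatment model misspecified): IPW clearly biased at the
  # Monte-Carlo resolution of the study; OR and DR are not
  r2 <- ratios(run_study(2, M = 40, N = 4000, times = 0.8,
                         methods = c("ipw", "or", "dr"), seed = 5))
  expect_gt(max(r2$ipw), 3)
  expect_lt(max(r2$or), 3)
  expect_lt(max(r2$dr), 3)
  # Scenario 3 (outcome model misspecified): OR biased, IPW and DR not
  r3 <- ratios(run_study(3, M = 30, N = 4000, times = 5,
                         methods = c("ipw", "or", "dr"), seed = 6))
  expect_gt(max(r3$or), 3)
  expect_lt(max(r3$ipw), 3)
  expect_lt(max(r3$dr), 3)
})
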