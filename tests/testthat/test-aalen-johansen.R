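test_that("hand-computed product-limit table is reproduced", {
  fit <- aalen_johansen(toy4_time, toy4_status)
  expect_equal(cif_at(fit, 1, cause = 1), 1 / 4)
  expect_equal(cif_at(fit, 2, cause = 1), 1 / 4)   # censoring: no step
  expect_equal(cif_at(fit, 3, cause = 2), 3 / 8)
  expect_equal(cif_at(fit, 4, cause = 1), 5 / 8)
  expect_equal(surv_at(fit, 4), 0)
  expect_equal(cif_at(fit, 0.5, cause = 1), 0)     # before first event
})

test_that("without censoring the estimator is the empirical distribution", {
  fit <- aalen_johansen(c(1, 2), c(1, 1))
  expect_equal(cif_at(fit, 2, cause = 1), 1)
  expect_equal(surv_at(fit, 2), 0)

  s <- random_cr(60, seed = 3, p_cens = 0)
  fit <- aalen_johansen(s$time, s$status, K = 2)
  for (t in c(0.3, 0.9, 2)) {
    expect_equal(cif_at(fit, t, cause = 1),
                 mean(s$time <= t & s$status == 1))
    expect_equal(cif_at(fit, t, cause = 2),
                 mean(s$time <= t & s$status == 2))
  }
})

test_that("conservation, monotonicity and range hold for any data and weights", {
  for (seed in 1:8) {
    s <- random_cr(70, seed = seed)
    set.seed(seed + 100)
    w <- if (seed %% 2) NULL else runif(70, 0.2, 3)
    fit <- aalen_johansen(s$time, s$status, weights = w, K = 2)
    expect_lt(max(abs(fit$surv + rowSums(fit$cif) - 1)), 1e-12)
    expect_true(all(diff(fit$surv) <= 1e-12))
    expect_true(all(apply(fit$cif, 2, function(x) all(diff(x) >= -1e-12))))
    expect_true(all(fit$cif >= -1e-12 & fit$cif <= 1 + 1e-12))
  }
})

test_that("integer weights are equivalent to row replication", {
  s <- random_cr(50, seed = 5)
  set.seed(6)
  m <- sample(1:3, 50, replace = TRUE)
  fw <- aalen_johansen(s$time, s$status, weights = m, K = 2)
  fr <- aalen_johansen(rep(s$time, m), rep(s$status, m), K = 2)
  expect_equal(fw$times, fr$times)
  expect_equal(fw$cif, fr$cif, tolerance = 1e-12)
  expect_equal(fw$surv, fr$surv, tolerance = 1e-12)
})

test_that("unweighted estimator agrees with the multi-state product-limit oracle", {
  for (seed in c(2, 9)) {
    s <- random_cr(90, seed = seed)
    fit <- aalen_johansen(s$time, s$status, K = 2)
    sf <- survival::survfit(
      survival::Surv(s$time, factor(s$status, levels = 0:2)) ~ 1)
    idx <- match(fit$times, sf$time)
    expect_equal(fit$cif[, 1], sf$pstate[idx, 2], tolerance = 1e-12)
    expect_equal(fit$cif[, 2], sf$pstate[idx, 3], tolerance = 1e-12)
    expect_equal(fit$surv, sf$pstate[idx, 1], tolerance = 1e-12)
  }
})

test_that("degenerate inputs are handled", {
  # all censored: a valid fit with zero incidence
  fit <- aalen_johansen(c(1, 2, 3), c(0, 0, 0), K = 2)
  expect_equal(cif_at(fit, 5), matrix(0, 1, 2))
  expect_equal(surv_at(fit, 5), 1)
  expect_error(aalen_johansen(c(1, 2), c(1, 1), weights = c(-1, 1)),
               "negative weights")
  expect_error(aalen_johansen(c(1, 2), c(1, 1), weights = c(0, 0)),
               "not all be zero")
})
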