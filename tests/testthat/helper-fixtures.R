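# Small in-code fixtures used across the suite.

# 4-subject dataset whose Aalen-Johansen table was worked out by hand:
# times (1, 2, 3, 4), statuses (1, 0, 2, 1)
# t=1: n=4, d1=1 -> I1 = 1/4,        S = 3/4
# t=3: n=2, d2=1 -> I2 = 3/4 * 1/2 = 3/8, S = 3/8
# t=4: n=1, d1=1 -> I1 = 1/4 + 3/8 = 5/8, S = 0
toy4_time <- c(1, 2, 3, 4)
toy4_status <- c(1L, 0L, 2L, 1L)

# random competing-risks sample with ties (rounded times) and censoring
random_cr <- function(n, seed, K = 2, p_cens = 0.3) {
  set.seed(seed)
  time <- round(rexp(n), 1) + 0.1
  status <- ifelse(runif(n) < p_cens, 0L, sample.int(K, n, replace = TRUE))
  list(time = time, status = status)
}

# small confounded dataset via the scenario generator
sim_data <- function(n, seed, scenario = 1) {
  simulate_crisk(scenario_config(scenario, N = n, seed = seed))
}
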