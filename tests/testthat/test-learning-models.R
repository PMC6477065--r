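test_that("sigmoid is stable, symmetric and matches closed forms", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  x <- c(-800, -5, -0.3, 0, 2, 700)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(is.finite(sigmoid(c(-1e6, 1e6)))))
})

test_that("one HGF step matches the scalar arithmetic oracle to 1e-10", {
  pars <- list(omega2 = -2, omega3 = -6, kappa = 1,
               mu2 = 0, sigma2 = 0.1, mu3 = 1, sigma3 = 1)
  oracle <- hgf_step_oracle(1, pars$omega2, pars$omega3, pars$kappa,
                            pars$mu2, pars$sigma2, pars$mu3, pars$sigma3)
  tr <- hgf_filter(hgf_params(omega2 = -2, omega3 = -6, kappa = 1,
                              mu2_0 = 0, sigma2_0 = 0.1,
                              mu3_0 = 1, sigma3_0 = 1),
                   inputs = 1)
  for (f in c("muhat1", "pihat2", "pihat3", "delta1", "delta2",
              "mu2", "sigma2", "mu3", "sigma3")) {
    expect_lt(abs(tr[[f]] - oracle[[f]]), 1e-10)
  }
  # and a multi-step sequence, iterating the oracle
  u <- c(1, 0, 1, 1, 0, 1)
  st <- pars
  tr <- hgf_filter(hgf_params(omega2 = -2, omega3 = -6, kappa = 1,
                              mu2_0 = 0, sigma2_0 = 0.1,
                              mu3_0 = 1, sigma3_0 = 1), u)
  for (k in seq_along(u)) {
    step <- hgf_step_oracle(u[k], st$omega2, st$omega3, st$kappa,
                            st$mu2, st$sigma2, st$mu3, st$sigma3)
    expect_lt(abs(tr$mu2[k] - step$mu2), 1e-10)
    expect_lt(abs(tr$mu3[k] - step$mu3), 1e-10)
    expect_lt(abs(tr$sigma3[k] - step$sigma3), 1e-10)
    st[c("mu2", "sigma2", "mu3", "sigma3")] <-
      step[c("mu2", "sigma2", "mu3", "sigma3")]
  }
})

test_that("HGF first-trial prediction is 0.5 when mu2_0 = 0 and beliefs rise under constant input", {
  tr <- hgf_filter(hgf_params(mu2_0 = 0, zeta = 1), c(1, 1, 1, 1, 1))
  expect_equal(tr$muhat1[1], 0.5)
  expect_true(all(diff(c(0, tr$mu2)) > 0))
})

test_that("kappa = 0 decouples the third level", {
  p <- hgf_params(omega2 = -3, omega3 = -4, kappa = 0, mu3_0 = 1.7)
  tr <- hgf_filter(p, rbinom(80, 1, 0.7))
  expect_true(all(tr$mu3 == 1.7))
})

test_that("inadmissible HGF parameter regimes raise a classed error", {
  u <- generate_trials(canonical_schedule(), seed = 1)$u
  expect_error(hgf_filter(hgf_params(omega2 = 0.5), u),
               class = "proalhgf_invalid_regime")
})

test_that("higher omega2 produces larger level-2 belief jumps", {
  u <- generate_trials(canonical_schedule(), seed = 12)$u
  jump <- vapply(c(-6, -4, -2), function(o2) {
    tr <- hgf_filter(hgf_params(omega2 = o2), u)
    mean(abs(diff(c(0, tr$mu2))))
  }, numeric(1))
  expect_true(all(diff(jump) > 0))
})

test_that("RW recurrence matches direct arithmetic and its limits", {
  tr <- rw_filter(rw_params(alpha = 0.5, v0 = 0.5), c(1, 1, 0))
  expect_equal(tr$value, c(0.75, 0.875, 0.4375))
  # vanishing learning rate: value stays at v0
  tr0 <- rw_filter(rw_params(alpha = 1e-6, v0 = 0.37), rbinom(50, 1, 0.5))
  expect_true(all(abs(tr0$value - 0.37) < 1e-4))
  # full learning rate: value tracks the input
  u <- rbinom(50, 1, 0.5)
  tr1 <- rw_filter(rw_params(alpha = 1 - 1e-9, v0 = 0.5), u)
  expect_true(all(abs(tr1$value - u) < 1e-6))
})

test_that("SK1 reduces to RW when mu_meta = 0 and matches its one-step oracle", {
  u <- rbinom(100, 1, 0.6)
  sk <- sk1_filter(sk1_params(mu_meta = 0, beta0 = log(0.3), v0 = 0.5), u)
  rw <- rw_filter(rw_params(alpha = 0.3, v0 = 0.5), u)
  expect_equal(sk$value, rw$value, tolerance = 1e-12)

  # one step: h0 = 0 so beta unchanged, alpha = 0.3, v = 0.65,
  # h = 0.3 * 0.5 * 0.7 = 0.105
  tr <- sk1_filter(sk1_params(mu_meta = 0.1, beta0 = log(0.3), v0 = 0.5), 1)
  expect_equal(tr$beta, log(0.3))
  expect_equal(tr$lr, 0.3)
  expect_equal(tr$value, 0.65)
  expect_equal(tr$h, 0.105)
})

test_that("SK1 learning rate never exceeds the cap", {
  u <- rbinom(300, 1, 0.5)
  tr <- sk1_filter(sk1_params(mu_meta = 2, beta0 = log(0.5)), u)
  expect_true(all(tr$lr <= 1))
  expect_error(sk1_params(mu_meta = -0.1), class = "proalhgf_bad_param")
})

test_that("filters are deterministic in params and inputs", {
  u <- generate_trials(canonical_schedule(), seed = 2)$u
  expect_identical(hgf_filter(hgf_params(), u), hgf_filter(hgf_params(), u))
  expect_identical(rw_filter(rw_params(), u), rw_filter(rw_params(), u))
  expect_identical(sk1_filter(sk1_params(), u), sk1_filter(sk1_params(), u))
})

test_that("unit-square sigmoid response model matches closed forms", {
  expect_equal(response_prob(0.5, 7.3), 0.5)
  m <- c(0.1, 0.42, 0.9)
  expect_equal(response_prob(m, 1), m)
  expect_equal(response_prob(0.75, 2), 0.9) # 0.5625 / 0.625
  expect_error(response_prob(0.5, 0), class = "proalhgf_bad_param")
})

test_that("response log-likelihood sums over non-missing trials", {
  traj <- data.frame(muhat1 = c(0.5, 0.8, 0.3))
  expect_equal(response_loglik(traj, c(NA, NA, NA), 2), 0)
  expect_equal(response_loglik(traj[1, , drop = FALSE], 1, 5), log(0.5))
  # hand-summed three-trial case
  zeta <- 2
  p <- response_prob(c(0.5, 0.8, 0.3), zeta)
  y <- c(1, 0, 1)
  expected <- log(p[1]) + log(1 - p[2]) + log(p[3])
  expect_equal(response_loglik(traj, y, zeta), expected, tolerance = 1e-12)
  # missing trials drop out but the rest still count
  expect_equal(response_loglik(traj, c(1, NA, 1), zeta),
               log(p[1]) + log(p[3]), tolerance = 1e-12)
  expect_error(response_loglik(traj, c(1, 0), zeta),
               class = "proalhgf_length_mismatch")
})

test_that("simulated agents are reproducible and calibrated on trial one", {
  p <- hgf_params(omega2 = -4, zeta = 3)
  s1 <- simulate_agent(p, canonical_schedule(), seed = 5)
  s2 <- simulate_agent(p, canonical_schedule(), seed = 5)
  expect_identical(s1$trials, s2$trials)

  # with mu2_0 = 0 the first-trial prediction is 0.5, so the response rate
  # in match coordinates must be 0.5 whatever zeta is
  n_agents <- 200
  y1 <- vapply(seq_len(n_agents), function(i) {
    s <- simulate_agent(p, canonical_schedule(), seed = 3000 + i)
    proalhgf:::response_to_match(s$trials$cue[1], s$trials$response[1])
  }, integer(1))
  se <- sqrt(0.25 / n_agents)
  expect_lt(abs(mean(y1) - 0.5), 3 * se)
})

test_that("a near-deterministic agent exploits a learned 90/10 block", {
  sched <- proal_schedule(rep(15, 10), rep(0.9, 10), levels = 0.9)
  p <- hgf_params(omega2 = -3, zeta = 100)
  s <- simulate_agent(p, sched, seed = 11)
  y <- proalhgf:::response_to_match(s$trials$cue, s$trials$response)
  late <- y[101:150] # beliefs long converged towards u = 1
  expect_gt(mean(late), 0.9)
})
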