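test_that("negative log joint equals -loglik - logprior", {
  priors <- default_priors("hgf")
  # empty data at the prior mean: objective is the normalising constant of
  # the prior, sum of 0.5 * log(2 * pi * var)
  y_none <- rep(NA_integer_, 10)
  u <- rbinom(10, 1, 0.5)
  expect_equal(neg_log_joint(priors$free$mean, u, y_none, priors),
               sum(0.5 * log(2 * pi * priors$free$sd^2)),
               tolerance = 1e-12)

  # spot value on a 3-trial case, recomputed independently
  u3 <- c(1, 0, 1); y3 <- c(1, 1, 0)
  theta <- c(-2.5, -5.5, log(4))
  p <- hgf_params(omega2 = -2.5, omega3 = -5.5, zeta = 4)
  traj <- hgf_filter(p, u3)
  m <- pmin(pmax(traj$muhat1, 1e-4), 1 - 1e-4)
  pr <- m^4 / (m^4 + (1 - m)^4)
  ll <- log(pr[1]) + log(pr[2]) + log(1 - pr[3])
  lp <- sum(dnorm(theta, priors$free$mean, priors$free$sd, log = TRUE))
  expect_equal(neg_log_joint(theta, u3, y3, priors), -ll - lp,
               tolerance = 1e-8)

  # vague-prior limit: objective differences equal loglik differences
  vague <- priors
  vague$free$sd <- rep(1e6, 3)
  th2 <- theta + c(0.5, 0.2, -0.1)
  d_obj <- neg_log_joint(theta, u3, y3, vague) -
    neg_log_joint(th2, u3, y3, vague)
  traj2 <- hgf_filter(hgf_params(omega2 = th2[1], omega3 = th2[2],
                                 zeta = exp(th2[3])), u3)
  ll2 <- response_loglik(traj2, y3, exp(th2[3]))
  expect_equal(d_obj, -(ll - ll2), tolerance = 1e-6)

  # inadmissible regimes map to a large finite penalty, not an exception
  # (a 150-trial run at omega2 = 2 collapses the level-3 precision)
  tr150 <- generate_trials(canonical_schedule(), seed = 6)
  y150 <- rep(1L, 150)
  expect_error(hgf_filter(hgf_params(omega2 = 2), tr150$u),
               class = "proalhgf_invalid_regime")
  expect_equal(neg_log_joint(c(2, -6, log(4)), tr150$u, y150, priors), 1e10)
})

test_that("MAP fitting recovers simulated volatility on average", {
  sched <- canonical_schedule()
  n_agents <- 50
  est <- numeric(n_agents)
  for (i in seq_len(n_agents)) {
    sim <- simulate_agent(hgf_params(omega2 = -3, zeta = 5), sched,
                          seed = 5000 + i)
    y <- proalhgf:::response_to_match(sim$trials$cue, sim$trials$response)
    fit <- fit_map(sim$trials$u, y, "hgf", n_restarts = 2, seed = i)
    est[i] <- fit$params$omega2
  }
  expect_lt(abs(mean(est) + 3), 0.5)
})

test_that("fixed parameters pass through and tighter priors shrink", {
  sim <- simulate_agent(hgf_params(omega2 = -4, zeta = 3),
                        canonical_schedule(), seed = 21)
  y <- proalhgf:::response_to_match(sim$trials$cue, sim$trials$response)
  fit <- fit_map(sim$trials$u, y, "hgf", n_restarts = 3, seed = 2)
  expect_equal(fit$params$kappa, 1)
  expect_equal(fit$params$sigma2_0, 0.1)

  # shrinking every prior variance by 10 pulls the MAP towards the prior
  # mean in the prior-whitened metric (componentwise shrinkage need not
  # hold when the likelihood couples the parameters)
  tight <- default_priors("hgf")
  tight$free$sd <- tight$free$sd / sqrt(10)
  fit_t <- fit_map(sim$trials$u, y, "hgf", priors = tight,
                   n_restarts = 3, seed = 2)
  base <- default_priors("hgf")$free
  dist_w <- function(th) sum(((th - base$mean) / base$sd)^2)
  expect_lt(dist_w(fit_t$theta_est), dist_w(fit$theta_est))
})

test_that("fitting requires at least one response", {
  u <- rbinom(20, 1, 0.5)
  expect_error(fit_map(u, rep(NA_integer_, 20), "hgf"),
               class = "proalhgf_no_data")
})

test_that("Laplace evidence is exact in the conjugate Gaussian case", {
  set.seed(1)
  yv <- rnorm(5, 1.3, 0.8)
  sig2 <- 0.64; m0 <- 0; tau2 <- 2
  nlj <- function(th) {
    -sum(dnorm(yv, th, sqrt(sig2), log = TRUE)) -
      dnorm(th, m0, sqrt(tau2), log = TRUE)
  }
  opt <- optimize(nlj, c(-10, 10), tol = 1e-12)
  h <- (nlj(opt$minimum + 1e-4) - 2 * opt$objective +
          nlj(opt$minimum - 1e-4)) / 1e-8
  lap <- laplace_evidence(opt$objective, matrix(h, 1, 1))$lme
  # independent oracle: numerical quadrature of the joint
  exact <- log(integrate(function(t) {
    vapply(t, function(ti) exp(-nlj(ti)), numeric(1))
  }, -20, 20, rel.tol = 1e-12)$value)
  expect_lt(abs(lap - exact), 1e-6)
})

test_that("Laplace evidence handles the degenerate and non-PD cases", {
  # no free parameters: evidence is the log joint itself
  expect_equal(laplace_evidence(12.5)$lme, -12.5)
  # an ignored parameter with a Gaussian prior marginalises to one and
  # leaves the evidence unchanged (prior normalisation cancels the
  # occupancy penalty exactly)
  h11 <- 4.2; nlj1 <- 7.7; v <- 1
  lme1 <- laplace_evidence(nlj1, matrix(h11, 1, 1))$lme
  nlj2 <- nlj1 + 0.5 * log(2 * pi * v)
  lme2 <- laplace_evidence(nlj2, diag(c(h11, 1 / v)))$lme
  expect_equal(lme1, lme2, tolerance = 1e-12)
  # non-positive-definite Hessian is flagged, not crashed
  bad <- laplace_evidence(1, matrix(c(1, 2, 2, 1), 2, 2))
  expect_false(bad$pd)
  expect_true(is.na(bad$lme))
})

test_that("laplace_lme reproduces the evidence stored in a fit", {
  sim <- simulate_agent(hgf_params(omega2 = -4, zeta = 3),
                        canonical_schedule(), seed = 31)
  y <- proalhgf:::response_to_match(sim$trials$cue, sim$trials$response)
  fit <- fit_map(sim$trials$u, y, "hgf", n_restarts = 2, seed = 3)
  expect_equal(laplace_lme(fit), fit$lme)
  expect_true(fit$hessian_pd)
  expect_true(is.finite(fit$lme))
})

test_that("parameter recovery machinery reports per-parameter correlations", {
  truths <- make_recovery_agents(n = 10, seed = 42)
  rec <- recover_parameters(truths, canonical_schedule(), n_sims = 2,
                            seed = 6, n_restarts = 2)
  expect_named(rec$correlations, c("omega2", "omega3", "zeta"))
  expect_length(rec$excluded, 0)
  expect_gt(rec$correlations["omega2"], 0.5)
  expect_equal(dim(rec$recovered), c(10, 3))
})

test_that("averaging more simulations does not hurt recovery", {
  # paired comparison at small scale: same truths, same master seeds
  cors1 <- numeric(5); cors5 <- numeric(5)
  for (r in 1:5) {
    truths <- make_recovery_agents(n = 10, seed = 400 + r)
    cors1[r] <- recover_parameters(truths, canonical_schedule(),
                                   n_sims = 1, seed = r,
                                   n_restarts = 2)$correlations["omega2"]
    cors5[r] <- recover_parameters(truths, canonical_schedule(),
                                   n_sims = 5, seed = r,
                                   n_restarts = 2)$correlations["omega2"]
  }
  expect_gte(mean(cors5), mean(cors1) - 1e-9)
})

test_that("fit summaries flatten into the evidence table and matrix", {
  trials <- do.call(rbind, lapply(1:3, function(i) {
    s <- simulate_agent(hgf_params(omega2 = -4, zeta = 3),
                        canonical_schedule(), seed = 40 + i)
    s$trials$subject_id <- sprintf("S%02d", i)
    s$trials
  }))
  fits <- fit_all_subjects(trials, models = c("hgf", "rw"),
                           n_restarts = 2, seed = 1)
  df <- fit_summary(fits)
  expect_setequal(unique(df$model), c("hgf", "rw"))
  expect_setequal(unique(df$subject_id), c("S01", "S02", "S03"))
  L <- evidence_matrix(fits)
  expect_equal(dim(L), c(3, 2))
  expect_true(all(is.finite(L)))
  # round trip through the flat file
  f <- tempfile(fileext = ".csv")
  write_evidence(df, f)
  L2 <- evidence_from_summary(read_evidence(f))
  expect_equal(unname(L2), unname(L), tolerance = 1e-9)

  # structured per-fit record
  fj <- tempfile(fileext = ".json")
  write_fit_json(fits$S01$hgf, fj)
  rec <- jsonlite::fromJSON(fj)
  expect_equal(rec$model_id, "hgf")
  expect_equal(rec$lme, fits$S01$hgf$lme, tolerance = 1e-12)
  expect_equal(rec$params$omega2, fits$S01$hgf$params$omega2,
               tolerance = 1e-12)
})
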