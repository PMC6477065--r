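# Shared helpers: independent scalar oracles and small fixtures built in
# code. The oracles deliberately re-derive quantities with plain arithmetic
# so they stay independent of the package implementation paths they check.

# One prediction/update step of the three-level binary HGF, straight-line
# scalar arithmetic.
hgf_step_oracle <- function(u, omega2, omega3, kappa,
                            mu2, sigma2, mu3, sigma3) {
  muhat2 <- mu2
  muhat3 <- mu3
  muhat1 <- 1 / (1 + exp(-muhat2))
  pihat2 <- 1 / (sigma2 + exp(kappa * muhat3 + omega2))
  pihat3 <- 1 / (sigma3 + exp(omega3))
  delta1 <- u - muhat1
  pi2 <- pihat2 + muhat1 * (1 - muhat1)
  mu2_new <- muhat2 + delta1 / pi2
  v2 <- exp(kappa * muhat3 + omega2)
  w2 <- v2 * pihat2
  delta2 <- (1 / pi2 + (mu2_new - muhat2)^2) * pihat2 - 1
  pi3 <- pihat3 + kappa^2 / 2 * w2 * (w2 + (2 * w2 - 1) * delta2)
  mu3_new <- muhat3 + kappa / (2 * pi3) * w2 * delta2
  list(muhat1 = muhat1, pihat2 = pihat2, pihat3 = pihat3,
       delta1 = delta1, delta2 = delta2,
       mu2 = mu2_new, sigma2 = 1 / pi2, mu3 = mu3_new, sigma3 = 1 / pi3)
}

# Scalar implementation of the variational RFX-BMS recursion (loops, no
# vectorised shortcuts), used as the fixed-point oracle.
bms_recursion_oracle <- function(L, alpha0, tol = 1e-10, max_iter = 1e5) {
  n <- nrow(L); K <- ncol(L)
  alpha <- alpha0 + n / K
  for (it in seq_len(max_iter)) {
    g <- matrix(0, n, K)
    for (i in seq_len(n)) {
      lognum <- numeric(K)
      for (k in seq_len(K)) {
        lognum[k] <- L[i, k] + digamma(alpha[k]) - digamma(sum(alpha))
      }
      w <- exp(lognum - max(lognum))
      g[i, ] <- w / sum(w)
    }
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) return(list(alpha = alpha_new,
                                                       g = g))
    alpha <- alpha_new
  }
  stop("oracle recursion did not converge")
}

# A reproducible set of HGF agents spanning the volatility range used in the
# recovery studies.
make_recovery_agents <- function(n = 36, seed = 99) {
  proalhgf:::with_seed(seed, {
    lapply(seq_len(n), function(i) hgf_params(
      omega2 = seq(-9, -2, length.out = n)[i],
      omega3 = rnorm(1, -6, 0.14),
      zeta = exp(rnorm(1, log(3.16), 0.5))))
  })
}

# small cohort simulated from RW agents (for identifiability sanity)
make_rw_cohort_trials <- function(n = 36, seed = 5) {
  proalhgf:::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i) {
      p <- rw_params(alpha = plogis(rnorm(1, qlogis(0.3), 0.7)),
                     zeta = exp(rnorm(1, log(3), 0.5)))
      s <- simulate_agent(p, canonical_schedule(), seed = 700 + i)
      s$trials$subject_id <- sprintf("S%02d", i)
      s$trials
    }))
  })
}
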