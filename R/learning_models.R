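#' Numerically stable logistic sigmoid
#'
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`, computed without overflow for large `|x|`.
#' @export
sigmoid <- function(x) plogis(x)

# probability clipping used in the response likelihood
PROB_EPS <- 1e-4

#' Parameter sets for the three perceptual models
#'
#' Constructors validate and bundle the parameters of the three-level binary
#' hierarchical Gaussian filter (HGF), the Rescorla--Wagner (RW) learner and
#' the Sutton K1 (SK1) gain-adaptation learner. All three share the
#' unit-square sigmoid response model with inverse decision noise `zeta`.
#'
#' For the HGF, `omega2` and `omega3` are the tonic log-volatilities of the
#' Gaussian random walks at levels 2 (cue--outcome contingency in logit
#' space) and 3 (log-volatility of the contingency); `kappa` couples level 3
#' into the level-2 step size and is fixed during estimation.
#'
#' @param omega2,omega3 Tonic log-volatility at levels 2 and 3.
#' @param kappa Non-negative phasic coupling; fixed at 1 by default.
#' @param zeta Positive inverse decision noise.
#' @param mu2_0,sigma2_0,mu3_0,sigma3_0 Initial level-2/3 means and
#'   variances.
#' @return A parameter object of class `hgf_params`, `rw_params` or
#'   `sk1_params`.
#' @export
hgf_params <- function(omega2 = -3, omega3 = -6, kappa = 1, zeta = 48,
                       mu2_0 = 0, sigma2_0 = 0.1, mu3_0 = 1, sigma3_0 = 1) {
  if (zeta <= 0) stop_proalhgf("zeta must be positive", "proalhgf_bad_param")
  if (kappa < 0) stop_proalhgf("kappa must be non-negative",
                               "proalhgf_bad_param")
  if (sigma2_0 <= 0 || sigma3_0 <= 0) {
    stop_proalhgf("initial variances must be positive", "proalhgf_bad_param")
  }
  structure(list(omega2 = omega2, omega3 = omega3, kappa = kappa,
                 zeta = zeta, mu2_0 = mu2_0, sigma2_0 = sigma2_0,
                 mu3_0 = mu3_0, sigma3_0 = sigma3_0),
            class = "hgf_params")
}

#' @rdname hgf_params
#' @param alpha RW learning rate in (0, 1).
#' @param v0 Initial value (predicted match probability) in (0, 1).
#' @export
rw_params <- function(alpha = 0.3, v0 = 0.5, zeta = 48) {
  if (alpha <= 0 || alpha >= 1) {
    stop_proalhgf("alpha must lie in (0, 1)", "proalhgf_bad_param")
  }
  if (v0 <= 0 || v0 >= 1) {
    stop_proalhgf("v0 must lie in (0, 1)", "proalhgf_bad_param")
  }
  if (zeta <= 0) stop_proalhgf("zeta must be positive", "proalhgf_bad_param")
  structure(list(alpha = alpha, v0 = v0, zeta = zeta), class = "rw_params")
}

#' @rdname hgf_params
#' @param mu_meta Non-negative meta-learning rate of the SK1 gain update.
#' @param beta0 Initial log learning rate; `exp(beta0)` must not exceed
#'   `alpha_cap`.
#' @param alpha_cap Upper cap on the effective learning rate.
#' @export
sk1_params <- function(mu_meta = 0.05, beta0 = log(0.1), v0 = 0.5,
                       zeta = 48, alpha_cap = 1) {
  if (mu_meta < 0) stop_proalhgf("mu_meta must be non-negative",
                                 "proalhgf_bad_param")
  if (exp(beta0) > alpha_cap) {
    stop_proalhgf("exp(beta0) exceeds alpha_cap", "proalhgf_bad_param")
  }
  if (v0 <= 0 || v0 >= 1) {
    stop_proalhgf("v0 must lie in (0, 1)", "proalhgf_bad_param")
  }
  if (zeta <= 0) stop_proalhgf("zeta must be positive", "proalhgf_bad_param")
  structure(list(mu_meta = mu_meta, beta0 = beta0, v0 = v0, zeta = zeta,
                 alpha_cap = alpha_cap),
            class = "sk1_params")
}

#' Run the three-level binary HGF over a binary input sequence
#'
#' Single forward sweep of prediction and update at each trial. Per trial
#' `k`, the predictions are the previous posteriors (`muhat2 = mu2`,
#' `muhat3 = mu3`, `muhat1 = sigmoid(muhat2)`); the precision predictions
#' are `pihat2 = 1 / (sigma2 + exp(kappa * muhat3 + omega2))` and
#' `pihat3 = 1 / (sigma3 + exp(omega3))`; the level-2 posterior follows the
#' outcome prediction error `delta1 = u - muhat1`, and the level-3 posterior
#' follows the volatility prediction error `delta2`.
#'
#' @param params An [hgf_params()] object.
#' @param inputs Binary vector of match indicators `u`.
#' @return A `belief_trajectory` data frame with one row per trial and the
#'   columns `muhat1`, `mu2`, `sigma2`, `mu3`, `sigma3`, `pihat2`, `pihat3`,
#'   `delta1`, `delta2`.
#' @export
hgf_filter <- function(params, inputs) {
  stopifnot(inherits(params, "hgf_params"), all(inputs %in% c(0, 1)))
  res <- hgf_filter_core(as.numeric(inputs), params$omega2, params$omega3,
                         params$kappa, params$mu2_0, params$sigma2_0,
                         params$mu3_0, params$sigma3_0)
  if (!res$ok) {
    stop_proalhgf(
      sprintf("HGF precision became non-positive at trial %d; parameter regime inadmissible",
              res$bad_trial),
      "proalhgf_invalid_regime")
  }
  traj <- data.frame(trial = seq_along(inputs), u = as.numeric(inputs),
                     muhat1 = res$muhat1, mu2 = res$mu2, sigma2 = res$sigma2,
                     mu3 = res$mu3, sigma3 = res$sigma3,
                     pihat2 = res$pihat2, pihat3 = res$pihat3,
                     delta1 = res$delta1, delta2 = res$delta2)
  class(traj) <- c("belief_trajectory", "data.frame")
  traj
}

#' Run the Rescorla--Wagner learner
#'
#' Fixed-rate delta rule: `v(k) = v(k-1) + alpha * (u(k) - v(k-1))`. The
#' prediction track `muhat1` is the pre-update value clipped away from 0/1.
#'
#' @param params An [rw_params()] object.
#' @inheritParams hgf_filter
#' @return A `belief_trajectory` data frame with columns `muhat1`, `value`,
#'   `lr`, `delta1`.
#' @export
rw_filter <- function(params, inputs) {
  stopifnot(inherits(params, "rw_params"), all(inputs %in% c(0, 1)))
  res <- rw_filter_core(as.numeric(inputs), params$alpha, params$v0,
                        PROB_EPS)
  traj <- data.frame(trial = seq_along(inputs), u = as.numeric(inputs),
                     muhat1 = res$muhat1, value = res$value, lr = res$lr,
                     delta1 = res$delta1)
  class(traj) <- c("belief_trajectory", "data.frame")
  traj
}

#' Run the Sutton K1 gain-adaptation learner
#'
#' Single-predictor K1: the log learning rate follows the correlation of
#' successive prediction errors through the eligibility trace `h`, with the
#' effective rate capped at `alpha_cap`:
#' `beta(k) = beta(k-1) + mu_meta * delta * h(k-1)`,
#' `alpha(k) = min(exp(beta(k)), alpha_cap)`,
#' `v(k) = v(k-1) + alpha(k) * delta`,
#' `h(k) = (h(k-1) + alpha(k) * delta) * max(0, 1 - alpha(k))`, `h(0) = 0`.
#'
#' @param params An [sk1_params()] object.
#' @inheritParams hgf_filter
#' @return A `belief_trajectory` data frame with columns `muhat1`, `value`,
#'   `lr`, `delta1`, `beta`, `h`.
#' @export
sk1_filter <- function(params, inputs) {
  stopifnot(inherits(params, "sk1_params"), all(inputs %in% c(0, 1)))
  res <- sk1_filter_core(as.numeric(inputs), params$mu_meta, params$beta0,
                         params$v0, params$alpha_cap, PROB_EPS)
  traj <- data.frame(trial = seq_along(inputs), u = as.numeric(inputs),
                     muhat1 = res$muhat1, value = res$value, lr = res$lr,
                     delta1 = res$delta1, beta = res$beta, h = res$h)
  class(traj) <- c("belief_trajectory", "data.frame")
  traj
}

# Fast path used inside optimisation loops: predicted outcome probabilities
# only, no trajectory data frame. Returns NULL on inadmissible regimes.
filter_muhat1 <- function(params, inputs) {
  switch(class(params)[1],
    hgf_params = {
      res <- hgf_filter_core(inputs, params$omega2, params$omega3,
                             params$kappa, params$mu2_0, params$sigma2_0,
                             params$mu3_0, params$sigma3_0)
      if (!res$ok) NULL else res$muhat1
    },
    rw_params = rw_filter_core(inputs, params$alpha, params$v0,
                               PROB_EPS)$muhat1,
    sk1_params = sk1_filter_core(inputs, params$mu_meta, params$beta0,
                                 params$v0, params$alpha_cap,
                                 PROB_EPS)$muhat1)
}

# Log-likelihood given the prediction track directly. Log-probabilities are
# computed on the logit scale so confident wrong predictions stay finite.
loglik_muhat1 <- function(muhat1, y, zeta) {
  keep <- !is.na(y)
  if (!any(keep)) return(0)
  m <- pmin(pmax(muhat1[keep], PROB_EPS), 1 - PROB_EPS)
  x <- zeta * (log(m) - log1p(-m))
  sum(plogis(ifelse(y[keep] == 1, x, -x), log.p = TRUE))
}

# dispatch on parameter class
filter_model <- function(params, inputs) {
  switch(class(params)[1],
         hgf_params = hgf_filter(params, inputs),
         rw_params  = rw_filter(params, inputs),
         sk1_params = sk1_filter(params, inputs),
         stop_proalhgf("unknown model parameter class",
                       "proalhgf_bad_param"))
}

#' Unit-square sigmoid response model
#'
#' Maps the predicted match probability `muhat1` to the probability of
#' responding "match" under inverse decision noise `zeta`:
#' `p(y = 1) = muhat1^zeta / (muhat1^zeta + (1 - muhat1)^zeta)`. Computed on
#' the log scale for numerical stability at large `zeta`.
#'
#' @param muhat1 Predicted probability in (0, 1); vectorised.
#' @param zeta Positive inverse decision noise. `zeta = 1` is probability
#'   matching; large `zeta` approaches deterministic maximising.
#' @return Response probabilities.
#' @export
response_prob <- function(muhat1, zeta) {
  if (zeta <= 0) stop_proalhgf("zeta must be positive", "proalhgf_bad_param")
  stopifnot(all(muhat1 > 0 & muhat1 < 1))
  # logit(p) = zeta * (log(muhat1) - log(1 - muhat1))
  plogis(zeta * (log(muhat1) - log1p(-muhat1)))
}

#' Log-likelihood of binary responses under a belief trajectory
#'
#' Sums `log p(y(k))` over non-missing trials, with `muhat1` clipped to
#' `[1e-4, 1 - 1e-4]`. Missing responses contribute nothing to the
#' likelihood; the beliefs they sit on were still updated by the inputs.
#'
#' @param trajectory A `belief_trajectory` (needs a `muhat1` column).
#' @param y Binary responses in match coordinates (1 = responded with the
#'   outcome the reference association predicts), `NA` = missing.
#' @param zeta Positive inverse decision noise.
#' @return Scalar log-likelihood.
#' @export
response_loglik <- function(trajectory, y, zeta) {
  muhat1 <- trajectory$muhat1
  if (length(muhat1) != length(y)) {
    stop_proalhgf("trajectory and responses have different lengths",
                  "proalhgf_length_mismatch")
  }
  if (zeta <= 0) stop_proalhgf("zeta must be positive", "proalhgf_bad_param")
  loglik_muhat1(muhat1, y, zeta)
}

# Map a categorical response to the match coordinate y (same convention as
# the input u), and back.
response_to_match <- function(cue, response) {
  ifelse(is.na(response), NA_integer_, match_indicator(cue, response))
}

match_to_response <- function(cue, y) {
  ifelse(is.na(y), NA_character_,
         ifelse(y == 1L,
                ifelse(cue == "high_tone", "female", "male"),
                ifelse(cue == "high_tone", "male", "female")))
}

#' Simulate an artificial agent performing the ProAL task
#'
#' Generates a session from the schedule, filters the inputs through the
#' requested perceptual model, and samples a response on every trial from
#' the unit-square sigmoid response model.
#'
#' @param params A parameter object ([hgf_params()], [rw_params()] or
#'   [sk1_params()]); its class selects the model.
#' @param schedule A [proal_schedule()].
#' @param seed Integer seed; trials and responses are both reproducible.
#' @return A list with `trials` (responses filled in, `correct` computed)
#'   and `trajectory`.
#' @export
simulate_agent <- function(params, schedule, seed = NULL) {
  trials <- generate_trials(schedule, seed = if (is.null(seed)) NULL else
    derive_seed(seed, 1L))
  traj <- filter_model(params, trials$u)
  m <- pmin(pmax(traj$muhat1, PROB_EPS), 1 - PROB_EPS)
  p1 <- response_prob(m, params$zeta)
  y <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 2L),
                 rbinom(length(p1), 1L, p1))
  trials$response <- match_to_response(trials$cue, y)
  trials$correct <- trials$response == trials$outcome
  list(trials = trials, trajectory = traj)
}

#' Write a belief trajectory as delimited text
#'
#' @param trajectory A `belief_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
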