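#' Configuration for the synthetic cohort generator
#'
#' Bundles the marginal moments, score ranges, latent correlation targets
#' and generative regression structure of the emulated study population:
#' young adults who completed a 150-trial ProAL session, the Verbal Abuse
#' Questionnaire (VAQ; 15 items per developmental period, each 0--8), the
#' Resilience Appraisal Scale (RAS; three 4-item subscales, items 1--5) and
#' the state/trait anxiety inventories (20 items each, 1--4, totals 20--80).
#'
#' The emotion-coping subscale is generated from a linear model on the
#' log-transformed preschool VAQ score and the HGF level-2 log-volatility
#' `omega2` plus Gaussian noise, then rounded and clipped to its scale; the
#' remaining scores come from a latent Gaussian copula whose off-diagonal
#' entries are calibrated so the stated correlations hold on the observed
#' score scale. Raw VAQ period scores are zero-inflated lognormal before
#' integer clipping, reproducing the strong right skew of self-reported
#' abuse scores.
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed.
#' @param simple_coefs Generative coefficients (intercept, transformed
#'   preschool VAQ, omega2) of the emotion-coping model.
#' @param simple_resid_sd Residual SD of the emotion-coping model.
#' @param corr_targets Data frame (`var1`, `var2`, `rho`) of observed-scale
#'   correlation targets among the copula-generated columns.
#' @param p_male Probability of a male subject.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 36, seed = 1,
                          simple_coefs = c(15.072, -0.891, -0.282),
                          simple_resid_sd = 2.281,
                          corr_targets = data.frame(
                            var1 = c("omega2", "omega2"),
                            var2 = c("vaq_childhood", "vaq_adolescent"),
                            rho = c(-0.379, -0.448),
                            stringsAsFactors = FALSE),
                          p_male = 23 / 36) {
  zeta_mean <- 3.16; zeta_sd <- 1.94
  zeta_sdlog <- sqrt(log(1 + (zeta_sd / zeta_mean)^2))
  structure(list(
    n_subjects = n_subjects,
    seed = seed,
    moments = list(
      age = list(mean = 23.42, sd = 4.10, min = 18, max = 45),
      ras_social = list(mean = 17.06, sd = 2.10, min = 4, max = 20),
      ras_situation = list(mean = 16.36, sd = 2.10, min = 4, max = 20),
      stai_s = list(mean = 35.83, sd = 9.19, min = 20, max = 80),
      stai_t = list(mean = 36.00, sd = 9.63, min = 20, max = 80),
      # truncated to the admissible regime of the binary HGF on this task:
      # above roughly -1.5 the level-3 precision can turn negative
      omega2 = list(mean = -5.46, sd = 2.82, lower = -14, upper = -1.5),
      omega3 = list(mean = -6.06, sd = 0.14),
      zeta = list(meanlog = log(zeta_mean) - zeta_sdlog^2 / 2,
                  sdlog = zeta_sdlog)),
    vaq = list(
      preschool = list(p_zero = 0.25, meanlog = 1.5, sdlog = 1.1),
      childhood = list(p_zero = 0.15, meanlog = 2.36, sdlog = 0.95),
      adolescent = list(p_zero = 0.10, meanlog = 2.40, sdlog = 0.85)),
    items = list(vaq = list(n = 15, min = 0, max = 8),
                 ras = list(n_per_subscale = 4, min = 1, max = 5),
                 stai = list(n = 20, min = 1, max = 4)),
    corr_targets = corr_targets,
    simple_coefs = simple_coefs,
    simple_resid_sd = simple_resid_sd,
    p_male = p_male), class = "cohort_config")
}

# Marginal quantile functions on the observed score scale, used both for
# generation and for calibrating latent copula correlations.
vaq_quantile <- function(u, spec) {
  x <- qlnorm(pmax((u - spec$p_zero) / (1 - spec$p_zero), 0),
              spec$meanlog, spec$sdlog)
  # the positive branch is kept at >= 1 so the zero mass is exactly the
  # configured inflation weight
  ifelse(u < spec$p_zero, 0, pmin(pmax(round(x), 1), 120))
}

gauss_quantile <- function(u, m) {
  x <- qnorm(u, m$mean, m$sd)
  if (!is.null(m$min)) x <- pmin(pmax(x, m$min), m$max)
  x
}

# mean and sd of a normal(mu, sigma) truncated to [lo, hi]
trunc_normal_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  mean <- mu + sigma * (dnorm(a) - dnorm(b)) / Z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                    ((dnorm(a) - dnorm(b)) / Z)^2)
  c(mean = mean, sd = sqrt(v))
}

# underlying (mu, sigma) such that the truncated normal realises the target
# observed moments
solve_trunc_normal <- function(target_mean, target_sd, lo, hi) {
  obj <- function(th) {
    mo <- trunc_normal_moments(th[1], exp(th[2]), lo, hi)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  opt <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  list(mu = opt$par[1], sigma = exp(opt$par[2]))
}

# normal truncated to [lower, upper] with *observed* moments (mean, sd):
# continuous, no boundary point mass
trunc_gauss_quantile <- function(u, m) {
  s <- solve_trunc_normal(m$mean, m$sd, m$lower, m$upper)
  pa <- pnorm(m$lower, s$mu, s$sigma)
  pb <- pnorm(m$upper, s$mu, s$sigma)
  qnorm(pa + u * (pb - pa), s$mu, s$sigma)
}

# Calibrate the latent normal correlation so that the observed-scale Pearson
# correlation of the two transformed margins hits `target`. Uses a
# fixed-seed Monte Carlo estimate of the (approximately linear) attenuation
# factor of the Gaussian copula under the two marginal transforms.
calibrate_latent_rho <- function(target, qf1, qf2, n_mc = 1e5) {
  if (target == 0) return(0)
  with_seed(90210L, {
    z1 <- rnorm(n_mc)
    e <- rnorm(n_mc)
    x1 <- qf1(pnorm(z1))
    r_obs <- function(rho) {
      z2 <- rho * z1 + sqrt(1 - rho^2) * e
      cor(x1, qf2(pnorm(z2)))
    }
    # fixed-point iteration on the multiplicative attenuation, common
    # random numbers keep the map smooth
    rho <- max(min(target, 0.99), -0.99)
    for (it in 1:4) {
      r <- r_obs(rho)
      if (abs(r) < 1e-10) break
      rho <- max(min(rho * target / r, 0.99), -0.99)
    }
    rho
  })
}

# Random composition of `total` into `k` item scores each in [lo, hi].
partition_total <- function(total, k, lo, hi) {
  total <- as.integer(round(total))
  stopifnot(total >= k * lo, total <= k * hi)
  out <- integer(k)
  remaining <- total
  for (i in seq_len(k)) {
    left <- k - i
    a <- as.integer(max(lo, remaining - left * hi))
    b <- as.integer(min(hi, remaining - left * lo))
    out[i] <- if (a == b) a else sample(seq.int(a, b), 1L)
    remaining <- remaining - out[i]
  }
  sample(out) # shuffle so early items are not systematically larger
}

#' Generate a synthetic questionnaire-plus-parameters cohort
#'
#' Draws per-subject questionnaire scores and learning-model parameters with
#' the configured correlation structure (latent Gaussian copula), generates
#' the emotion-coping subscale from the configured linear model, and
#' partitions every total into item-level scores on the instrument scales.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (data frame, one row per subject), `agents`
#'   (per-subject HGF parameters), `items` (list of item-score matrices) and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  m <- config$moments
  # copula variables, in order
  vars <- c("age", "vaq_preschool", "vaq_childhood", "vaq_adolescent",
            "ras_social", "ras_situation", "stai_s", "stai_t",
            "omega2", "omega3", "zeta", "gender")
  qfs <- list(
    age = function(u) gauss_quantile(u, m$age),
    vaq_preschool = function(u) vaq_quantile(u, config$vaq$preschool),
    vaq_childhood = function(u) vaq_quantile(u, config$vaq$childhood),
    vaq_adolescent = function(u) vaq_quantile(u, config$vaq$adolescent),
    ras_social = function(u) pmin(pmax(round(qnorm(u, m$ras_social$mean,
                                                   m$ras_social$sd)), 4), 20),
    ras_situation = function(u) pmin(pmax(round(qnorm(u, m$ras_situation$mean,
                                                      m$ras_situation$sd)),
                                          4), 20),
    stai_s = function(u) pmin(pmax(round(qnorm(u, m$stai_s$mean,
                                               m$stai_s$sd)), 20), 80),
    stai_t = function(u) pmin(pmax(round(qnorm(u, m$stai_t$mean,
                                               m$stai_t$sd)), 20), 80),
    omega2 = function(u) trunc_gauss_quantile(u, m$omega2),
    omega3 = function(u) qnorm(u, m$omega3$mean, m$omega3$sd),
    zeta = function(u) qlnorm(u, m$zeta$meanlog, m$zeta$sdlog),
    gender = function(u) ifelse(u < config$p_male, 1, 0))
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  ct <- config$corr_targets
  if (nrow(ct)) for (i in seq_len(nrow(ct))) {
    v1 <- ct$var1[i]; v2 <- ct$var2[i]
    stopifnot(v1 %in% vars, v2 %in% vars)
    rho_z <- calibrate_latent_rho(ct$rho[i], qfs[[v1]], qfs[[v2]])
    R[v1, v2] <- R[v2, v1] <- rho_z
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dimnames(R) <- list(vars, vars)
    if (min(eigen(R, symmetric = TRUE,
                  only.values = TRUE)$values) < 1e-10) {
      stop_proalhgf("correlation target matrix infeasible after repair",
                    "proalhgf_bad_corr")
    }
  }
  with_seed(derive_seed(config$seed, 1L), {
    Z <- matrix(rnorm(n * length(vars)), n) %*% chol(R)
    colnames(Z) <- vars
    U <- pnorm(Z)
    cohort <- as.data.frame(lapply(vars, function(v) qfs[[v]](U[, v])))
    names(cohort) <- vars
    cohort$gender <- ifelse(cohort$gender == 1, "male", "female")
    # transformed preschool score used as the generative predictor
    # (log rung of the power ladder with the +1 offset)
    cohort$vaq_preschool_t <- log(cohort$vaq_preschool + 1)
    b <- config$simple_coefs
    lin <- b[1] + b[2] * cohort$vaq_preschool_t + b[3] * cohort$omega2
    cohort$ras_emotion <- pmin(pmax(
      round(lin + rnorm(n, 0, config$simple_resid_sd)), 4), 20)
    cohort$ras_total <- cohort$ras_emotion + cohort$ras_social +
      cohort$ras_situation
    cohort <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), cohort,
                         stringsAsFactors = FALSE)
    it <- config$items
    part_rows <- function(tot, k, lo, hi) {
      t(vapply(tot, partition_total, integer(k), k = k, lo = lo, hi = hi))
    }
    items <- list(
      vaq_preschool = part_rows(cohort$vaq_preschool, it$vaq$n,
                                it$vaq$min, it$vaq$max),
      vaq_childhood = part_rows(cohort$vaq_childhood, it$vaq$n,
                                it$vaq$min, it$vaq$max),
      vaq_adolescent = part_rows(cohort$vaq_adolescent, it$vaq$n,
                                 it$vaq$min, it$vaq$max),
      ras = cbind(
        part_rows(cohort$ras_emotion, it$ras$n_per_subscale,
                  it$ras$min, it$ras$max),
        part_rows(cohort$ras_situation, it$ras$n_per_subscale,
                  it$ras$min, it$ras$max),
        part_rows(cohort$ras_social, it$ras$n_per_subscale,
                  it$ras$min, it$ras$max)),
      stai_s = part_rows(cohort$stai_s, it$stai$n, it$stai$min,
                         it$stai$max),
      stai_t = part_rows(cohort$stai_t, it$stai$n, it$stai$min,
                         it$stai$max))
    agents <- data.frame(subject_id = cohort$subject_id,
                         omega2 = cohort$omega2, omega3 = cohort$omega3,
                         zeta = cohort$zeta, stringsAsFactors = FALSE)
    list(cohort = cohort, agents = agents, items = items, config = config)
  })
}

#' Simulate ProAL behaviour for a cohort of HGF agents
#'
#' One session per subject on the given schedule, each agent parameterised
#' by its row of `agents`.
#'
#' @param agents Data frame with columns `subject_id`, `omega2`, `omega3`,
#'   `zeta`.
#' @param schedule A [proal_schedule()].
#' @param seed Master seed (per-subject seeds derived from it).
#' @return List with `trials` (stacked trial table, `subject_id` column) and
#'   `sessions` (per-subject list of `trials`/`trajectory`).
#' @export
generate_behavior <- function(agents, schedule = canonical_schedule(),
                              seed = 1) {
  sessions <- lapply(seq_len(nrow(agents)), function(i) {
    params <- hgf_params(omega2 = agents$omega2[i],
                         omega3 = agents$omega3[i],
                         zeta = agents$zeta[i])
    # near the admissibility boundary a rare input sequence can still break
    # the filter; such a subject is given a fresh session (new seed)
    sim <- NULL
    for (try in 1:5) {
      sim <- tryCatch(
        simulate_agent(params, schedule,
                       seed = derive_seed(seed, 101L * i + 1000000L * (try - 1L))),
        proalhgf_invalid_regime = function(e) NULL)
      if (!is.null(sim)) break
    }
    if (is.null(sim)) {
      stop_proalhgf(
        sprintf("agent %s inadmissible on this schedule (omega2 = %.2f)",
                agents$subject_id[i], agents$omega2[i]),
        "proalhgf_invalid_regime")
    }
    sim$trials$subject_id <- agents$subject_id[i]
    sim
  })
  names(sessions) <- agents$subject_id
  trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  rownames(trials) <- NULL
  list(trials = trials, sessions = sessions)
}

# stable fingerprint of a config for the manifest
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a complete synthetic dataset bundle
#'
#' Generates the cohort and its trial-level behaviour and writes
#' `cohort.csv`, `agents.csv`, `trials.csv`, `schedule.csv` and
#' `manifest.yaml` (seeds, config, config hash, generator version) to
#' `outdir`. The manifest is sufficient to regenerate the bundle
#' byte-for-byte.
#'
#' @param config A [cohort_config()].
#' @param outdir Output directory (created if absent).
#' @param schedule Session schedule (default canonical).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
end_to_end_dataset <- function(config = cohort_config(), outdir,
                               schedule = canonical_schedule()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_cohort(config)
  beh <- generate_behavior(gen$agents, schedule,
                           seed = derive_seed(config$seed, 2L))
  paths <- list(cohort = file.path(outdir, "cohort.csv"),
                agents = file.path(outdir, "agents.csv"),
                trials = file.path(outdir, "trials.csv"),
                schedule = file.path(outdir, "schedule.csv"),
                manifest = file.path(outdir, "manifest.yaml"))
  write.csv(gen$cohort, paths$cohort, row.names = FALSE)
  write.csv(gen$agents, paths$agents, row.names = FALSE)
  write_trials(beh$trials, paths$trials)
  write_schedule(schedule, paths$schedule)
  manifest <- list(
    generator = "proalhgf",
    generator_version = as.character(utils::packageVersion("proalhgf")),
    master_seed = config$seed,
    config_hash = config_hash(config),
    # full-precision JSON so regeneration reproduces doubles bit-for-bit
    config_json = as.character(jsonlite::toJSON(unclass(config),
                                                auto_unbox = TRUE,
                                                digits = NA)))
  yaml::write_yaml(manifest, paths$manifest)
  invisible(list(cohort = gen$cohort, agents = gen$agents,
                 items = gen$items, behavior = beh, schedule = schedule,
                 paths = paths, manifest = manifest))
}

#' Regenerate a dataset bundle from its manifest
#'
#' @param manifest_path Path to a `manifest.yaml` written by
#'   [end_to_end_dataset()].
#' @param outdir Output directory for the regenerated files.
#' @return Invisibly, the regenerated bundle (see [end_to_end_dataset()]).
#' @export
regenerate_from_manifest <- function(manifest_path, outdir) {
  man <- yaml::read_yaml(manifest_path)
  cfg <- jsonlite::fromJSON(man$config_json)
  config <- cohort_config(
    n_subjects = cfg$n_subjects, seed = cfg$seed,
    simple_coefs = unlist(cfg$simple_coefs),
    simple_resid_sd = cfg$simple_resid_sd,
    corr_targets = as.data.frame(cfg$corr_targets,
                                 stringsAsFactors = FALSE),
    p_male = cfg$p_male)
  end_to_end_dataset(config, outdir)
}
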