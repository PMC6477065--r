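#' Per-variable distribution summary
#'
#' Mean, sample SD, median, min, max, adjusted Fisher--Pearson skewness and
#' excess kurtosis (both the bias-adjusted sample versions) for each numeric
#' variable. A constant variable gets `NA` skewness/kurtosis rather than an
#' error.
#'
#' @param table Data frame.
#' @param vars Character vector of variables (defaults to all numeric
#'   columns).
#' @return Data frame with one row per variable.
#' @export
summarize_cohort <- function(table, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  rows <- lapply(vars, function(v) {
    x <- table[[v]]
    x <- x[!is.na(x)]
    stopifnot(length(x) >= 3)
    constant <- sd(x) == 0
    data.frame(
      variable = v, mean = mean(x), sd = sd(x), median = median(x),
      min = min(x), max = max(x),
      skewness = if (constant) NA_real_ else e1071::skewness(x, type = 2),
      # the bias-adjusted kurtosis needs at least 4 observations
      kurtosis = if (constant || length(x) < 4) NA_real_ else
        e1071::kurtosis(x, type = 2),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tukey ladder-of-powers transformation
#'
#' Picks the rung of the ladder `{-2, -1, -1/2, 0 (log), 1/3, 1/2, 1, 2}`
#' that minimises the absolute sample skewness of the transformed variable.
#' When `min(x) <= 0` an offset of `+1` is applied before all rungs. Ties
#' are broken towards the lambda closest to 1 (the identity).
#'
#' @param x Numeric vector, at least 5 observations.
#' @return List with `x_transformed`, `lambda` and `offset`.
#' @export
tukey_ladder <- function(x) {
  stopifnot(length(x[!is.na(x)]) >= 5)
  ladder <- c(-2, -1, -0.5, 0, 1 / 3, 0.5, 1, 2)
  offset <- if (min(x, na.rm = TRUE) <= 0) 1 else 0
  transform_rung <- function(lambda) {
    z <- x + offset
    if (lambda == 0) log(z) else z^lambda
  }
  skews <- vapply(ladder, function(l) {
    xt <- suppressWarnings(transform_rung(l)) # NaN rungs are dropped below
    if (any(!is.finite(xt[!is.na(xt)]))) return(Inf)
    s <- e1071::skewness(xt, type = 2, na.rm = TRUE)
    if (is.na(s)) Inf else abs(s)
  }, numeric(1))
  best <- min(skews)
  cand <- which(skews <= best + 1e-12)
  lambda <- ladder[cand[which.min(abs(ladder[cand] - 1))]]
  list(x_transformed = transform_rung(lambda), lambda = lambda,
       offset = offset)
}

#' Pearson correlation matrix with p values
#'
#' Pairwise-complete Pearson correlations and two-sided p values from the
#' t reference distribution with `n - 2` degrees of freedom. A zero-variance
#' variable yields `NA` in its row and column.
#'
#' @param table Data frame.
#' @param vars Variables to correlate (default: all numeric columns).
#' @return List with matrices `r`, `p` and `n` (pairwise complete cases).
#' @export
pearson_matrix <- function(table, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  X <- as.matrix(table[, vars, drop = FALSE])
  k <- length(vars)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- r
  nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cc <- stats::complete.cases(X[, i], X[, j])
    n <- sum(cc)
    nmat[i, j] <- n
    if (n < 3 || sd(X[cc, i]) == 0 || sd(X[cc, j]) == 0) next
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    rij <- cor(X[cc, i], X[cc, j])
    r[i, j] <- rij
    tstat <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- 2 * pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p, n = nmat)
}

#' Variance inflation factors
#'
#' For each predictor in the model, `VIF = 1 / (1 - R^2)` of the regression
#' of that predictor on all the others. Exactly collinear predictors are
#' flagged with `Inf`.
#'
#' @param table Data frame.
#' @param formula Model formula; only the right-hand side is used.
#' @return Named vector of VIFs, one per model-matrix column.
#' @export
vif_table <- function(table, formula) {
  mf <- model.frame(formula, table)
  X <- model.matrix(formula, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  stopifnot(ncol(X) >= 2)
  vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (1 - r2 < 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

# Shared OLS reporting: estimates, t-based 95% CIs, adjusted R^2, residual
# SE, overall F test.
ols_report <- function(formula, data, label) {
  mf <- model.frame(formula, data)
  fit <- lm(formula, data = mf)
  mm <- model.matrix(formula, mf)
  if (fit$rank < ncol(mm)) {
    aliased <- colnames(mm)[is.na(coef(fit))]
    stop_proalhgf(
      sprintf("rank-deficient fit in model '%s': aliased term(s) %s",
              label, paste(aliased, collapse = ", ")),
      "proalhgf_rank_deficient")
  }
  s <- summary(fit)
  ci <- confint(fit, level = 0.95)
  terms_df <- data.frame(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, 1],
    ci_low = ci[, 1], ci_high = ci[, 2],
    p = s$coefficients[, 4],
    row.names = NULL, stringsAsFactors = FALSE)
  fstat <- s$fstatistic
  structure(list(
    label = label, formula = formula, terms = terms_df,
    adj_r2 = s$adj.r.squared, sigma = s$sigma,
    df_residual = fit$df.residual,
    f_value = unname(fstat[1]),
    f_df = unname(fstat[2:3]),
    f_p = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = nrow(mf), fit = fit), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$label, deparse(x$formula)))
  print(transform(x$terms, estimate = round(estimate, 3),
                  ci_low = round(ci_low, 3), ci_high = round(ci_high, 3),
                  p = signif(p, 3)))
  cat(sprintf(
    "adj R2 = %.3f, residual SE = %.3f (df = %d), F(%d, %d) = %.3f, p = %.4f\n",
    x$adj_r2, x$sigma, x$df_residual, x$f_df[1], x$f_df[2], x$f_value,
    x$f_p))
  if (!is.null(x$q2)) cat(sprintf("LOOCV Q2 = %.3f\n", x$q2))
  invisible(x)
}

#' The four regression models for resilience appraisal
#'
#' Ordinary least squares for the named model suite predicting a resilience
#' score from the transformed preschool verbal-abuse score and the HGF
#' level-2 log-volatility:
#' Simple (`outcome ~ vaq + omega2`), Full (adds the interaction),
#' Partial-with-omega2 (`outcome ~ omega2 + vaq:omega2`) and
#' Partial-with-VAQ (`outcome ~ vaq + vaq:omega2`). Each report carries the
#' LOOCV prediction score Q2.
#'
#' @param table Data frame (complete cases used).
#' @param outcome Name of the outcome column.
#' @param vaq Name of the transformed preschool VAQ column.
#' @param omega2 Name of the level-2 log-volatility column.
#' @return Named list of `regression_report`s:
#'   `simple`, `full`, `partial_omega2`, `partial_vaq`.
#' @export
fit_linear_models <- function(table, outcome = "ras_emotion",
                              vaq = "vaq_preschool_t", omega2 = "omega2") {
  dat <- table[stats::complete.cases(table[, c(outcome, vaq, omega2)]), ]
  f <- function(rhs) stats::as.formula(paste(outcome, "~", rhs))
  specs <- list(
    simple = f(paste(vaq, "+", omega2)),
    full = f(paste0(vaq, " + ", omega2, " + ", vaq, ":", omega2)),
    partial_omega2 = f(paste0(omega2, " + ", vaq, ":", omega2)),
    partial_vaq = f(paste0(vaq, " + ", vaq, ":", omega2)))
  reports <- mapply(function(fm, lbl) {
    rep <- ols_report(fm, dat, lbl)
    rep$q2 <- loocv_q2(dat, fm)
    rep
  }, specs, names(specs), SIMPLIFY = FALSE)
  reports
}

#' Leave-one-out cross-validated prediction score
#'
#' `Q2 = 1 - sum((y_i - yhat_(-i))^2) / sum((y_i - mean(y))^2)`, with each
#' `yhat_(-i)` predicted from a refit excluding observation `i`.
#'
#' @param table Data frame.
#' @param formula Regression formula.
#' @return Scalar Q2 (at most 1; negative when the model predicts worse
#'   than the mean).
#' @export
loocv_q2 <- function(table, formula) {
  mf <- model.frame(formula, table)
  y <- stats::model.response(mf)
  n <- nrow(mf)
  p <- ncol(model.matrix(formula, mf))
  stopifnot(n >= p + 3)
  press <- 0
  for (i in seq_len(n)) {
    fit <- lm(formula, data = mf[-i, , drop = FALSE])
    if (any(is.na(coef(fit)))) {
      stop_proalhgf(sprintf("rank-deficient fold when leaving out row %d", i),
                    "proalhgf_rank_deficient")
    }
    pred <- stats::predict(fit, newdata = mf[i, , drop = FALSE])
    press <- press + (y[i] - pred)^2
  }
  unname(1 - press / sum((y - mean(y))^2))
}

# EBIC for one nodewise regression path.
ebic_path <- function(fit, n, p_other, gamma) {
  df <- fit$df # nonzero coefficients, intercept excluded
  dev <- if (inherits(fit, "elnet")) {
    # gaussian: -2 loglik up to constants = n * log(RSS / n)
    n * log(pmax((1 - fit$dev.ratio) * fit$nulldev / n, 1e-12))
  } else {
    # binomial: deviance
    (1 - fit$dev.ratio) * fit$nulldev
  }
  dev + df * log(n) + 2 * gamma * df * log(p_other)
}

#' Mixed graphical model by nodewise penalised regression
#'
#' Estimates a pairwise graphical model over mixed continuous/binary
#' variables: each node is regressed on all the others with an L1 penalty
#' (linear response for continuous nodes, logistic for binary nodes) over a
#' log-spaced lambda path, the per-node lambda is selected by the Extended
#' Bayesian Information Criterion, and an edge is kept only when both
#' directed coefficients are nonzero (AND rule). The edge weight is the
#' signed mean of the two coefficients on the standardised scale, set to 0
#' if their signs conflict. Continuous nodes are standardised internally;
#' binary nodes must be coded 0/1.
#'
#' @param table Data frame of node variables.
#' @param types Character vector per column: `"g"` (continuous Gaussian) or
#'   `"c"` (binary). Default: columns with exactly two distinct values are
#'   binary, the rest continuous.
#' @param n_lambda Path length.
#' @param lambda_min_ratio Smallest lambda as a fraction of the per-node
#'   lambda_max.
#' @param ebic_gamma EBIC gamma (0 = plain BIC).
#' @return An `mgm_fit`: list with `adjacency` (symmetric weighted matrix,
#'   zero diagonal), `edges` (data frame), `lambda` (selected per node) and
#'   `types`.
#' @export
fit_mgm <- function(table, types = NULL, n_lambda = 50,
                    lambda_min_ratio = 1e-3, ebic_gamma = 0.25) {
  stopifnot(ncol(table) >= 3)
  nodes <- names(table)
  X0 <- as.data.frame(table)
  if (is.null(types)) {
    types <- vapply(X0, function(x)
      if (length(unique(x[!is.na(x)])) == 2) "c" else "g", character(1))
  }
  for (v in nodes) {
    x <- X0[[v]]
    if (types[[match(v, nodes)]] == "c") {
      u <- sort(unique(x))
      if (!all(u %in% c(0, 1))) {
        if (length(u) != 2) {
          stop_proalhgf(sprintf("binary node '%s' has %d levels", v,
                                length(u)),
                        "proalhgf_bad_node")
        }
        x <- as.numeric(x == u[2])
      }
      X0[[v]] <- x
    }
    if (sd(X0[[v]]) == 0) {
      stop_proalhgf(sprintf("node '%s' has zero variance", v),
                    "proalhgf_bad_node")
    }
  }
  n <- nrow(X0)
  p <- length(nodes)
  # standardised predictor matrix; responses keep their own scale rules
  Xs <- as.matrix(as.data.frame(lapply(X0, function(x) {
    as.numeric(scale(x))
  })))
  colnames(Xs) <- nodes
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  lambda_sel <- setNames(numeric(p), nodes)
  for (j in seq_len(p)) {
    yj <- if (types[j] == "c") X0[[j]] else as.numeric(scale(X0[[j]]))
    fam <- if (types[j] == "c") "binomial" else "gaussian"
    Xj <- Xs[, -j, drop = FALSE]
    fit <- glmnet::glmnet(Xj, yj, family = fam, nlambda = n_lambda,
                          lambda.min.ratio = lambda_min_ratio,
                          standardize = FALSE)
    crit <- ebic_path(fit, n, p - 1, ebic_gamma)
    k <- which.min(crit)
    lambda_sel[j] <- fit$lambda[k]
    beta <- as.numeric(fit$beta[, k])
    B[j, -j] <- beta
  }
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  edges <- list()
  for (i in seq_len(p - 1)) for (j in seq.int(i + 1, p)) {
    b_ij <- B[i, j]; b_ji <- B[j, i]
    if (b_ij != 0 && b_ji != 0) {
      w <- if (sign(b_ij) == sign(b_ji)) mean(c(b_ij, b_ji)) else 0
      A[i, j] <- A[j, i] <- w
      if (w != 0) {
        edges[[length(edges) + 1L]] <-
          data.frame(node1 = nodes[i], node2 = nodes[j], weight = w,
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    adjacency = A,
    edges = if (length(edges)) do.call(rbind, edges) else
      data.frame(node1 = character(), node2 = character(),
                 weight = numeric()),
    lambda = lambda_sel, types = setNames(types, nodes), n = n),
    class = "mgm_fit")
}

#' @export
print.mgm_fit <- function(x, ...) {
  cat(sprintf("Mixed graphical model: %d nodes, %d edges\n",
              nrow(x$adjacency), nrow(x$edges)))
  if (nrow(x$edges)) print(transform(x$edges, weight = round(weight, 3)))
  invisible(x)
}

#' Simple-model coefficient recovery simulation
#'
#' Simulates repeated small cohorts from a two-predictor linear model with
#' independent Gaussian predictors and Gaussian noise, refits by OLS each
#' time, and averages the estimates. Used to check that the regression
#' machinery recovers a published coefficient set at the study's sample
#' size.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param n Subjects per cohort.
#' @param coefs Length-3 generative coefficients: intercept and the two
#'   predictor slopes.
#' @param resid_sd Generative residual standard deviation.
#' @param pred_means,pred_sds Length-2 moments of the two predictors.
#' @param seed Integer seed.
#' @return List with `mean_coefs` (named: intercept, x1, x2),
#'   `mean_sigma` (mean refitted residual SE) and the per-cohort `estimates`
#'   matrix.
#' @export
simulate_regression_recovery <- function(n_cohorts = 500, n = 36,
                                         coefs = c(15.072, -0.891, -0.282),
                                         resid_sd = 2.281,
                                         pred_means = c(1.31, -5.46),
                                         pred_sds = c(0.98, 2.82),
                                         seed = 1) {
  est <- matrix(NA_real_, n_cohorts, 4,
                dimnames = list(NULL, c("intercept", "x1", "x2", "sigma")))
  with_seed(seed, {
    for (b in seq_len(n_cohorts)) {
      x1 <- rnorm(n, pred_means[1], pred_sds[1])
      x2 <- rnorm(n, pred_means[2], pred_sds[2])
      y <- coefs[1] + coefs[2] * x1 + coefs[3] * x2 + rnorm(n, 0, resid_sd)
      fit <- lm(y ~ x1 + x2)
      est[b, 1:3] <- coef(fit)
      est[b, 4] <- summary(fit)$sigma
    }
  })
  list(mean_coefs = colMeans(est[, 1:3]), mean_sigma = mean(est[, 4]),
       estimates = est)
}
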