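test_that("summaries report the standard sample moments", {
  d <- data.frame(x = c(1, 2, 3), k = c(5, 5, 5))
  s <- summarize_cohort(d)
  xr <- s[s$variable == "x", ]
  expect_equal(xr$mean, 2)
  expect_equal(xr$sd, 1)
  expect_equal(xr$median, 2)
  expect_equal(xr$skewness, 0)
  # constant variable: undefined markers, no exception
  kr <- s[s$variable == "k", ]
  expect_true(is.na(kr$skewness) && is.na(kr$kurtosis))

  set.seed(1)
  z <- rnorm(1e5)
  sz <- summarize_cohort(data.frame(z = z))
  se_kurt <- sqrt(24 / 1e5)
  expect_lt(abs(sz$kurtosis), 3 * se_kurt) # excess kurtosis near 0
})

test_that("the power ladder picks the log for lognormal data and identity for symmetric data", {
  set.seed(2)
  x <- exp(rnorm(1000))
  tl <- tukey_ladder(x)
  expect_equal(tl$lambda, 0)
  expect_equal(tl$offset, 0)

  y <- rnorm(500)
  tly <- tukey_ladder(y)
  expect_equal(tly$lambda, 1)

  # zeros force the +1 offset and keep all rungs finite
  xz <- c(0, 0, rpois(200, 4))
  tlz <- tukey_ladder(xz)
  expect_equal(tlz$offset, 1)
  expect_true(all(is.finite(tlz$x_transformed)))
})

test_that("Pearson matrix matches the hand formula and its t-based p values", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  pm <- pearson_matrix(d)
  expect_equal(pm$r["x", "y"], 0.6)
  expect_equal(pm$r, t(pm$r))
  expect_equal(diag(pm$r), c(x = 1, y = 1))
  tstat <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(pm$p["x", "y"], 2 * pt(-tstat, 2), tolerance = 1e-12)

  # exact linear relation
  d2 <- data.frame(x = 1:5, y = 2 * (1:5) + 1)
  expect_equal(pearson_matrix(d2)$r["x", "y"], 1)

  # zero-variance column flagged as NA
  d3 <- data.frame(x = 1:5, c = rep(2, 5))
  expect_true(is.na(pearson_matrix(d3)$r["x", "c"]))
})

test_that("p values are calibrated at the study sample size", {
  n_rep <- 4000
  n <- 36
  set.seed(3)
  rej <- 0
  for (i in seq_len(n_rep)) {
    d <- data.frame(a = rnorm(n), b = rnorm(n))
    rej <- rej + (pearson_matrix(d)$p["a", "b"] < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rej / n_rep - 0.05), 3 * se)
})

test_that("VIF matches the closed form and flags exact collinearity", {
  set.seed(4)
  n <- 200
  # two correlated predictors: both VIF = 1 / (1 - r^2)
  x1 <- rnorm(n); x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)
  x3 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  v <- vif_table(d, ~ x1 + x2 + x3)
  r2 <- cor(lm(x1 ~ x2 + x3)$fitted.values, x1)^2
  expect_equal(unname(v["x1"]), 1 / (1 - r2), tolerance = 1e-8)

  # orthogonal predictors: VIF 1 (balanced design)
  db <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1))
  vb <- vif_table(db, ~ a + b + c)
  expect_equal(unname(vb), rep(1, 3), tolerance = 1e-12)

  # duplicated predictor: infinite VIF, no crash
  d$x4 <- d$x1
  v4 <- vif_table(d, ~ x1 + x2 + x3 + x4)
  expect_true(is.infinite(v4["x1"]) && is.infinite(v4["x4"]))
})

test_that("the regression suite fits all four named models", {
  set.seed(5)
  n <- 36
  d <- data.frame(vaq_preschool_t = rnorm(n, 1.31, 0.98),
                  omega2 = rnorm(n, -5.46, 2.82))
  d$ras_emotion <- 15.072 - 0.891 * d$vaq_preschool_t -
    0.282 * d$omega2 + rnorm(n, 0, 2.281)
  reps <- fit_linear_models(d)
  expect_named(reps, c("simple", "full", "partial_omega2", "partial_vaq"))
  expect_equal(reps$simple$df_residual, n - 3)
  expect_equal(nrow(reps$full$terms), 4)
  expect_true(all(vapply(reps, function(r) is.finite(r$q2), logical(1))))
  # CIs symmetric about the estimate under the t reference
  tt <- reps$simple$terms
  expect_equal(tt$estimate - tt$ci_low, tt$ci_high - tt$estimate,
               tolerance = 1e-9)
})

test_that("noise-free data recovers exact coefficients and unit R2", {
  d <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  d$y <- 2 * d$x1 - d$x2 + 3
  rep <- proalhgf:::ols_report(y ~ x1 + x2, d, "exact")
  expect_equal(rep$terms$estimate, c(3, 2, -1), tolerance = 1e-10)
  expect_equal(rep$adj_r2, 1, tolerance = 1e-10)
  expect_equal(loocv_q2(d, y ~ x1 + x2), 1, tolerance = 1e-10)
})

test_that("F statistic matches an independent sum-of-squares decomposition", {
  set.seed(6)
  d <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  d$y <- 1 + 0.5 * d$x1 + rnorm(20)
  rep <- proalhgf:::ols_report(y ~ x1 + x2, d, "toy")
  fit <- lm(y ~ x1 + x2, d)
  rss <- sum(residuals(fit)^2)
  tss <- sum((d$y - mean(d$y))^2)
  p <- 2; n <- 20
  f_manual <- ((tss - rss) / p) / (rss / (n - p - 1))
  expect_equal(rep$f_value, f_manual, tolerance = 1e-10)
  expect_equal(rep$f_p, pf(f_manual, p, n - p - 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("rank deficiency is reported with the aliased term", {
  d <- data.frame(x1 = rnorm(20))
  d$x2 <- d$x1
  d$y <- d$x1 + rnorm(20)
  err <- tryCatch(proalhgf:::ols_report(y ~ x1 + x2, d, "aliased"),
                  proalhgf_rank_deficient = function(e) conditionMessage(e))
  expect_match(err, "x2")
})

test_that("LOOCV Q2 matches a fold-by-fold oracle and is negative under the null", {
  d <- data.frame(x = c(1, 2, 3, 4, 10), y = c(1.2, 1.9, 3.3, 4.1, 9.5))
  press <- 0
  for (i in 1:5) {
    f <- lm(y ~ x, d[-i, ])
    press <- press + (d$y[i] - predict(f, d[i, , drop = FALSE]))^2
  }
  q2_oracle <- unname(1 - press / sum((d$y - mean(d$y))^2))
  expect_equal(loocv_q2(d, y ~ x), q2_oracle, tolerance = 1e-12)

  set.seed(7)
  q2s <- replicate(100, {
    d0 <- data.frame(x1 = rnorm(36), x2 = rnorm(36), y = rnorm(36))
    loocv_q2(d0, y ~ x1 + x2)
  })
  expect_lt(mean(q2s), 0)
})

test_that("regression reports are equivariant under predictor scaling", {
  set.seed(8)
  d <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  d$y <- 1 + 2 * d$x1 - d$x2 + rnorm(30, 0, 0.5)
  r1 <- proalhgf:::ols_report(y ~ x1 + x2, d, "raw")
  d2 <- transform(d, x1 = 10 * x1)
  r2 <- proalhgf:::ols_report(y ~ x1 + x2, d2, "scaled")
  expect_equal(r2$terms$estimate[2], r1$terms$estimate[2] / 10,
               tolerance = 1e-10)
  expect_equal(r2$adj_r2, r1$adj_r2, tolerance = 1e-12)
  expect_equal(r2$f_value, r1$f_value, tolerance = 1e-9)
  expect_equal(loocv_q2(d2, y ~ x1 + x2), loocv_q2(d, y ~ x1 + x2),
               tolerance = 1e-10)
})

test_that("the mixed graphical model stays empty under independence", {
  edge_counts <- vapply(1:20, function(s) {
    set.seed(s)
    d <- as.data.frame(matrix(rnorm(500 * 6), 500))
    nrow(fit_mgm(d)$edges)
  }, numeric(1))
  expect_lt(mean(edge_counts), 0.5)
})

test_that("the mixed graphical model recovers a chain without the spurious edge", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(1000); y <- 0.7 * x + rnorm(1000); z <- 0.7 * y + rnorm(1000)
    A <- fit_mgm(data.frame(x = x, y = y, z = z))$adjacency
    if (A["x", "y"] != 0 && A["y", "z"] != 0 && A["x", "z"] == 0) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 18)
})

test_that("binary nodes couple through the logistic link", {
  set.seed(9)
  xc <- rnorm(1000)
  xb <- rbinom(1000, 1, plogis(1.5 * xc))
  g <- fit_mgm(data.frame(xc = xc, xb = xb, noise = rnorm(1000)))
  expect_true(g$adjacency["xc", "xb"] != 0)
  expect_equal(g$types[["xb"]], "c")
  expect_equal(diag(g$adjacency), rep(0, 3), ignore_attr = TRUE)
  expect_equal(g$adjacency, t(g$adjacency))
})

test_that("zero-variance nodes are rejected by name", {
  d <- data.frame(a = rnorm(50), b = rnorm(50), dead = rep(1, 50))
  err <- tryCatch(fit_mgm(d),
                  proalhgf_bad_node = function(e) conditionMessage(e))
  expect_match(err, "dead")
})
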