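#' Pipeline configuration
#'
#' Settings for the end-to-end analysis: synthetic-cohort generation, model
#' fitting, random-effects model selection and cohort statistics.
#'
#' @param cohort A [cohort_config()].
#' @param models Models to fit and compare.
#' @param n_restarts MAP optimisation restarts per fit.
#' @param alpha0 Prior Dirichlet concentration for model selection.
#' @param mc_samples Monte Carlo draws for exceedance probabilities.
#' @param ebic_gamma EBIC gamma for the mixed graphical model.
#' @param seed Master seed of the pipeline.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            models = c("hgf", "rw", "sk1"),
                            n_restarts = 8, alpha0 = 1, mc_samples = 1e5,
                            ebic_gamma = 0.25, seed = 1) {
  structure(list(cohort = cohort, models = models,
                 n_restarts = n_restarts, alpha0 = alpha0,
                 mc_samples = mc_samples, ebic_gamma = ebic_gamma,
                 seed = seed), class = "pipeline_config")
}

#' Fit all models to every subject's session
#'
#' @param trials Stacked trial table with a `subject_id` column.
#' @param models Character vector of model ids.
#' @param n_restarts Restarts per fit.
#' @param seed Master seed.
#' @return Nested list `fits[[subject]][[model]]` of `proal_fit`s.
#' @export
fit_all_subjects <- function(trials, models = c("hgf", "rw", "sk1"),
                             n_restarts = 8, seed = 1) {
  required <- c("subject_id", "trial", "cue", "outcome", "u", "response")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop_proalhgf(
      sprintf("trial table is missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "proalhgf_schema_error")
  }
  subjects <- unique(trials$subject_id)
  fits <- lapply(seq_along(subjects), function(i) {
    tr <- trials[trials$subject_id == subjects[i], ]
    out <- lapply(seq_along(models), function(j) {
      fit_trials(tr, models[j], n_restarts = n_restarts,
                 seed = derive_seed(seed, i * 31L + j))
    })
    names(out) <- models
    out
  })
  names(fits) <- subjects
  fits
}

#' Read and write evidence tables
#'
#' The flat per-subject-per-model summary written by the inversion stage:
#' comma-separated with columns `subject_id, model, param, estimate, lme,
#' converged`.
#'
#' @param summary_df A data frame from [fit_summary()].
#' @param path File path.
#' @export
write_evidence <- function(summary_df, path) {
  write.csv(summary_df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Evidence matrix from a flat evidence table
#'
#' @param summary_df Data frame with columns `subject_id`, `model`, `lme`.
#' @return Subjects x models matrix of log model evidences.
#' @export
evidence_from_summary <- function(summary_df) {
  sub <- unique(summary_df[, c("subject_id", "model", "lme")])
  subjects <- unique(sub$subject_id)
  models <- unique(sub$model)
  L <- matrix(NA_real_, length(subjects), length(models),
              dimnames = list(subjects, models))
  for (r in seq_len(nrow(sub))) {
    L[sub$subject_id[r], sub$model[r]] <- sub$lme[r]
  }
  L
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: (1) generate the synthetic cohort and its trial-level behaviour;
#' (2) invert every model for every subject by MAP with Laplace evidence;
#' (3) random-effects Bayesian model selection; (4) cohort statistics on the
#' generated questionnaire scores joined with the fitted HGF parameters:
#' summary table, Tukey transformation of the preschool VAQ score, Pearson
#' correlations, VIFs of the all-predictor model, the four regression models
#' with LOOCV Q2, and the mixed graphical model over emotion coping, the
#' fitted omega2, transformed preschool VAQ, anxiety scores and gender.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory; when given, tables and a text
#'   report are written there.
#' @return List with `data`, `fits`, `evidence`, `bms`, `stats` and
#'   `report` (character vector of report lines).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  tmp_out <- is.null(outdir)
  if (tmp_out) outdir <- tempfile("proalhgf_run_")
  bundle <- end_to_end_dataset(config$cohort, outdir)
  message(sprintf("simulate: %d subjects, %d trials each",
                  nrow(bundle$cohort), bundle$schedule$session_length))
  fits <- fit_all_subjects(bundle$behavior$trials, config$models,
                           n_restarts = config$n_restarts,
                           seed = derive_seed(config$seed, 3L))
  summary_df <- fit_summary(fits)
  message(sprintf("fit: %d subjects x %d models, %d converged",
                  length(fits), length(config$models),
                  sum(vapply(fits, function(s)
                    sum(vapply(s, `[[`, logical(1), "converged")),
                    numeric(1)))))
  L <- evidence_matrix(fits)
  bms <- bms_compare(L, alpha0 = config$alpha0,
                     n_samples = config$mc_samples,
                     seed = derive_seed(config$seed, 4L))
  message(sprintf("bms: best model %s (pxp %.3f)",
                  bms$models[which.max(bms$pxp)], max(bms$pxp)))

  # analysis table: questionnaire scores + fitted HGF parameters
  hgf_est <- do.call(rbind, lapply(names(fits), function(sid) {
    p <- fits[[sid]]$hgf$params
    data.frame(subject_id = sid, omega2_hat = p$omega2,
               omega3_hat = p$omega3, zeta_hat = p$zeta,
               stringsAsFactors = FALSE)
  }))
  tab <- merge(bundle$cohort, hgf_est, by = "subject_id")
  tab$vaq_preschool_t <- tukey_ladder(tab$vaq_preschool)$x_transformed
  stat_tab <- tab
  stat_tab$omega2 <- tab$omega2_hat # analysis uses the *fitted* parameters
  stat_tab$omega3 <- tab$omega3_hat
  stat_tab$zeta <- tab$zeta_hat
  stats <- list(
    summary = summarize_cohort(stat_tab, c(
      "age", "vaq_preschool", "vaq_preschool_t", "vaq_childhood",
      "vaq_adolescent", "ras_total", "ras_emotion", "ras_social",
      "ras_situation", "stai_s", "stai_t", "omega2", "omega3", "zeta")),
    correlations = pearson_matrix(stat_tab, c(
      "omega2", "omega3", "zeta", "ras_total", "ras_emotion",
      "ras_social", "ras_situation", "vaq_preschool", "vaq_childhood",
      "vaq_adolescent", "stai_s", "stai_t", "age")),
    vif = vif_table(stat_tab,
                    ~ vaq_preschool_t + vaq_childhood + vaq_adolescent +
                      omega2 + omega3 + zeta),
    regressions = fit_linear_models(stat_tab),
    mgm = fit_mgm(
      data.frame(ras_emotion = stat_tab$ras_emotion,
                 omega2 = stat_tab$omega2,
                 vaq_preschool_t = stat_tab$vaq_preschool_t,
                 stai_s = stat_tab$stai_s, stai_t = stat_tab$stai_t,
                 gender = as.numeric(stat_tab$gender == "male")),
      ebic_gamma = config$ebic_gamma))
  message("stats: summaries, correlations, regressions, graph done")
  report <- render_report(bms, stats, stat_tab)
  if (!tmp_out) {
    write_evidence(summary_df, file.path(outdir, "evidence.csv"))
    write_bms_result(bms, file.path(outdir, "bms.json"))
    write.csv(stats$summary, file.path(outdir, "summary.csv"),
              row.names = FALSE)
    writeLines(report, file.path(outdir, "report.txt"))
  }
  invisible(list(data = bundle, fits = fits, evidence = summary_df,
                 bms = bms, stats = stats, report = report))
}

#' Render a text report of the pipeline results
#'
#' Mirrors the shape of the study's results section: the HGF parameter
#' summary (mean and SD of omega2, omega3, zeta, in that order), model
#' frequencies and protected exceedance probabilities, the headline
#' correlations, the regression table and the selected graph edges.
#'
#' @param bms A `bms_result`.
#' @param stats The `stats` element of [run_pipeline()]'s return value.
#' @param table The analysis table (fitted parameters joined to scores).
#' @return Character vector of report lines.
#' @export
render_report <- function(bms, stats, table) {
  par_line <- function(v) sprintf("%s: %.2f ± %.2f", v,
                                  mean(table[[v]]), sd(table[[v]]))
  lines <- c(
    "== HGF parameter summary (mean ± SD) ==",
    par_line("omega2"), par_line("omega3"), par_line("zeta"),
    "",
    "== Random-effects model selection ==",
    sprintf("model frequencies: %s",
            paste(sprintf("%s=%.3f", bms$models, bms$r), collapse = ", ")),
    sprintf("protected exceedance probabilities: %s",
            paste(sprintf("%s=%.3f", bms$models, bms$pxp), collapse = ", ")),
    sprintf("Bayesian omnibus risk: %.4f", bms$bor),
    "",
    "== Correlations (r) with RAS-emotion coping ==",
    sprintf("r_omega2 = %.3f, r_vaq_preschool = %.3f, r_stai_t = %.3f",
            stats$correlations$r["omega2", "ras_emotion"],
            stats$correlations$r["vaq_preschool", "ras_emotion"],
            stats$correlations$r["stai_t", "ras_emotion"]),
    "",
    "== Regression models (outcome: RAS-emotion coping) ==")
  for (nm in names(stats$regressions)) {
    rg <- stats$regressions[[nm]]
    lines <- c(lines, sprintf(
      "%s: adjR2=%.3f, resSE=%.3f (df=%d), F(%d,%d)=%.3f p=%.4f, Q2=%.3f",
      nm, rg$adj_r2, rg$sigma, rg$df_residual, rg$f_df[1], rg$f_df[2],
      rg$f_value, rg$f_p, rg$q2))
  }
  lines <- c(lines, "", "== Mixed graphical model edges ==")
  if (nrow(stats$mgm$edges)) {
    lines <- c(lines, sprintf("%s -- %s: %.3f", stats$mgm$edges$node1,
                              stats$mgm$edges$node2,
                              stats$mgm$edges$weight))
  } else {
    lines <- c(lines, "(no edges selected)")
  }
  lines
}
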