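## End-to-end orchestration: simulate -> reliability -> aggregate ->
## evaluate -> survival, with deterministic seeding and delimited-text
## artifacts.

#' Pipeline configuration
#'
#' Collects every tunable of the full run. Seeds for the individual stages
#' are derived deterministically from the master seed so stages can be
#' re-run in isolation.
#'
#' @param seed master seed.
#' @param n_cores number of tumor cores.
#' @param n_users number of crowd scorers.
#' @param crowd see [crowd_config()].
#' @param cores see [core_config()].
#' @param n_expert expert reference-set size.
#' @param variant aggregation variant (see [consensus_table()]).
#' @param cancer_threshold cell-count score cut for the cancer-present call.
#' @param er_cut pseudo-Allred cut for the ER call (positive when greater).
#' @param beta1,beta2 ER log-hazard-ratio intercept and slope of the
#'   survival generator.
#' @param baseline see [baseline_hazard()].
#' @param horizon administrative censoring horizon, years.
#' @param m_impute number of imputations for missing stage/grade.
#' @param p_missing_stage,p_missing_grade missingness fractions.
#' @param ups_tol,ups_max_iter reliability-iteration controls.
#' @param out_dir output directory (`NULL` for in-memory only).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_cores = 300L, n_users = 600L,
                            crowd = crowd_config(), cores = core_config(),
                            n_expert = 200L, variant = "plain",
                            cancer_threshold = 10L, er_cut = 2L,
                            beta1 = -1.41, beta2 = 0.21,
                            baseline = baseline_hazard(), horizon = 15,
                            m_impute = 20L,
                            p_missing_stage = 0.078, p_missing_grade = 0.093,
                            ups_tol = 3e-4, ups_max_iter = 100L,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

stage_seed <- function(seed, k) (as.integer(seed) * 97L + k * 7919L) %% 2147483647L

#' Run the full crowd-scoring pipeline
#'
#' Simulates cores and a crowd, estimates user reliability, aggregates
#' consensus scores into per-core cancer-cell-count and pseudo-Allred
#' scores, evaluates them against the ground truth (ROC/AUC, confusion
#' rates at the configured cuts, Spearman correlation, mean difference),
#' then simulates a linked survival cohort and validates the prognostic
#' value of the crowd ER call with Kaplan-Meier/log-rank and the
#' time-varying-covariate Cox model (with multiple imputation of missing
#' stage/grade pooled by Rubin's rules).
#'
#' @param config see [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return list of class `pipeline_result` with elements `truth`, `scorers`,
#'   `events`, `expert`, `ups`, `consensus`, `images`, `metrics`, `tumors`,
#'   `km`, `cox`, `config`. Written to `config$out_dir` as CSV/JSON when
#'   set.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_users < 1L) stop_invalid("config: n_users must be >= 1")
  if (config$n_cores < 1L) stop_invalid("config: n_cores must be >= 1")
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- Sys.time()

  truth <- simulate_cores(config$n_cores, config$cores,
                          seed = stage_seed(config$seed, 1L))
  scorers <- simulate_crowd(config$n_users, config$crowd,
                            seed = stage_seed(config$seed, 2L))
  events <- simulate_classifications(truth, scorers,
                                     seed = stage_seed(config$seed, 3L))
  expert <- make_expert_set(truth, min(config$n_expert, nrow(truth)),
                            seed = stage_seed(config$seed, 4L))
  say("simulate: %d cores, %d users, %d events, %d expert sub-images",
      config$n_cores, config$n_users, nrow(events), nrow(expert))

  ups <- iterate_to_convergence(events, expert, tol = config$ups_tol,
                                max_iter = config$ups_max_iter)
  say("ups: %d iterations%s", ups$n_iterations,
      if (ups$converged) "" else " (not converged)")

  consensus <- consensus_table(events, users = ups$users,
                               variant = config$variant)
  images <- score_images(consensus, cancer_threshold = config$cancer_threshold,
                         er_cut = config$er_cut)

  core1 <- truth[!duplicated(truth$image_id), ]
  idx <- match(images$image_id, core1$image_id)
  images$true_cancer <- core1$core_cancer[idx]
  images$true_allred <- core1$core_allred[idx]
  images$true_er <- core1$core_er_positive[idx]

  cancer_roc <- roc_auc(images$cell_count_score, images$true_cancer)
  cancer_conf <- confusion_from_calls(images$true_cancer,
                                      images$cancer_present_call)
  er_subset <- images[images$true_cancer & images$cancer_present_call, ]
  er_roc <- if (length(unique(er_subset$true_er)) == 2L)
    roc_auc(er_subset$pseudo_allred, er_subset$true_er) else NULL
  er_conf <- confusion_from_calls(er_subset$true_er, er_subset$er_call)
  metrics <- list(
    cancer_auc = cancer_roc$auc,
    cancer = confusion_metrics(cancer_conf),
    er_auc = if (!is.null(er_roc)) er_roc$auc else NA_real_,
    er = confusion_metrics(er_conf),
    spearman_allred = spearman_rho(er_subset$true_allred,
                                   er_subset$pseudo_allred),
    mean_difference = mean_difference(er_subset$true_allred,
                                      er_subset$pseudo_allred),
    n_er_subset = nrow(er_subset)
  )
  say("evaluate: cancer AUC %.3f, ER AUC %.3f, Spearman %.3f",
      metrics$cancer_auc, metrics$er_auc, metrics$spearman_allred)

  tumors <- simulate_tumors(truth, p_missing_stage = 0, p_missing_grade = 0,
                            seed = stage_seed(config$seed, 5L))
  tumors <- simulate_survival(tumors, beta1 = config$beta1,
                              beta2 = config$beta2,
                              baseline = config$baseline,
                              horizon = config$horizon,
                              seed = stage_seed(config$seed, 6L))
  tumors <- mask_stage_grade(tumors, config$p_missing_stage,
                             config$p_missing_grade,
                             seed = stage_seed(config$seed, 7L))
  tumors$er_call <- images$er_call[match(tumors$image_id, images$image_id)]

  km <- km_fit(tumors, group = "er_call")
  cox <- tryCatch({
    if (anyNA(tumors$stage) || anyNA(tumors$grade)) {
      imp <- impute_stage_grade(tumors, m = config$m_impute,
                                seed = stage_seed(config$seed, 8L))
      cox_tvc_pooled(imp, er_col = "er_call")
    } else {
      cox_tvc_fit(tumors, er_col = "er_call")
    }
  }, error = function(e) {
    warning("survival stage failed: ", conditionMessage(e))
    NULL
  })
  if (!is.null(cox)) {
    cr <- if (inherits(cox, "rubin_pool")) cox$crossing else cox$crossing
    say("survival: log-rank p %.2g; HR(t) crosses 1 at %.1f years",
        km$p_value, cr$time %||% NA_real_)
  }

  res <- structure(list(truth = truth, scorers = scorers, events = events,
                        expert = expert, ups = ups, consensus = consensus,
                        images = images, metrics = metrics, tumors = tumors,
                        km = km, cox = cox, config = config,
                        elapsed = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline(res, config$out_dir)
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline run: %d cores, %d users, %d events (%.1f s)\n",
              x$config$n_cores, x$config$n_users, nrow(x$events), x$elapsed))
  cat(sprintf("  cancer AUC %.3f | ER AUC %.3f | Spearman %.3f\n",
              x$metrics$cancer_auc, x$metrics$er_auc,
              x$metrics$spearman_allred))
  if (!is.null(x$cox)) {
    cr <- x$cox$crossing
    b <- if (inherits(x$cox, "rubin_pool"))
      x$cox$estimates[c("er", "er:t"), "estimate"]
    else unname(x$cox$coefficients[c("er", "er:t")])
    cat(sprintf("  ER beta1 %.2f, beta2 %.2f; HR crosses 1 at %.1f years\n",
                b[1], b[2], cr$time))
  }
  invisible(x)
}
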