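## Delimited-text artifacts. All tables are comma-separated UTF-8 with a
## header row and "." decimals; missing values are empty fields; the first
## line is a comment recording the seed and config hash so outputs can be
## traced to the run that produced them.

artifact_schemas <- list(
  events = c("user_id", "sub_image_id", "cancer_present"),
  expert = c("sub_image_id", "cancer_present"),
  users = c("user_id", "n_scored", "preliminary_ups", "final_ups"),
  consensus = c("sub_image_id", "modal_cancer_prob", "n_scores",
                "median_cell_count", "median_proportion", "median_intensity",
                "median_pseudo_allred"),
  images = c("image_id", "cell_count_score", "pseudo_allred", "er_call",
             "cancer_present_call"),
  tumors = c("patient_id", "study", "age", "stage", "grade", "time", "event")
)

bin_ranges <- list(cell_count_bin = c(1L, 4L), proportion_bin = c(0L, 5L),
                   intensity_bin = c(0L, 3L), median_pseudo_allred = c(0L, 8L))

#' Write a pipeline table as CSV
#'
#' @param x data frame.
#' @param path output path.
#' @param what schema name (`"events"`, `"expert"`, `"users"`,
#'   `"consensus"`, `"images"` or `"tumors"`) or `NULL` to skip validation.
#' @param seed,hash recorded in the leading comment line.
#' @export
write_table_csv <- function(x, path, what = NULL, seed = NA, hash = "") {
  if (!is.null(what)) check_columns(x, artifact_schemas[[what]], what)
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(sprintf("# crowdihc %s seed=%s hash=%s", what %||% "table",
                     seed, hash), con)
  close(con)
  data.table::fwrite(x, path, append = TRUE, col.names = TRUE, sep = ",",
                     na = "")
  invisible(path)
}

#' Read a pipeline table from CSV
#'
#' Skips the comment line, checks the schema and validates ordinal bins
#' against their scales, reporting the offending column and line.
#'
#' @param path CSV path.
#' @param what schema name or `NULL`.
#' @return data frame.
#' @export
read_table_csv <- function(path, what = NULL) {
  x <- as.data.frame(data.table::fread(path, sep = ",", na.strings = ""))
  if (!is.null(what)) check_columns(x, artifact_schemas[[what]], what)
  for (col in intersect(names(bin_ranges), names(x))) {
    rng <- bin_ranges[[col]]
    v <- x[[col]]
    bad <- which(!is.na(v) & (v < rng[1] | v > rng[2] | v != floor(v)))
    if (length(bad))
      stop_invalid("%s: column %s out of range %d-%d at data line %d",
                   basename(path), col, rng[1], rng[2], bad[1])
  }
  x
}

#' Write every pipeline artifact to a directory
#'
#' Events, expert set, user table, consensus table, image scores and tumor
#' table as CSV plus a top-level JSON report (accuracy metrics, survival
#' fit, crossing time, config).
#'
#' @param res a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- res$config$seed
  hash <- config_hash(res$config[setdiff(names(res$config), "out_dir")])
  w <- function(x, name, what) write_table_csv(
    x, file.path(dir, paste0(name, ".csv")), what, seed, hash)
  w(res$events, "events", "events")
  w(res$expert, "expert", "expert")
  w(res$ups$users, "users", "users")
  w(res$consensus, "consensus", "consensus")
  w(res$images, "image_scores", "images")
  w(res$tumors, "tumors", "tumors")
  jsonlite::write_json(pipeline_report(res),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Summary report of a pipeline run
#'
#' @param res a `pipeline_result`.
#' @return plain list suitable for JSON serialisation.
#' @export
pipeline_report <- function(res) {
  m <- res$metrics
  cox <- res$cox
  surv_block <- NULL
  if (!is.null(cox)) {
    if (inherits(cox, "rubin_pool")) {
      est <- cox$estimates
      surv_block <- list(
        pooled = TRUE, m = cox$m,
        er_beta1 = est["er", "estimate"], er_beta1_se = est["er", "se"],
        er_beta2 = est["er:t", "estimate"], er_beta2_se = est["er:t", "se"],
        crossing_years = cox$crossing$time, crossing_ci = cox$crossing$ci)
    } else {
      surv_block <- list(
        pooled = FALSE,
        er_beta1 = unname(cox$coefficients["er"]),
        er_beta1_se = unname(cox$se["er"]),
        er_beta2 = unname(cox$coefficients["er:t"]),
        er_beta2_se = unname(cox$se["er:t"]),
        loglik = cox$loglik,
        crossing_years = cox$crossing$time, crossing_ci = cox$crossing$ci)
    }
    surv_block$hr_at_diagnosis <- exp(surv_block$er_beta1)
  }
  list(
    seed = res$config$seed,
    config_hash = config_hash(res$config[setdiff(names(res$config),
                                                 "out_dir")]),
    n_cores = res$config$n_cores,
    n_users = res$config$n_users,
    n_events = nrow(res$events),
    ups_iterations = res$ups$n_iterations,
    ups_converged = res$ups$converged,
    accuracy = list(
      cancer_auc = m$cancer_auc,
      cancer_sensitivity = m$cancer$sensitivity,
      cancer_specificity = m$cancer$specificity,
      er_auc = m$er_auc,
      er_sensitivity = m$er$sensitivity,
      er_specificity = m$er$specificity,
      er_agreement = m$er$agreement,
      spearman_allred = m$spearman_allred,
      mean_difference = m$mean_difference$mean),
    survival = c(list(logrank_p = res$km$p_value), surv_block)
  )
}

#' Save / load a pipeline configuration as JSON
#'
#' Nested parameter lists (crowd, cores, baseline) are preserved; reading
#' restores a `pipeline_config` object with defaults filled in for any
#' field absent from the file.
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], raw[[nm]])
    else cfg[[nm]] <- raw[[nm]]
  }
  cfg
}
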