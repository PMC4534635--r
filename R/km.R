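#' Kaplan-Meier curves by ER call with a log-rank test
#'
#' Product-limit estimates per group with Greenwood pointwise 95% intervals
#' (via [survival::survfit()]) and the two-group log-rank chi-square
#' ([survival::survdiff()], optionally stratified by study).
#'
#' @param tumors table with `time`, `event` and the grouping column.
#' @param group column name of the (logical or factor) group, e.g. the
#'   crowd ER call.
#' @param strata optional column name to stratify the log-rank test by.
#' @return list of class `km_fit`: `fit` (a `survfit` object), `logrank`
#'   (chi-square), `df`, `p_value`.
#' @export
km_fit <- function(tumors, group = "er_call", strata = NULL) {
  check_columns(tumors, c("time", "event", group), "tumor table")
  if (sum(tumors$event) == 0L)
    warning("no events: survival curves are identically 1")
  dat <- data.frame(time = tumors$time, event = as.numeric(tumors$event),
                    group = factor(tumors[[group]]))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat,
                           conf.type = "log", conf.int = 0.95)
  logrank <- NULL; p <- NA_real_; df <- NA_integer_
  if (nlevels(dat$group) > 1L && sum(dat$event) > 0L) {
    if (!is.null(strata)) {
      dat$.str <- factor(tumors[[strata]])
      sd <- survival::survdiff(
        survival::Surv(time, event) ~ group + survival::strata(.str),
        data = dat)
    } else {
      sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = dat)
    }
    df <- length(sd$n) - 1L
    logrank <- unname(sd$chisq)
    p <- pchisq(sd$chisq, df = df, lower.tail = FALSE)
  }
  structure(list(fit = fit, logrank = logrank, df = df, p_value = p,
                 group = group),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$logrank))
    cat(sprintf("log-rank chi-square = %.2f (df = %d), p = %.3g\n",
                x$logrank, x$df, x$p_value))
  invisible(x)
}

#' Survival probability at a given time per group
#'
#' @param km a `km_fit` object.
#' @param at time point in years.
#' @return named vector of survival probabilities.
#' @export
km_survival_at <- function(km, at = 15) {
  s <- summary(km$fit, times = at, extend = TRUE)
  setNames(s$surv, sub("^group=", "", as.character(s$strata)))
}

#' @importFrom stats pchisq
NULL
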