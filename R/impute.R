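## Chained-equation imputation of missing stage and grade, and Rubin's-rules
## pooling of the Cox fits across completed datasets.

## One proper ordinal-logistic imputation draw: fit on complete rows, draw
## parameters from the approximate posterior N(hat, vcov), sample categories
## from the implied probabilities. Falls back to multinomial logistic and
## finally to hot-deck sampling when a fit fails on a sparse pattern.
draw_categorical <- function(y, Xp, miss_rows) {
  dat <- data.frame(y = y, Xp)
  obs <- dat[!is.na(y), , drop = FALSE]
  newd <- dat[miss_rows, , drop = FALSE]
  probs <- tryCatch({
    fit <- MASS::polr(y ~ ., data = obs, Hess = TRUE)
    par_hat <- c(coef(fit), fit$zeta)
    V <- vcov(fit)
    par_star <- drop(par_hat + t(chol(V)) %*% rnorm(length(par_hat)))
    k <- length(coef(fit))
    beta <- par_star[seq_len(k)]
    zeta <- sort(par_star[-seq_len(k)])
    eta <- drop(as.matrix(newd[, -1, drop = FALSE]) %*% beta)
    cum <- vapply(zeta, function(z) stats::plogis(z - eta),
                  numeric(length(eta)))
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
    cbind(cum[, 1, drop = FALSE],
          if (ncol(cum) > 1) cum[, -1, drop = FALSE] -
            cum[, -ncol(cum), drop = FALSE],
          1 - cum[, ncol(cum)])
  }, error = function(e) NULL)
  if (is.null(probs)) {
    probs <- tryCatch({
      fit <- nnet::multinom(y ~ ., data = obs, trace = FALSE)
      p <- stats::predict(fit, newdata = newd, type = "probs")
      if (is.null(dim(p))) p <- matrix(p, nrow = nrow(newd), byrow = FALSE)
      p
    }, error = function(e) NULL)
  }
  lev <- levels(y)
  if (is.null(probs)) {   # hot deck: sample observed values
    return(sample(as.character(obs$y), length(miss_rows), replace = TRUE))
  }
  probs <- pmax(probs, 0)
  apply(probs, 1, function(pr) sample(lev, 1, prob = pr + 1e-12))
}

#' Multiple imputation of missing stage and grade
#'
#' Chained equations: ordinal-logistic draws for stage given (age, ER,
#' event indicator, Nelson-Aalen cumulative hazard of the follow-up time,
#' study, current grade) alternate with the corresponding draws for grade,
#' following the usual convention for imputation in survival models of
#' conditioning on the cumulative-hazard transform of time rather than raw
#' time. Each of the `m` streams starts from a random fill and runs `maxit`
#' cycles with freshly drawn parameters, giving proper between-imputation
#' variability.
#'
#' @param tumors table with `time`, `event`, `age`, `stage`, `grade` and
#'   optionally the ER and study columns named below.
#' @param m number of completed datasets (default 20).
#' @param seed RNG seed.
#' @param maxit chained-equation cycles per stream.
#' @param er_col,study_col predictor columns (skipped when absent or
#'   single-level).
#' @return list of `m` completed data frames (class `imputed_sets`).
#' @export
impute_stage_grade <- function(tumors, m = 20L, seed = 1L, maxit = 5L,
                               er_col = "er_call", study_col = "study") {
  m <- check_count(m, "m", min = 2L)
  check_columns(tumors, c("time", "event", "age", "stage", "grade"),
                "tumor table")
  for (v in c("stage", "grade"))
    if (all(is.na(tumors[[v]])))
      stop_invalid("column %s is entirely missing; cannot impute", v)
  miss_s <- which(is.na(tumors$stage))
  miss_g <- which(is.na(tumors$grade))
  if (!length(miss_s) && !length(miss_g)) {
    out <- replicate(m, tumors, simplify = FALSE)
    class(out) <- c("imputed_sets", "list")
    return(out)
  }
  set.seed(seed)

  # Nelson-Aalen cumulative hazard evaluated at each subject's time
  sf <- survival::survfit(survival::Surv(time, as.numeric(event)) ~ 1,
                          data = tumors, ctype = 1)
  na_ch <- approx(sf$time, sf$cumhaz, xout = tumors$time, method = "constant",
                  rule = 2, f = 0, yleft = 0)$y

  Xbase <- data.frame(age = tumors$age,
                      event = as.numeric(tumors$event),
                      cumhaz = na_ch)
  if (er_col %in% names(tumors))
    Xbase$er <- as.numeric(as.logical(tumors[[er_col]]))
  if (study_col %in% names(tumors) &&
      length(unique(tumors[[study_col]])) > 1L) {
    sm <- stats::model.matrix(~ s, data.frame(s = factor(tumors[[study_col]])))
    Xbase <- cbind(Xbase, as.data.frame(sm[, -1, drop = FALSE]))
  }

  stage_lev <- levels(factor(tumors$stage))
  grade_lev <- levels(factor(tumors$grade))
  out <- vector("list", m)
  for (k in seq_len(m)) {
    stage <- factor(as.character(tumors$stage), levels = stage_lev,
                    ordered = TRUE)
    grade <- factor(as.character(tumors$grade), levels = grade_lev,
                    ordered = TRUE)
    if (length(miss_s))
      stage[miss_s] <- sample(as.character(stage[-miss_s]),
                              length(miss_s), replace = TRUE)
    if (length(miss_g))
      grade[miss_g] <- sample(as.character(grade[-miss_g]),
                              length(miss_g), replace = TRUE)
    for (it in seq_len(maxit)) {
      if (length(miss_s)) {
        ys <- factor(as.character(tumors$stage), levels = stage_lev,
                     ordered = TRUE)
        stage[miss_s] <- draw_categorical(
          ys, cbind(Xbase, grade = as.numeric(grade)), miss_s)
      }
      if (length(miss_g)) {
        yg <- factor(as.character(tumors$grade), levels = grade_lev,
                     ordered = TRUE)
        grade[miss_g] <- draw_categorical(
          yg, cbind(Xbase, stage = as.numeric(stage)), miss_g)
      }
    }
    comp <- tumors
    comp$stage <- factor(as.character(stage), levels = stage_lev,
                         ordered = TRUE)
    comp$grade <- factor(as.character(grade), levels = grade_lev,
                         ordered = TRUE)
    out[[k]] <- comp
  }
  class(out) <- c("imputed_sets", "list")
  out
}

#' Pool model fits across imputed datasets by Rubin's rules
#'
#' Pooled estimate is the mean of the per-imputation estimates; total
#' variance is the mean within-imputation variance plus `(1 + 1/m)` times
#' the between-imputation variance; intervals use Barnard-Rubin adjusted
#' degrees of freedom. Works on any list of fits exposing `coefficients`
#' and `se` (e.g. [cox_tvc_fit()] results); the full covariance matrices
#' are pooled the same way when available.
#'
#' @param fits list of `m >= 2` fits with identical coefficient layouts.
#' @param dfcom complete-data residual degrees of freedom (default: events
#'   minus parameters from the first fit, `Inf` if unknown).
#' @param level confidence level.
#' @return object of class `rubin_pool`: `estimates` (data frame with
#'   `estimate`, `se`, `df`, `ci_lo`, `ci_hi`, `p`), `m`, `vcov` (pooled),
#'   `within`, `between`.
#' @export
rubin_pool <- function(fits, dfcom = NULL, level = 0.95) {
  m <- length(fits)
  if (m < 2L) stop_invalid("rubin_pool needs m >= 2 fits")
  cf <- lapply(fits, function(f) f$coefficients %||% coef(f))
  nms <- names(cf[[1]])
  if (!all(vapply(cf, function(x) identical(names(x), nms), TRUE)))
    stop_invalid("fits have mismatched coefficient layouts")
  Q <- do.call(rbind, cf)
  U <- do.call(rbind, lapply(fits, function(f) f$se^2))
  qbar <- colMeans(Q)
  W <- colMeans(U)
  B <- apply(Q, 2, var)
  Tvar <- W + (1 + 1 / m) * B
  if (is.null(dfcom)) {
    f1 <- fits[[1]]
    dfcom <- if (!is.null(f1$n_events)) max(f1$n_events - length(nms), 1)
             else Inf
  }
  lambda <- (1 + 1 / m) * B / Tvar
  df <- ifelse(B == 0, Inf, {
    df_old <- (m - 1) / pmax(lambda, 1e-12)^2
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df_old * df_obs / (df_old + df_obs)
  })
  tq <- qt(1 - (1 - level) / 2, df)
  est <- data.frame(
    estimate = qbar, se = sqrt(Tvar), df = df,
    ci_lo = qbar - tq * sqrt(Tvar), ci_hi = qbar + tq * sqrt(Tvar),
    p = 2 * stats::pt(-abs(qbar / sqrt(Tvar)), df),
    row.names = nms
  )
  vc <- NULL
  if (!is.null(fits[[1]]$vcov)) {
    Wm <- Reduce(`+`, lapply(fits, vcov)) / m
    Bm <- stats::cov(Q)
    vc <- Wm + (1 + 1 / m) * Bm
  }
  structure(list(estimates = est, m = m, vcov = vc,
                 within = W, between = B),
            class = "rubin_pool")
}

#' @export
print.rubin_pool <- function(x, ...) {
  cat(sprintf("Rubin's rules pooling of %d imputations\n", x$m))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Fit the time-varying Cox model across imputed datasets and pool
#'
#' Convenience wrapper: [cox_tvc_fit()] on each completed dataset, pooled
#' with [rubin_pool()]; the crossing time is recomputed from the pooled ER
#' coefficients and pooled covariance.
#'
#' @param imputed list of completed datasets (see [impute_stage_grade()]).
#' @param ... passed to [cox_tvc_fit()].
#' @return `rubin_pool` object with an added `crossing` element and the
#'   per-imputation fits in `fits`.
#' @export
cox_tvc_pooled <- function(imputed, ...) {
  fits <- lapply(imputed, cox_tvc_fit, ...)
  pooled <- rubin_pool(fits)
  if (fits[[1]]$tvc && !is.null(pooled$vcov)) {
    b <- pooled$estimates[c("er", "er:t"), "estimate"]
    pooled$crossing <- crossing_time(b[1], b[2],
                                     pooled$vcov[c("er", "er:t"),
                                                 c("er", "er:t")])
  }
  pooled$fits <- fits
  pooled
}
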