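## Cox regression with a time-varying ER effect.
##
## The estrogen-receptor contribution to subject i's log hazard at event
## time t is er_i * (beta1 + beta2 * g(t)) with g the identity by default,
## so HR(t) = exp(beta1 + beta2 * t): protective at diagnosis, crossing 1 at
## t = -beta1/beta2 when beta2 > 0. The stratified partial likelihood with
## Breslow tie handling is maximised by Newton-Raphson from a zero start,
## with step halving; standard errors come from the inverse observed
## information. Risk-set sums are accumulated once per stratum as reverse
## cumulative sums split by ER group, which keeps each Newton iteration
## O(n * p^2) despite the time-dependent design.

#' Hazard ratio at a given follow-up time
#'
#' @param beta1 log hazard ratio at time zero.
#' @param beta2 slope of the log hazard ratio per year.
#' @param t follow-up time(s), years, >= 0.
#' @return `exp(beta1 + beta2 * t)`.
#' @export
hr_at_time <- function(beta1, beta2, t) {
  if (any(t < 0)) stop_invalid("t must be non-negative")
  exp(beta1 + beta2 * t)
}

#' Time at which the fitted hazard ratio crosses one
#'
#' `t* = -beta1/beta2`, defined when the effect starts protective
#' (`beta1 < 0`) and attenuates (`beta2 > 0`). The interval is the delta
#' method on the ratio by default; Fieller's method is available.
#'
#' @param beta1,beta2 coefficient pair.
#' @param cov 2x2 covariance matrix of `(beta1, beta2)`.
#' @param level confidence level.
#' @param method `"delta"` or `"fieller"`.
#' @return list `time`, `ci` (length 2), `se`; `time` is `NA` when no
#'   crossing exists.
#' @export
crossing_time <- function(beta1, beta2, cov = matrix(0, 2, 2),
                          level = 0.95, method = c("delta", "fieller")) {
  method <- match.arg(method)
  if (!(beta2 > 0 && beta1 < 0))
    return(list(time = NA_real_, ci = c(NA_real_, NA_real_), se = NA_real_))
  tstar <- -beta1 / beta2
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "delta") {
    g <- c(-1 / beta2, beta1 / beta2^2)
    v <- drop(t(g) %*% cov %*% g)
    se <- sqrt(max(v, 0))
    ci <- tstar + c(-1, 1) * z * se
  } else {
    # roots t of (beta1 + beta2 t)^2 = z^2 (v11 + 2 t v12 + t^2 v22)
    a <- beta2^2 - z^2 * cov[2, 2]
    b <- 2 * (beta1 * beta2 - z^2 * cov[1, 2])
    cc <- beta1^2 - z^2 * cov[1, 1]
    disc <- b^2 - 4 * a * cc
    if (a <= 0 || disc < 0) {
      ci <- c(NA_real_, NA_real_)
    } else {
      ci <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
    }
    g <- c(-1 / beta2, beta1 / beta2^2)
    se <- sqrt(max(drop(t(g) %*% cov %*% g), 0))
  }
  list(time = tstar, ci = ci, se = se)
}

## Design matrix for the fixed (proportional) covariates.
cox_design <- function(tumors, covariates) {
  cols <- list()
  if ("age" %in% covariates) cols$age <- as.numeric(tumors$age)
  if ("stage" %in% covariates) {
    s <- as.character(tumors$stage)
    cols$stageII <- as.numeric(s == "II")
    cols$stageIII <- as.numeric(s == "III")
    cols$stageIV <- as.numeric(s == "IV")
  }
  if ("grade" %in% covariates) {
    g <- as.character(tumors$grade)
    cols$grade2 <- as.numeric(g == "2")
    cols$grade3 <- as.numeric(g == "3")
  }
  extra <- setdiff(covariates, c("age", "stage", "grade"))
  for (e in extra) cols[[e]] <- as.numeric(tumors[[e]])
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(0, nrow(tumors), 0)
  X
}

## Pre-sorted per-stratum structures reused across Newton iterations.
coxtvc_prepare <- function(time, event, X, er, strata, g) {
  lapply(split(seq_along(time), strata), function(idx) {
    o <- idx[order(time[idx], decreasing = TRUE)]
    ti <- time[o]; ev <- event[o]
    Xs <- X[o, , drop = FALSE]; ers <- er[o]
    et <- sort(unique(ti[ev]))
    if (!length(et)) return(NULL)
    pos <- vapply(et, function(t) sum(ti >= t), 0L)   # risk-set size
    dsum <- lapply(et, function(t) {
      d <- which(ev & ti == t)
      list(d = length(d),
           sx = colSums(Xs[d, , drop = FALSE]),
           ser = sum(ers[d]))
    })
    list(X = Xs, er = ers, et = et, g_et = g(et), pos = pos, dsum = dsum)
  })
}

colcumsum <- function(m) {
  if (nrow(m) == 1L) return(m)
  apply(m, 2, cumsum)
}

## loglik (and optionally gradient/information) of the stratified Breslow
## partial likelihood at parameter c(beta_x, beta1[, beta2]).
coxtvc_eval <- function(par, prep, p, tvc, deriv = TRUE) {
  q <- p + 1L + as.integer(tvc)
  bx <- par[seq_len(p)]
  b1 <- par[p + 1L]
  b2 <- if (tvc) par[p + 2L] else 0
  ll <- 0
  grad <- numeric(q)
  info <- matrix(0, q, q)
  for (st in prep) {
    if (is.null(st)) next
    n <- nrow(st$X)
    rt <- exp(if (p > 0) drop(st$X %*% bx) else numeric(n))
    e0 <- st$er == 0
    cw0 <- cumsum(rt * e0); cw1 <- cumsum(rt * !e0)
    if (p > 0) {
      cv0 <- colcumsum(st$X * (rt * e0))
      cv1 <- colcumsum(st$X * (rt * !e0))
      if (deriv) {
        XX <- st$X[, rep(seq_len(p), each = p), drop = FALSE] *
          st$X[, rep(seq_len(p), p), drop = FALSE]
        cq0 <- colcumsum(XX * (rt * e0))
        cq1 <- colcumsum(XX * (rt * !e0))
      }
    }
    for (j in seq_along(st$et)) {
      k <- st$pos[j]
      gj <- st$g_et[j]
      f <- exp(b1 + b2 * gj)
      W0 <- cw0[k]; W1 <- cw1[k]
      S0 <- W0 + f * W1
      ds <- st$dsum[[j]]
      lp_d <- (if (p > 0) sum(ds$sx * bx) else 0) + ds$ser * (b1 + b2 * gj)
      ll <- ll + lp_d - ds$d * log(S0)
      if (!deriv) next
      erpart <- c(f * W1, if (tvc) gj * f * W1)
      S1 <- c(if (p > 0) cv0[k, ] + f * cv1[k, ], erpart)
      S2 <- matrix(0, q, q)
      if (p > 0) {
        S2[1:p, 1:p] <- matrix(cq0[k, ] + f * cq1[k, ], p, p)
        S2[1:p, p + 1L] <- S2[p + 1L, 1:p] <- f * cv1[k, ]
        if (tvc) S2[1:p, p + 2L] <- S2[p + 2L, 1:p] <- gj * f * cv1[k, ]
      }
      S2[p + 1L, p + 1L] <- f * W1
      if (tvc) {
        S2[p + 1L, p + 2L] <- S2[p + 2L, p + 1L] <- gj * f * W1
        S2[p + 2L, p + 2L] <- gj^2 * f * W1
      }
      mu <- S1 / S0
      zd <- c(if (p > 0) ds$sx, ds$ser, if (tvc) gj * ds$ser)
      grad <- grad + zd - ds$d * mu
      info <- info + ds$d * (S2 / S0 - tcrossprod(mu))
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

#' Cox model with a time-varying estrogen-receptor effect
#'
#' Fits a Cox proportional-hazards model stratified by study in which every
#' covariate except ER has a constant log hazard ratio and the ER log hazard
#' ratio is `beta1 + beta2 * g(t)` (`g` the identity by default, optionally
#' the natural logarithm). Breslow handling of tied event times; bespoke
#' Newton-Raphson maximiser (see the methods vignette).
#'
#' @param tumors data frame with `time`, `event`, the ER column, the model
#'   covariates and the stratification column. Covariates must be complete;
#'   impute first (see [impute_stage_grade()]).
#' @param covariates fixed-effect covariates; `"stage"` and `"grade"`
#'   expand to indicator contrasts against stage I / grade 1.
#' @param er_col logical/0-1 column with the ER status being tested.
#' @param strata_col stratification column (`NULL` for none).
#' @param tvc fit the time-varying term (`FALSE` gives an ordinary
#'   proportional-hazards ER effect, used for oracle comparisons).
#' @param time_transform `"identity"` or `"log"`.
#' @param max_iter,tol Newton iteration cap and convergence tolerance on the
#'   log-likelihood change.
#' @return object of class `cox_tvc`: `coefficients`, `se`, `vcov`,
#'   `loglik`, `loglik_null`, `n`, `n_events`, `iterations`, `converged`,
#'   `crossing` (see [crossing_time()]), `er_beta1`, `er_beta2`.
#' @export
cox_tvc_fit <- function(tumors,
                        covariates = c("age", "stage", "grade"),
                        er_col = "er_call", strata_col = "study",
                        tvc = TRUE,
                        time_transform = c("identity", "log"),
                        max_iter = 50L, tol = 1e-9) {
  time_transform <- match.arg(time_transform)
  check_columns(tumors, c("time", "event", er_col), "tumor table")
  g <- if (time_transform == "identity") identity else function(t) log(t)
  time <- as.numeric(tumors$time)
  event <- as.logical(tumors$event)
  if (sum(event) == 0L) stop_invalid("no events in the data")
  if (length(unique(time[event])) < 2L)
    stop_invalid("need at least 2 distinct event times")
  er <- as.numeric(as.logical(tumors[[er_col]]))
  X <- cox_design(tumors, covariates)
  if (anyNA(X) || anyNA(er) || anyNA(time))
    stop_invalid("missing covariate values; impute before fitting")
  if (ncol(X) > 0) {   # center continuous columns for numerical stability
    ctr <- vapply(seq_len(ncol(X)), function(j) {
      if (length(unique(X[, j])) > 2) mean(X[, j]) else 0
    }, 0)
    X <- sweep(X, 2, ctr)
  }
  strata <- if (is.null(strata_col)) rep(1L, nrow(tumors))
            else as.character(tumors[[strata_col]])
  p <- ncol(X)
  q <- p + 1L + as.integer(tvc)

  prep <- coxtvc_prepare(time, event, X, er, strata, g)
  par <- numeric(q)
  ev0 <- coxtvc_eval(par, prep, p, tvc, deriv = TRUE)
  ll_null <- ev0$loglik
  ll <- ll_null
  ev <- ev0
  n_it <- 0L
  converged <- FALSE
  repeat {
    n_it <- n_it + 1L
    step <- tryCatch(solve(ev$info, ev$grad), error = function(e)
      stop_invalid("singular information matrix at iteration %d", n_it))
    new_par <- par + step
    new_ll <- coxtvc_eval(new_par, prep, p, tvc, deriv = FALSE)$loglik
    h <- 0L
    while (!is.finite(new_ll) || new_ll < ll - 1e-12) {
      h <- h + 1L
      if (h > 25L) break
      step <- step / 2
      new_par <- par + step
      new_ll <- coxtvc_eval(new_par, prep, p, tvc, deriv = FALSE)$loglik
    }
    if (!is.finite(new_ll) || any(abs(new_par) > 50))
      stop_invalid(paste0(
        "partial likelihood is not finite or diverges ",
        "(possible separation / monotone likelihood; too few events?)"))
    par <- new_par
    dll <- new_ll - ll
    ll <- new_ll
    ev <- coxtvc_eval(par, prep, p, tvc, deriv = TRUE)
    # converge on the loglik change (the usual criterion), with a coarse
    # gradient guard against stalling far from the optimum
    if (abs(dll) < tol * max(1, abs(ll)) && max(abs(ev$grad)) < 1e-3) {
      converged <- TRUE
      break
    }
    if (n_it >= max_iter) break
  }
  if (!converged)
    stop_invalid(paste0(
      "Newton-Raphson did not converge in %d iterations ",
      "(loglik change %.3g, max |gradient| %.3g)"),
      max_iter, abs(ll - ll_null), max(abs(ev$grad)))

  vc <- solve(ev$info)
  nms <- c(colnames(X), "er", if (tvc) "er:t")
  coefficients <- setNames(par, nms)
  se <- setNames(sqrt(diag(vc)), nms)
  dimnames(vc) <- list(nms, nms)
  b1 <- coefficients[["er"]]
  b2 <- if (tvc) coefficients[["er:t"]] else 0
  crossing <- if (tvc) {
    crossing_time(b1, b2, vc[c("er", "er:t"), c("er", "er:t")])
  } else list(time = NA_real_, ci = c(NA_real_, NA_real_), se = NA_real_)

  structure(list(coefficients = coefficients, se = se, vcov = vc,
                 loglik = ll, loglik_null = ll_null,
                 n = nrow(tumors), n_events = sum(event),
                 iterations = n_it, converged = converged,
                 er_beta1 = b1, er_beta2 = b2, tvc = tvc,
                 time_transform = time_transform, crossing = crossing),
            class = "cox_tvc")
}

#' @export
print.cox_tvc <- function(x, ...) {
  cat(sprintf("Cox model%s: n = %d, events = %d, loglik = %.2f\n",
              if (x$tvc) " with time-varying ER effect" else "",
              x$n, x$n_events, x$loglik))
  z <- x$coefficients / x$se
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                    se = x$se, z = z, p = 2 * pnorm(-abs(z)),
                    check.names = FALSE)
  print(round(tab, 4))
  if (x$tvc && !is.na(x$crossing$time))
    cat(sprintf("HR(t) = exp(%.2f %+.2f t): %.2f at diagnosis, crosses 1 at %.1f years (95%% CI %.1f to %.1f)\n",
                x$er_beta1, x$er_beta2, exp(x$er_beta1),
                x$crossing$time, x$crossing$ci[1], x$crossing$ci[2]))
  invisible(x)
}

#' @export
coef.cox_tvc <- function(object, ...) object$coefficients

#' @export
vcov.cox_tvc <- function(object, ...) object$vcov

#' @export
logLik.cox_tvc <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}
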