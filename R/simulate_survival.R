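## Survival-time generator with a time-varying ER effect.
##
## The hazard for subject i is
##   h_i(t) = h0(t) * exp(x_i' gamma + er_i * (beta1 + beta2 * t)),
## so the ER log hazard ratio varies linearly with follow-up time: strongly
## protective at diagnosis, attenuating and eventually reversing. Times are
## drawn by inverse transform on the numerically integrated cumulative
## hazard, with administrative censoring at the follow-up horizon.

#' Baseline hazard specification
#'
#' @param dist `"exponential"` (constant rate) or `"weibull"`.
#' @param rate hazard rate per year for the exponential baseline.
#' @param shape,scale Weibull parameters, hazard
#'   `shape/scale * (t/scale)^(shape-1)`.
#' @return named list.
#' @export
baseline_hazard <- function(dist = c("exponential", "weibull"),
                            rate = 0.004, shape = 1.2, scale = 40) {
  dist <- match.arg(dist)
  if (dist == "exponential" && rate <= 0)
    stop_invalid("baseline rate must be positive")
  if (dist == "weibull" && (shape <= 0 || scale <= 0))
    stop_invalid("weibull shape and scale must be positive")
  list(dist = dist, rate = rate, shape = shape, scale = scale)
}

baseline_fn <- function(spec) {
  switch(spec$dist,
         exponential = function(t) rep(spec$rate, length(t)),
         weibull = function(t)
           spec$shape / spec$scale * (pmax(t, 1e-12) / spec$scale)^(spec$shape - 1))
}

#' Default covariate log hazard ratios for the survival generator
#'
#' Stage and grade effects of the size seen in breast-cancer cohort models
#' (stage II/III/IV vs I about 2.3/5.0/18.4, grade 2/3 vs 1 about 1.55/2.3,
#' no age effect).
#' @return named numeric vector.
#' @export
survival_covariate_effects <- function() {
  c(age = 0,
    stageII = log(2.32), stageIII = log(4.97), stageIV = log(18.39),
    grade2 = log(1.55), grade3 = log(2.30))
}

#' Simulate survival outcomes for a tumor table
#'
#' Adds `time` (years) and `event` (death) to a clinical table, with the ER
#' log hazard ratio equal to `beta1 + beta2 * t`. Censoring is uniform loss
#' to follow-up truncated by an administrative horizon (default 15 years).
#' Missing stage/grade contribute their covariate effect through the modal
#' category (the truth model is complete; missingness affects only what the
#' analyst sees).
#'
#' @param tumors clinical table from [simulate_tumors()]; ER status is taken
#'   from `er_col`.
#' @param beta1 ER log hazard ratio at diagnosis (default -1.41).
#' @param beta2 change in the ER log hazard ratio per year (default 0.21).
#' @param baseline see [baseline_hazard()].
#' @param effects covariate log hazard ratios
#'   (see [survival_covariate_effects()]).
#' @param horizon administrative censoring horizon in years (default 15).
#' @param loss_max upper bound of the uniform loss-to-follow-up time; larger
#'   values mean less random censoring (default 45, about one third censored
#'   before 15 years).
#' @param er_col column holding the ER indicator used in the hazard.
#' @param seed RNG seed.
#' @param grid_max,grid_n integration grid for the cumulative hazard.
#' @return `tumors` with `time` and `event` columns appended.
#' @export
simulate_survival <- function(tumors, beta1 = -1.41, beta2 = 0.21,
                              baseline = baseline_hazard(),
                              effects = survival_covariate_effects(),
                              horizon = 15, loss_max = 45,
                              er_col = "er_true", seed = 1L,
                              grid_max = 120, grid_n = 12000L) {
  check_columns(tumors, c(er_col, "age", "stage", "grade"), "tumor table")
  if (!is.finite(beta2)) stop_invalid("beta2 must be finite")
  if (horizon < 0) stop_invalid("censoring horizon must be non-negative")
  set.seed(seed)
  n <- nrow(tumors)
  er <- as.logical(tumors[[er_col]])

  stage <- as.character(tumors$stage); stage[is.na(stage)] <- "II"
  grade <- as.character(tumors$grade); grade[is.na(grade)] <- "2"
  lp <- effects["age"] * (tumors$age - mean(tumors$age)) +
    ifelse(stage == "II", effects["stageII"],
    ifelse(stage == "III", effects["stageIII"],
    ifelse(stage == "IV", effects["stageIV"], 0))) +
    ifelse(grade == "2", effects["grade2"],
    ifelse(grade == "3", effects["grade3"], 0))

  h0 <- baseline_fn(baseline)
  grid <- seq(0, grid_max, length.out = grid_n)
  dg <- diff(grid)
  cumtrap <- function(y) c(0, cumsum(dg * (head(y, -1) + y[-1]) / 2))
  H_neg <- cumtrap(h0(grid))                       # ER-negative base curve
  H_pos <- cumtrap(h0(grid) * exp(beta1 + beta2 * grid))

  E <- rexp(n)                                     # unit-exponential draws
  scale_i <- exp(lp)
  target <- E / scale_i
  t_ev <- numeric(n)
  for (g in c(FALSE, TRUE)) {
    idx <- which(er == g)
    if (!length(idx)) next
    H <- if (g) H_pos else H_neg
    t_ev[idx] <- approx(H, grid, xout = target[idx], rule = 1)$y
  }
  t_ev[is.na(t_ev)] <- Inf                         # beyond the grid: censored

  cens <- pmin(horizon, runif(n, 0, loss_max))
  tumors$time <- pmin(t_ev, cens)
  tumors$event <- t_ev <= cens
  tumors
}
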