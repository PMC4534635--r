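#' @importFrom stats approx coef median pnorm qnorm quantile rbinom rlnorm
#'   rnorm runif rexp rbeta rgamma sd var vcov cor qt setNames
#' @importFrom utils head modifyList
#' @importFrom data.table as.data.table :=
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Lower median of a numeric vector
#'
#' The order statistic at position `ceiling(n/2)`, so the result is always an
#' attained value. Ordinal crowd answers stay on their original integer scales
#' under this convention, unlike the midpoint convention of [stats::median()]
#' for even counts.
#'
#' @param x numeric vector, length >= 1.
#' @return an element of `x`.
#' @export
lower_median <- function(x) {
  if (length(x) == 0L) stop_invalid("lower_median: empty input")
  sort(x)[ceiling(length(x) / 2)]
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## tiny polynomial rolling hash over the deparsed object; used to stamp
## output files so a report and its inputs can be matched up. Not
## cryptographic.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

check_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_invalid("%s must be TRUE or FALSE", nm)
  x
}

check_count <- function(x, nm, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_invalid("%s must be a single integer >= %d", nm, min)
  as.integer(x)
}

check_number <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("%s must be a single finite number", nm)
  as.numeric(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_invalid("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", "))
  invisible(df)
}
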