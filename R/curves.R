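#' Log-spaced bin edges
#' @param from,to range of the abscissa.
#' @param per_decade bins per decade (default 20).
#' @return numeric vector of edges.
#' @export
log_bins <- function(from, to, per_decade = 20) {
  stopifnot(from > 0, to > from)
  n <- ceiling(log10(to / from) * per_decade)
  10^seq(log10(from), log10(to), length.out = n + 1)
}

# binned statistic container: abscissa mid, value, count
curve_table <- function(mid, value, n) {
  stopifnot(length(mid) == length(value), length(mid) == length(n))
  structure(data.frame(mid = mid, value = value, n = n),
            class = c("srev_curve", "data.frame"))
}

#' Log-log power-law slope of a binned curve
#'
#' Unweighted least-squares slope of `log(value)` against `log(mid)`
#' over a window of the abscissa.  Bins with missing values or zero
#' counts are dropped.
#'
#' @param curve a curve table (`data.frame` with `mid`, `value`, `n`).
#' @param window length-2 abscissa range (inclusive).
#' @return fitted slope (scalar).
#' @export
fit_loglog <- function(curve, window = range(curve$mid)) {
  keep <- is.finite(curve$value) & curve$value > 0 & curve$n > 0 &
    curve$mid >= window[1] & curve$mid <= window[2]
  if (sum(keep) < 3) stop("fewer than 3 usable bins in the fit window")
  unname(coef(lm(log(curve$value[keep]) ~ log(curve$mid[keep])))[2])
}
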