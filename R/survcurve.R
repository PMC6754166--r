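#' Monthly survival curve
#'
#' Construct a discrete-time survival curve on the monthly grid. The curve
#' stores the probability of being alive at integer months from model entry
#' (diagnosis), with \code{S(0) = 1}. All strategy comparisons in the package
#' reduce to transformations and mixtures of these objects.
#'
#' @param values Numeric vector of survival probabilities \code{S(0), S(1),
#'   ..., S(T)}. Must start at 1, be non-increasing and lie in \code{[0, 1]}.
#' @return An object of class \code{survcurve}: the numeric vector of
#'   probabilities with attribute \code{horizon} (the final month \code{T}).
#' @examples
#' s <- survival_curve(exp(-0.05 * 0:120))
#' life_expectancy(extend_to_zero(s))
#' @export
survival_curve <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || is.na(values[1L]) || abs(values[1L] - 1) > 1e-12)
    stop("survival curve must start at S(0) = 1")
  if (anyNA(values) || any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("survival probabilities must lie in [0, 1]")
  if (any(diff(values) > 1e-12))
    stop("survival curve must be non-increasing")
  values <- pmin(pmax(values, 0), 1)
  structure(values, horizon = length(values) - 1L, class = "survcurve")
}

#' @export
print.survcurve <- function(x, ...) {
  cat("Monthly survival curve: horizon", attr(x, "horizon"), "months\n")
  med <- tryCatch(median_survival(x), error = function(e) NA_real_)
  cat(sprintf("  S(12) = %.3f, S(60) = %.3f, median = %s months\n",
              if (length(x) > 12) x[13] else NA,
              if (length(x) > 60) x[61] else NA,
              ifelse(is.na(med), "not reached", format(med))))
  invisible(x)
}

#' Proportional-hazards adjustment of a survival curve
#'
#' Applies a hazard ratio to a discrete-time survival curve by scaling the
#' cumulative hazard, \code{S_adj(t) = S(t)^hr}. On the monthly grid this is
#' exact under proportional hazards and preserves all curve invariants.
#'
#' @param curve A \code{\link{survival_curve}}.
#' @param hr Positive hazard ratio relative to the curve's reference.
#' @return The adjusted \code{survcurve}.
#' @export
ph_adjust <- function(curve, hr) {
  if (!is.numeric(hr) || length(hr) != 1L || is.na(hr) || hr <= 0)
    stop("hazard ratio must be a positive number")
  survival_curve(unclass(curve)^hr)
}

#' Convert an annual death probability to a one-month cycle probability
#'
#' @param q_annual Annual probability of death in \code{[0, 1]}.
#' @return Monthly probability \code{1 - (1 - q_annual)^(1/12)}.
#' @export
monthly_hazard <- function(q_annual) {
  if (any(is.na(q_annual)) || any(q_annual < 0) || any(q_annual > 1))
    stop("annual death probability must lie in [0, 1]")
  1 - (1 - q_annual)^(1 / 12)
}

#' Mean life expectancy of a survival curve
#'
#' Half-cycle-corrected area under the monthly survival curve,
#' \code{sum_t (S(t-1) + S(t)) / 2}, in months. Equivalent to treating deaths
#' within a month as occurring at its midpoint. Warns when the curve has not
#' been run out to (near) zero, since the area is then truncated.
#'
#' @param curve A \code{\link{survival_curve}}.
#' @return Mean survival in months.
#' @export
life_expectancy <- function(curve) {
  v <- unclass(curve)
  n <- length(v)
  if (n < 2L) return(0)
  if (v[n] > 0.001)
    warning("curve does not reach zero; life expectancy is truncated")
  sum((v[-n] + v[-1L]) / 2)
}

#' Median survival of a survival curve
#'
#' The median is reported on the half-month grid: \code{m - 0.5} where
#' \code{m} is the first month at which \code{S(m) < 0.5}. With a one-month
#' cycle this is the natural midpoint convention and yields medians such as
#' 41.5 or 47.5 months.
#'
#' @param curve A \code{\link{survival_curve}}.
#' @return Median survival in months (a value on the half-month grid).
#' @export
median_survival <- function(curve) {
  v <- unclass(curve)
  m <- which(v < 0.5)[1L]
  if (is.na(m))
    stop("survival never falls below 0.5 within the horizon; median undefined")
  (m - 1L) - 0.5
}

#' Pad a survival curve with trailing zeros
#'
#' Used for curves that already reach zero before the model horizon (e.g. the
#' early surgical-death curve) so that curves can be mixed on a common grid.
#'
#' @param curve A \code{\link{survival_curve}}.
#' @param horizon Target horizon in months (\code{>=} current horizon).
#' @return The padded \code{survcurve}.
#' @export
extend_to_zero <- function(curve, horizon = attr(curve, "horizon")) {
  v <- unclass(curve)
  if (horizon + 1L < length(v)) stop("horizon shorter than curve")
  survival_curve(c(v, rep(0, horizon + 1L - length(v))))
}

#' Read / write a survival curve as CSV
#'
#' The on-disk format is a two-column CSV with header \code{month,survival}.
#'
#' @param path File path.
#' @return \code{read_curve} returns a \code{survcurve};
#'   \code{write_curve} returns \code{path} invisibly.
#' @export
read_curve <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("month", "survival") %in% names(d)))
    stop("curve CSV must have columns month,survival")
  d <- d[order(d$month), ]
  if (!identical(as.integer(d$month), seq(0L, nrow(d) - 1L)))
    stop("curve CSV months must be contiguous from 0")
  survival_curve(d$survival)
}

#' @rdname read_curve
#' @param curve A \code{\link{survival_curve}} to write.
#' @export
write_curve <- function(curve, path) {
  v <- unclass(curve)
  utils::write.csv(data.frame(month = seq_along(v) - 1L, survival = v),
                   path, row.names = FALSE)
  invisible(path)
}
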