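#' Annual all-cause lifetable
#'
#' A female all-cause lifetable mapping integer age in years to the annual
#' probability of death \code{qx}. It supplies the background mortality to
#' which cured patients are exposed. Survival is forced to zero once the
#' attained age reaches \code{max_age}.
#'
#' @param age Integer ages, contiguous.
#' @param qx Annual death probabilities in \code{[0, 1]}; the probability at
#'   \code{max_age} must be 1 (absorbing age).
#' @return An object of class \code{lifetable} (a data frame with columns
#'   \code{age}, \code{qx} and attribute \code{max_age}).
#' @export
lifetable <- function(age, qx) {
  age <- as.integer(age)
  o <- order(age)
  age <- age[o]; qx <- as.numeric(qx)[o]
  if (length(age) != length(qx) || length(age) < 2L)
    stop("age and qx must be vectors of equal length >= 2")
  if (!identical(age, seq(age[1L], age[length(age)])))
    stop("lifetable ages must be contiguous integers")
  if (anyNA(qx) || any(qx < 0) || any(qx > 1))
    stop("qx must lie in [0, 1]")
  if (qx[length(qx)] != 1)
    stop("qx at max_age must equal 1 (absorbing age)")
  structure(data.frame(age = age, qx = qx),
            max_age = age[length(age)], class = c("lifetable", "data.frame"))
}

lifetable_qx <- function(lt, ages) {
  idx <- match(pmin(ages, attr(lt, "max_age")), lt$age)
  if (anyNA(idx)) stop("age outside lifetable range")
  lt$qx[idx]
}

#' @rdname lifetable
#' @param path Path to a CSV file with header \code{age,qx}.
#' @export
read_lifetable <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(d)))
    stop("lifetable CSV must have columns age,qx")
  lifetable(d$age, d$qx)
}

#' @rdname lifetable
#' @param lt A \code{lifetable} to write.
#' @export
write_lifetable <- function(lt, path) {
  utils::write.csv(data.frame(age = lt$age, qx = lt$qx), path,
                   row.names = FALSE)
  invisible(path)
}

# Monthly background survival factors for months 1..T after entry:
# factor(t) = (1 - qx(attained age during month t))^(1/12), with the attained
# age taken as entry_age + floor((t - 1) / 12).
background_factors <- function(lt, entry_age, horizon) {
  t <- seq_len(horizon)
  ages <- entry_age + (t - 1L) %/% 12L
  1 - monthly_hazard(lifetable_qx(lt, ages))
}

#' Impose cure and background mortality on a survival curve
#'
#' Patients surviving \code{cure_years} after diagnosis are considered cured:
#' beyond the cure month their disease-specific curve is replaced by
#' background (all-cause) mortality from the lifetable at the attained age.
#' Background mortality before cure is assumed to be embodied in the
#' registry-derived (overall-survival) input curve and is not double counted.
#' The curve is extended to the month at which the attained age reaches the
#' lifetable's \code{max_age}, where survival is forced to zero.
#'
#' @param curve A \code{\link{survival_curve}} of overall survival from
#'   diagnosis.
#' @param cure_years Years after diagnosis at which survivors are cured
#'   (base case 12).
#' @param lt A \code{\link{lifetable}}.
#' @param entry_age Age in years at model entry (must be within the
#'   lifetable).
#' @return A \code{survcurve} with horizon \code{(max_age - entry_age) * 12}.
#' @export
apply_cure_and_background <- function(curve, cure_years, lt, entry_age) {
  if (cure_years <= 0) stop("cure_years must be positive")
  if (!entry_age %in% lt$age) stop("entry_age outside lifetable range")
  v <- unclass(curve)
  mc <- round(12 * cure_years)
  if (mc >= length(v) - 1L) return(curve)  # cure beyond horizon: no-op
  horizon <- (attr(lt, "max_age") - entry_age) * 12L
  fac <- background_factors(lt, entry_age, horizon)
  out <- numeric(horizon + 1L)
  out[seq_len(mc + 1L)] <- v[seq_len(mc + 1L)]
  if (horizon > mc)
    out[(mc + 2L):(horizon + 1L)] <- v[mc + 1L] * cumprod(fac[(mc + 1L):horizon])
  out[horizon + 1L] <- 0
  survival_curve(out)
}
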