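#' Synthetic female all-cause lifetable
#'
#' Generates a lifetable from a Gompertz-Makeham hazard,
#' \code{mu(age) = makeham + gompertz_a * exp(gompertz_b * age)}, converted to
#' annual death probabilities \code{qx = 1 - exp(-mu)}. The defaults are
#' chosen so that remaining life expectancy at age 63 falls in the 20-25 year
#' band typical of contemporary US female lifetables; they are a documented
#' emulation, not a fit to any published table.
#'
#' @param makeham Age-independent annual hazard component.
#' @param gompertz_a Level of the senescent hazard at age 0.
#' @param gompertz_b Log-slope of the senescent hazard per year of age.
#' @param min_age,max_age Age range; \code{qx(max_age)} is forced to 1.
#' @return A \code{\link{lifetable}}.
#' @examples
#' lt <- make_lifetable()
#' lt$qx[lt$age == 63]
#' @export
make_lifetable <- function(makeham = 5e-4, gompertz_a = 1.2e-5,
                           gompertz_b = 0.103, min_age = 0L, max_age = 110L) {
  if (makeham < 0 || gompertz_a < 0 || gompertz_b < 0)
    stop("Gompertz-Makeham parameters must be non-negative")
  age <- seq(min_age, max_age)
  mu <- makeham + gompertz_a * exp(gompertz_b * age)
  qx <- 1 - exp(-mu)
  qx[length(qx)] <- 1
  lifetable(age, qx)
}

#' Remaining life expectancy under a lifetable
#'
#' Annual-step expectation of remaining years at a given age, with half-cycle
#' correction; used to sanity-check synthetic lifetables.
#'
#' @param lt A \code{\link{lifetable}}.
#' @param age Starting age.
#' @return Expected remaining years.
#' @export
lifetable_expectancy <- function(lt, age) {
  ages <- seq(age, attr(lt, "max_age"))
  surv <- cumprod(1 - lifetable_qx(lt, ages))
  s <- c(1, surv)
  sum((s[-1] + s[-length(s)]) / 2) - 0.5
}

#' Synthetic registry-style patient extract
#'
#' Emulates the structure of a registry extract of stage IIIC ovarian cancer
#' patients: one row per patient with diagnosis age, treatment arm,
#' cytoreduction status, follow-up in months and a death indicator. Death
#' times for the reference pathway (NACT+ICS with complete/optimal
#' cytoreduction, standard IV chemotherapy) are drawn from the mixture-cure
#' Weibull baseline \code{theta} with cure and background mortality applied;
#' independent uniform administrative censoring is superimposed.
#'
#' @param params A \code{\link{model_params}} (supplies lifetable, entry age,
#'   cure time, horizon).
#' @param theta Baseline curve parameters, see \code{\link{baseline_curve}}.
#' @param n Number of patients.
#' @param censoring_rate Proportion of patients administratively censored at
#'   a Uniform(0, horizon) time.
#' @param seed Integer RNG seed (required for reproducibility).
#' @return A data frame with columns \code{id, diagnosis_age, arm,
#'   cytoreduction, followup_months, death_indicator}.
#' @export
make_registry_extract <- function(params, theta = params$baseline_theta,
                                  n = 10000L, censoring_rate = 0,
                                  seed = 1L) {
  stopifnot(n >= 1, censoring_rate >= 0, censoring_rate <= 1)
  set.seed(as.integer(seed))
  horizon <- model_horizon(params)
  base <- baseline_curve(theta, horizon)
  curve <- apply_cure_and_background(base, params$cure_years,
                                     params$lifetable, params$entry_age)
  death <- sample_death_months(unclass(curve), n)
  fup <- death
  event <- rep(1L, n)
  cens <- stats::runif(n) < censoring_rate
  ct <- ceiling(stats::runif(n) * horizon)
  trunc <- cens & ct < death
  fup[trunc] <- ct[trunc]
  event[trunc] <- 0L
  data.frame(id = seq_len(n),
             diagnosis_age = params$entry_age,
             arm = "NACT_ICS",
             cytoreduction = "COMPLETE_OPTIMAL",
             followup_months = fup,
             death_indicator = event)
}

# Inverse-transform sampling of integer death months from a monthly survival
# vector that ends at zero: P(M = m) = S(m-1) - S(m).
sample_death_months <- function(v, n) {
  pmf <- -diff(v)
  pmf <- pmf / sum(pmf)
  sample.int(length(pmf), n, replace = TRUE, prob = pmf)
}
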