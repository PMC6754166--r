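#' Individual-level Monte Carlo simulation of a strategy
#'
#' Simulates patients one at a time through the decision tree: each patient
#' draws a pathway according to the enumerated pathway probabilities, then a
#' death month from that pathway's survival curve by inverse transform on
#' the monthly grid. Life expectancy and median survival use the same
#' half-cycle conventions as the deterministic solver (a death in month
#' \code{m} contributes \code{m - 0.5} months of life). Runs are
#' bit-reproducible for a fixed seed.
#'
#' @param params Calibrated \code{\link{model_params}}.
#' @param strategy A \code{\link{strategy_config}}.
#' @param n Number of simulated patients.
#' @param seed Integer RNG seed.
#' @return List with \code{le_months}, \code{le_se} (Monte Carlo standard
#'   error), \code{median_months}, \code{curve} (Kaplan-Meier estimate of
#'   the simulated cohort) and \code{patients} (data frame: \code{id},
#'   \code{arm}, \code{cytoreduction}, \code{regimen}, \code{death_month},
#'   \code{cause}).
#' @export
simulate_cohort <- function(params, strategy, n = 100000L, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  set.seed(as.integer(seed))
  paths <- enumerate_pathways(params, strategy)
  cache <- curve_cache(params)
  idx <- sample.int(nrow(paths), n, replace = TRUE,
                    prob = paths$probability)
  death <- integer(n)
  for (i in seq_len(nrow(paths))) {
    who <- which(idx == i)
    if (!length(who)) next
    v <- if (paths$kind[i] == "SURGICAL_DEATH") cache$surgical
         else cache$curve_for_hr(paths$hr_total[i])
    death[who] <- sample_death_months(v, length(who))
  }
  cause <- ifelse(paths$kind[idx] == "SURGICAL_DEATH", "surgical",
                  ifelse(death > cache$cure_month, "background_after_cure",
                         "cancer_other"))
  patients <- data.frame(id = seq_len(n), arm = paths$arm[idx],
                         cytoreduction = paths$cytoreduction[idx],
                         regimen = paths$regimen[idx],
                         death_month = death, cause = cause)
  km <- km_estimate(patients, horizon = cache$horizon)
  list(le_months = mean(death) - 0.5,
       le_se = stats::sd(death) / sqrt(n),
       median_months = median_survival(km),
       curve = km, patients = patients)
}

#' Kaplan-Meier estimate of a simulated cohort
#'
#' Product-limit estimate of the survival of simulated (or registry-style)
#' patients, evaluated on the monthly grid. Without censoring this equals
#' the empirical survival function. The estimate itself is delegated to
#' \code{\link[survival]{survfit}}.
#'
#' @param patients Data frame with a \code{death_month} column and,
#'   optionally, an \code{event} column (1 = death, 0 = censored; all deaths
#'   if absent). \code{\link{make_registry_extract}} output is accepted via
#'   its \code{followup_months}/\code{death_indicator} columns.
#' @param horizon Last month of the output grid (default: last observed
#'   time).
#' @return A \code{\link{survival_curve}}.
#' @export
km_estimate <- function(patients, horizon = NULL) {
  if (!nrow(patients)) stop("at least one patient required")
  if ("followup_months" %in% names(patients)) {
    time <- patients$followup_months
    event <- patients$death_indicator
  } else {
    time <- patients$death_month
    event <- if ("event" %in% names(patients)) patients$event
             else rep(1L, nrow(patients))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  if (is.null(horizon)) horizon <- max(time)
  step <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  # S(t) = P(T > t): survfit's right-continuous step evaluated at t.
  survival_curve(pmin(1, cummin(step(0:horizon))))
}

#' Write simulated patients to CSV
#'
#' @param patients Patient data frame from \code{\link{simulate_cohort}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_patients <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE)
  invisible(path)
}
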