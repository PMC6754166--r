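# Shared machinery for turning pathway hazard multipliers into monthly
# survival curves. All treated/partial curves are powers of the same baseline
# before the cure month and share the same background-mortality tail after
# it, so a per-parameter-set cache avoids recomputing them.
curve_cache <- function(params) {
  horizon <- model_horizon(params)
  base <- baseline_curve(params$baseline_theta, horizon)
  logS <- log(unclass(base))
  mc <- round(12 * params$cure_years)
  if (mc > horizon) mc <- horizon
  fac <- background_factors(params$lifetable, params$entry_age, horizon)
  bg_tail <- if (mc < horizon) cumprod(fac[(mc + 1L):horizon]) else numeric(0)
  surg <- extend_to_zero(survival_curve(c(1, 2 / 3, 1 / 3, 0)), horizon)
  env <- new.env(parent = emptyenv())
  list(
    horizon = horizon, cure_month = mc, surgical = unclass(surg),
    curve_for_hr = function(hr) {
      key <- sprintf("%.15g", hr)
      if (!is.null(env[[key]])) return(env[[key]])
      v <- exp(hr * logS)
      if (mc < horizon) {
        v[(mc + 2L):(horizon + 1L)] <- v[mc + 1L] * bg_tail
        v[horizon + 1L] <- 0
      }
      env[[key]] <- v
      v
    })
}

pathway_curves_matrix <- function(paths, cache) {
  vapply(seq_len(nrow(paths)), function(i) {
    if (paths$kind[i] == "SURGICAL_DEATH") cache$surgical
    else cache$curve_for_hr(paths$hr_total[i])
  }, numeric(cache$horizon + 1L))
}

#' Survival curve of a single decision-tree pathway
#'
#' Treated and partial-treatment pathways apply the leaf's total hazard
#' multiplier to the baseline curve and then impose cure and background
#' mortality. Surgical-death pathways place death uniformly over months 1-3
#' (90-day surgical mortality).
#'
#' @param pathway One row of \code{\link{enumerate_pathways}} output.
#' @param params A calibrated \code{\link{model_params}}.
#' @return A \code{\link{survival_curve}} on the model horizon.
#' @export
pathway_curve <- function(pathway, params) {
  cache <- curve_cache(params)
  if (pathway$kind == "SURGICAL_DEATH") survival_curve(cache$surgical)
  else survival_curve(cache$curve_for_hr(pathway$hr_total))
}

#' Deterministic cohort solution of a strategy
#'
#' Computes the exact expected outcome of a strategy by mixing the survival
#' curves of all decision-tree pathways by their probabilities:
#' \code{S_mix(t) = sum_i p_i S_i(t)}. Life expectancy and median survival
#' are read off the mixture curve; as an internal consistency check, the
#' mixture life expectancy is verified against the probability-weighted sum
#' of per-pathway life expectancies (to 1e-9 months).
#'
#' @param params A calibrated \code{\link{model_params}}.
#' @param strategy A \code{\link{strategy_config}}.
#' @param cache Optional precomputed \code{curve_cache}; callers evaluating
#'   many strategies under identical survival parameters may share one.
#' @return An object of class \code{ovc_result}: list with \code{le_months},
#'   \code{median_months}, \code{curve} (the mixture \code{survcurve}) and
#'   \code{pathway_table} (per-leaf probability and life expectancy).
#' @export
solve_strategy <- function(params, strategy, cache = NULL) {
  paths <- enumerate_pathways(params, strategy)
  if (is.null(cache)) cache <- curve_cache(params)
  curves <- pathway_curves_matrix(paths, cache)
  mix <- as.vector(curves %*% paths$probability)
  mix_curve <- survival_curve(mix)
  le <- life_expectancy(mix_curve)
  per_le <- apply(curves, 2L, function(v) life_expectancy(survival_curve(v)))
  if (abs(le - sum(paths$probability * per_le)) > 1e-9)
    stop("internal error: mixture LE disagrees with pathway-weighted LE")
  paths$le_months <- per_le
  structure(list(strategy = strategy$name,
                 le_months = le,
                 median_months = median_survival(mix_curve),
                 curve = mix_curve,
                 pathway_table = paths),
            class = "ovc_result")
}

#' @export
print.ovc_result <- function(x, ...) {
  cat(sprintf("Strategy '%s': LE %.1f months, median survival %.1f months\n",
              x$strategy, x$le_months, x$median_months))
  invisible(x)
}

#' Compare strategies against current practice
#'
#' Solves each strategy deterministically and tabulates life expectancy and
#' median survival with their differences from the \code{current_practice}
#' strategy, which must be among those supplied.
#'
#' @param params A calibrated \code{\link{model_params}}.
#' @param strategies Named list of \code{\link{strategy_config}} objects
#'   including one named \code{current_practice} (default: the five analysed
#'   strategies).
#' @return Data frame with columns \code{strategy}, \code{le_months},
#'   \code{median_months}, \code{delta_le}, \code{delta_median}.
#' @export
compare_strategies <- function(params, strategies = table1_strategies(params)) {
  if (!"current_practice" %in% names(strategies))
    stop("strategies must include 'current_practice'")
  cache <- curve_cache(params)
  res <- lapply(strategies, function(s) solve_strategy(params, s, cache))
  out <- data.frame(
    strategy = names(strategies),
    le_months = vapply(res, `[[`, 0, "le_months"),
    median_months = vapply(res, `[[`, 0, "median_months"),
    row.names = NULL)
  cp <- out[out$strategy == "current_practice", ]
  out$delta_le <- out$le_months - cp$le_months
  out$delta_median <- out$median_months - cp$median_months
  out
}

#' Write strategy comparison results
#'
#' Writes the comparison table as CSV preceded by comment lines recording
#' the full parameter set in effect, and one \code{month,survival} CSV per
#' strategy for survival-curve plotting.
#'
#' @param params A calibrated \code{\link{model_params}}.
#' @param comparison Output of \code{\link{compare_strategies}}.
#' @param dir Output directory (created if needed).
#' @param curves Logical; also write per-strategy mixture curves.
#' @param strategies Strategy list matching \code{comparison}.
#' @return \code{dir}, invisibly.
#' @export
write_results <- function(params, comparison, dir,
                          strategies = table1_strategies(params),
                          curves = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "strategies.csv")
  con <- file(path, "w")
  writeLines(params_header(params), con)
  utils::write.csv(comparison, con, row.names = FALSE)
  close(con)
  if (curves) {
    cache <- curve_cache(params)
    for (nm in names(strategies)) {
      r <- solve_strategy(params, strategies[[nm]], cache)
      write_curve(r$curve, file.path(dir, paste0("curve_", nm, ".csv")))
    }
  }
  invisible(dir)
}

params_header <- function(params) {
  th <- params$baseline_theta
  c(sprintf("# ovcsim parameters: entry_age=%d p_pcs=%g p_continue_pcs=%g p_continue_nact=%g",
            params$entry_age, params$p_pcs, params$p_continue_pcs,
            params$p_continue_nact),
    sprintf("#   surg_mort_pcs=%g surg_mort_ics=%g p_subopt_pcs=%g p_opt_nact=%g cure_years=%g",
            params$surg_mort_pcs, params$surg_mort_ics, params$p_subopt_pcs,
            params$p_opt_nact, params$cure_years),
    sprintf("#   ip_uptake=%g bev_uptake=%g dose_dense_share=%g",
            params$current_ip_uptake, params$current_bev_uptake,
            params$dose_dense_share_pcs),
    sprintf("#   regimen_hr: %s", paste(names(params$regimen_hr),
                                        params$regimen_hr, sep = "=",
                                        collapse = " ")),
    sprintf("#   pathway_hr: %s", paste(names(params$pathway_hr),
                                        signif(params$pathway_hr, 6),
                                        sep = "=", collapse = " ")),
    sprintf("#   baseline_theta: scale=%g shape=%g cure_fraction=%g",
            th$scale, th$shape, th$cure_fraction))
}
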