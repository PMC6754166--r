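#' Model parameters
#'
#' Assembles the full parameter set of the decision model for post-operative
#' chemotherapy in stage IIIC epithelial ovarian cancer. Printed inputs
#' (triage, continuation and surgical-mortality probabilities, regimen hazard
#' ratios, uptake rates) carry their base-case values; the unprinted inputs
#' (the baseline survival curve and the pathway-level hazard multipliers)
#' default to \code{NA} and are recovered by \code{\link{calibrate}}.
#'
#' @param entry_age Age at model entry, years.
#' @param p_pcs Probability of triage to primary cytoreductive surgery (PCS);
#'   the complement is neoadjuvant chemotherapy followed by interval surgery
#'   (NACT+ICS).
#' @param p_continue_pcs Probability that a PCS patient (surviving surgery)
#'   continues to adjuvant chemotherapy.
#' @param p_continue_nact Probability that a NACT patient continues to ICS.
#' @param surg_mort_pcs,surg_mort_ics 90-day surgical mortality after PCS and
#'   ICS.
#' @param p_subopt_pcs Probability of suboptimal cytoreduction among PCS
#'   patients reaching chemotherapy.
#' @param p_opt_nact Probability of complete/optimal cytoreduction at ICS
#'   (unprinted; calibrated).
#' @param cure_years Years after diagnosis at which survivors are considered
#'   cured and subject only to background mortality.
#' @param current_ip_uptake Proportion of eligible PCS patients receiving
#'   IP+IV chemotherapy under current practice.
#' @param current_bev_uptake Proportion of suboptimally cytoreduced PCS
#'   patients receiving bevacizumab+IV under current practice.
#' @param dose_dense_share_pcs Share of all PCS patients receiving dose-dense
#'   chemotherapy in the dose-dense scenario.
#' @param regimen_hr Named vector of overall-survival hazard ratios versus
#'   standard IV chemotherapy for the five regimens.
#' @param pathway_hr Named vector of hazard multipliers, relative to the
#'   reference pathway (NACT+ICS, complete/optimal cytoreduction, full
#'   treatment), for each (arm, cytoreduction) cell and for partial
#'   treatment. Calibrated; the reference entry is fixed at 1.
#' @param baseline_theta Baseline mixture-cure Weibull parameters
#'   (\code{scale}, \code{shape}, \code{cure_fraction}); calibrated.
#' @param lifetable A \code{\link{lifetable}} for background mortality; the
#'   synthetic default emulates a contemporary US female table.
#' @return An object of class \code{ovc_params} (a named list).
#' @seealso \code{\link{calibrate}}, \code{\link{solve_strategy}}
#' @export
model_params <- function(entry_age = 63L,
                         p_pcs = 0.745,
                         p_continue_pcs = 0.907,
                         p_continue_nact = 0.821,
                         surg_mort_pcs = 0.040,
                         surg_mort_ics = 0.023,
                         p_subopt_pcs = 0.11,
                         p_opt_nact = NA_real_,
                         cure_years = 12,
                         current_ip_uptake = 0.41,
                         current_bev_uptake = 0.04,
                         dose_dense_share_pcs = 0.152,
                         regimen_hr = c(STANDARD_IV = 1, IP_IV = 0.75,
                                        BEV_IV = 0.85, HIPEC_IV = 0.67,
                                        DOSE_DENSE_IV = 0.79),
                         pathway_hr = c(PCS.COMPLETE_OPTIMAL = NA_real_,
                                        PCS.SUBOPTIMAL = NA_real_,
                                        NACT_ICS.COMPLETE_OPTIMAL = 1,
                                        NACT_ICS.SUBOPTIMAL = NA_real_,
                                        PARTIAL = NA_real_),
                         baseline_theta = list(scale = NA_real_,
                                               shape = NA_real_,
                                               cure_fraction = NA_real_),
                         lifetable = make_lifetable()) {
  p <- list(entry_age = as.integer(entry_age), p_pcs = p_pcs,
            p_nact = 1 - p_pcs, p_continue_pcs = p_continue_pcs,
            p_continue_nact = p_continue_nact, surg_mort_pcs = surg_mort_pcs,
            surg_mort_ics = surg_mort_ics, p_subopt_pcs = p_subopt_pcs,
            p_opt_nact = p_opt_nact, cure_years = cure_years,
            current_ip_uptake = current_ip_uptake,
            current_bev_uptake = current_bev_uptake,
            dose_dense_share_pcs = dose_dense_share_pcs,
            regimen_hr = regimen_hr, pathway_hr = pathway_hr,
            baseline_theta = baseline_theta, lifetable = lifetable)
  validate_params(p)
  structure(p, class = "ovc_params")
}

validate_params <- function(p) {
  probs <- c(p$p_pcs, p$p_continue_pcs, p$p_continue_nact, p$surg_mort_pcs,
             p$surg_mort_ics, p$p_subopt_pcs, p$current_ip_uptake,
             p$current_bev_uptake, p$dose_dense_share_pcs)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (!is.na(p$p_opt_nact) && (p$p_opt_nact < 0 || p$p_opt_nact > 1))
    stop("p_opt_nact must lie in [0, 1]")
  if (p$cure_years <= 0) stop("cure_years must be positive")
  need <- c("STANDARD_IV", "IP_IV", "BEV_IV", "HIPEC_IV", "DOSE_DENSE_IV")
  if (!all(need %in% names(p$regimen_hr)))
    stop("regimen_hr must name all five regimens")
  if (any(!is.na(p$regimen_hr) & p$regimen_hr <= 0))
    stop("regimen hazard ratios must be positive")
  if (!"NACT_ICS.COMPLETE_OPTIMAL" %in% names(p$pathway_hr) ||
      p$pathway_hr[["NACT_ICS.COMPLETE_OPTIMAL"]] != 1)
    stop("pathway_hr must fix the reference pathway at exactly 1")
  if (!inherits(p$lifetable, "lifetable")) stop("lifetable required")
  if (!p$entry_age %in% p$lifetable$age)
    stop("entry_age outside lifetable range")
  invisible(p)
}

#' Override parameters of a model
#'
#' Returns a copy of a parameter set with named elements replaced; scenario
#' analyses use this so the base parameters are never mutated. Nested
#' elements (\code{regimen_hr}, \code{pathway_hr}, \code{baseline_theta})
#' may be overridden entry-wise with names like \code{regimen_hr.BEV_IV}.
#'
#' @param params An \code{ovc_params} object.
#' @param ... Named overrides, e.g. \code{cure_years = 8},
#'   \code{regimen_hr.IP_IV = 0.59}.
#' @return A new \code{ovc_params} object.
#' @export
set_params <- function(params, ...) {
  ov <- list(...)
  if (length(ov) == 0L) return(params)
  if (is.null(names(ov)) || any(names(ov) == ""))
    stop("all overrides must be named")
  p <- unclass(params)
  for (key in names(ov)) {
    if (grepl(".", key, fixed = TRUE)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      top <- parts[1L]; sub <- paste(parts[-1L], collapse = ".")
      if (!top %in% names(p) || !sub %in% names(p[[top]]))
        stop("unknown parameter: ", key)
      p[[top]][[sub]] <- ov[[key]]
    } else {
      if (!key %in% names(p)) stop("unknown parameter: ", key)
      p[[key]] <- ov[[key]]
      if (key == "p_pcs") p$p_nact <- 1 - ov[[key]]
    }
  }
  validate_params(p)
  structure(p, class = "ovc_params")
}

model_horizon <- function(params) {
  (attr(params$lifetable, "max_age") - params$entry_age) * 12L
}

params_calibrated <- function(params) {
  !anyNA(unlist(params$baseline_theta)) && !anyNA(params$pathway_hr) &&
    !is.na(params$p_opt_nact)
}

#' @export
print.ovc_params <- function(x, ...) {
  cat("Ovarian cancer chemotherapy model parameters\n")
  cat(sprintf("  entry age %d y; PCS %.1f%% / NACT+ICS %.1f%%; cure at %g y\n",
              x$entry_age, 100 * x$p_pcs, 100 * x$p_nact, x$cure_years))
  cat("  regimen HRs: ",
      paste(sprintf("%s=%.2f", names(x$regimen_hr), x$regimen_hr),
            collapse = ", "), "\n", sep = "")
  if (params_calibrated(x)) {
    cat(sprintf("  baseline: scale %.2f mo, shape %.3f, cure fraction %.3f\n",
                x$baseline_theta$scale, x$baseline_theta$shape,
                x$baseline_theta$cure_fraction))
    cat("  pathway HRs: ",
        paste(sprintf("%s=%.3f", names(x$pathway_hr), x$pathway_hr),
              collapse = ", "), "\n", sep = "")
  } else {
    cat("  baseline curve / pathway HRs: uncalibrated (run calibrate())\n")
  }
  invisible(x)
}

#' Write / read model parameters as YAML
#'
#' Round-trips an \code{ovc_params} object through a versioned YAML schema
#' (lifetable inline as parallel \code{age}/\code{qx} arrays). Unknown keys
#' are rejected on read so that typos in hazard ratios cannot silently alter
#' results.
#'
#' @param params An \code{ovc_params} object.
#' @param path File path.
#' @return \code{read_params} returns an \code{ovc_params};
#'   \code{write_params} returns \code{path} invisibly.
#' @export
write_params <- function(params, path) {
  obj <- list(schema = "ovcsim-params/1",
              entry_age = params$entry_age,
              p_pcs = params$p_pcs,
              p_continue_pcs = params$p_continue_pcs,
              p_continue_nact = params$p_continue_nact,
              surg_mort_pcs = params$surg_mort_pcs,
              surg_mort_ics = params$surg_mort_ics,
              p_subopt_pcs = params$p_subopt_pcs,
              p_opt_nact = params$p_opt_nact,
              cure_years = params$cure_years,
              current_ip_uptake = params$current_ip_uptake,
              current_bev_uptake = params$current_bev_uptake,
              dose_dense_share_pcs = params$dose_dense_share_pcs,
              regimen_hr = as.list(params$regimen_hr),
              pathway_hr = as.list(params$pathway_hr),
              baseline_theta = params$baseline_theta,
              lifetable = list(age = params$lifetable$age,
                               qx = params$lifetable$qx))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema, "ovcsim-params/1"))
    stop("unsupported or missing params schema (expected ovcsim-params/1)")
  known <- c("schema", "entry_age", "p_pcs", "p_continue_pcs",
             "p_continue_nact", "surg_mort_pcs", "surg_mort_ics",
             "p_subopt_pcs", "p_opt_nact", "cure_years", "current_ip_uptake",
             "current_bev_uptake", "dose_dense_share_pcs", "regimen_hr",
             "pathway_hr", "baseline_theta", "lifetable")
  extra <- setdiff(names(obj), known)
  if (length(extra))
    stop("unknown keys in params file: ", paste(extra, collapse = ", "))
  null2na <- function(x) if (is.null(x)) NA_real_ else x
  model_params(entry_age = obj$entry_age, p_pcs = obj$p_pcs,
               p_continue_pcs = obj$p_continue_pcs,
               p_continue_nact = obj$p_continue_nact,
               surg_mort_pcs = obj$surg_mort_pcs,
               surg_mort_ics = obj$surg_mort_ics,
               p_subopt_pcs = obj$p_subopt_pcs,
               p_opt_nact = null2na(obj$p_opt_nact),
               cure_years = obj$cure_years,
               current_ip_uptake = obj$current_ip_uptake,
               current_bev_uptake = obj$current_bev_uptake,
               dose_dense_share_pcs = obj$dose_dense_share_pcs,
               regimen_hr = vapply(obj$regimen_hr, null2na, 0),
               pathway_hr = vapply(obj$pathway_hr, null2na, 0),
               baseline_theta = lapply(obj$baseline_theta, null2na),
               lifetable = lifetable(obj$lifetable$age, obj$lifetable$qx))
}
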