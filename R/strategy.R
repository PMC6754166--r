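ARMS <- c("PCS", "NACT_ICS")
CYTO <- c("COMPLETE_OPTIMAL", "SUBOPTIMAL")
REGIMENS <- c("STANDARD_IV", "IP_IV", "BEV_IV", "HIPEC_IV", "DOSE_DENSE_IV")

#' Chemotherapy strategy configuration
#'
#' A strategy assigns, for each (treatment arm, cytoreduction status) cell, a
#' probability distribution over chemotherapy regimens. The five analysed
#' strategies are built by \code{\link{table1_strategies}}; an
#' \code{implementation_fraction} below 1 models imperfect adoption, with the
#' shortfall in every non-standard regimen reverting to standard IV
#' chemotherapy.
#'
#' @param name Strategy identifier.
#' @param assignment Nested named list \code{assignment[[arm]][[cyto]]}, each
#'   element a named probability vector over regimens summing to 1.
#' @param implementation_fraction Fraction of patients in each cell who
#'   actually receive the cell's non-standard regimen(s).
#' @param dose_dense_mode Logical flag recording that the assignment was
#'   built under the dose-dense scenario.
#' @return An object of class \code{ovc_strategy}.
#' @export
strategy_config <- function(name, assignment, implementation_fraction = 1,
                            dose_dense_mode = FALSE) {
  if (implementation_fraction < 0 || implementation_fraction > 1)
    stop("implementation_fraction must lie in [0, 1]")
  for (arm in ARMS) {
    if (!arm %in% names(assignment)) stop("assignment missing arm ", arm)
    for (cy in CYTO) {
      cell <- assignment[[arm]][[cy]]
      if (is.null(cell)) stop("assignment missing cell ", arm, "/", cy)
      if (!all(names(cell) %in% REGIMENS))
        stop("unknown regimen in cell ", arm, "/", cy)
      if (any(cell < 0) || abs(sum(cell) - 1) > 1e-9)
        stop("cell ", arm, "/", cy, " probabilities must sum to 1")
    }
  }
  structure(list(name = name, assignment = assignment,
                 implementation_fraction = implementation_fraction,
                 dose_dense_mode = dose_dense_mode),
            class = "ovc_strategy")
}

#' @export
print.ovc_strategy <- function(x, ...) {
  cat("Strategy:", x$name,
      if (x$implementation_fraction < 1)
        sprintf("(implementation %.0f%%)", 100 * x$implementation_fraction),
      if (x$dose_dense_mode) "(dose-dense scenario)", "\n")
  for (arm in ARMS) for (cy in CYTO) {
    cell <- assign_regimen(x, arm, cy)
    cat(sprintf("  %s / %s: %s\n", arm, cy,
                paste(sprintf("%s %.1f%%", names(cell), 100 * cell),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Regimen distribution for a strategy cell
#'
#' Returns the probability distribution over regimens for one (arm,
#' cytoreduction) cell, after applying the strategy's implementation
#' fraction: each non-standard regimen probability is multiplied by the
#' fraction and the remainder reverts to standard IV chemotherapy.
#'
#' @param strategy An \code{\link{strategy_config}}.
#' @param arm \code{"PCS"} or \code{"NACT_ICS"}.
#' @param cytoreduction \code{"COMPLETE_OPTIMAL"} or \code{"SUBOPTIMAL"}.
#' @return Named probability vector over regimens (entries sum to 1).
#' @export
assign_regimen <- function(strategy, arm, cytoreduction) {
  arm <- match.arg(arm, ARMS)
  cytoreduction <- match.arg(cytoreduction, CYTO)
  cell <- strategy$assignment[[arm]][[cytoreduction]]
  f <- strategy$implementation_fraction
  if (f < 1) {
    nonstd <- setdiff(names(cell), "STANDARD_IV")
    cell[nonstd] <- cell[nonstd] * f
    cell["STANDARD_IV"] <- 1 - sum(cell[nonstd])
  }
  cell[cell > 0]
}

cp_assignment <- function(params, dose_dense = FALSE) {
  ip <- params$current_ip_uptake
  bev <- params$current_bev_uptake
  a <- list(
    PCS = list(
      COMPLETE_OPTIMAL = c(IP_IV = ip, STANDARD_IV = 1 - ip),
      SUBOPTIMAL = c(BEV_IV = bev, STANDARD_IV = 1 - bev)),
    NACT_ICS = list(
      COMPLETE_OPTIMAL = c(STANDARD_IV = 1),
      SUBOPTIMAL = c(STANDARD_IV = 1)))
  if (dose_dense) a <- substitute_dose_dense(a, params)
  a
}

# Dose-dense scenario, current practice: a fixed share of ALL PCS patients
# receives dose-dense instead of standard IV. Only patients reaching
# chemotherapy can receive it, and it is drawn from the standard-IV pool,
# uniformly across cytoreduction cells.
substitute_dose_dense <- function(a, params) {
  share_cont <- params$dose_dense_share_pcs /
    ((1 - params$surg_mort_pcs) * params$p_continue_pcs)
  std_mass <- (1 - params$p_subopt_pcs) *
    a$PCS$COMPLETE_OPTIMAL["STANDARD_IV"] +
    params$p_subopt_pcs * a$PCS$SUBOPTIMAL["STANDARD_IV"]
  frac <- share_cont / std_mass
  if (is.na(frac) || frac > 1)
    stop("dose-dense share exceeds the available standard-IV pool")
  for (cy in CYTO) {
    std <- a$PCS[[cy]]["STANDARD_IV"]
    a$PCS[[cy]]["DOSE_DENSE_IV"] <- unname(std * frac)
    a$PCS[[cy]]["STANDARD_IV"] <- unname(std * (1 - frac))
  }
  a
}

#' The five analysed chemotherapy strategies
#'
#' Builds the strategy set compared in the primary analysis: current
#' practice; full optimized implementation (IP+IV for complete/optimal PCS,
#' bevacizumab+IV for suboptimal PCS, HIPEC+IV for complete/optimal
#' NACT+ICS); and the three single-component strategies that optimize IP+IV,
#' bevacizumab+IV or HIPEC alone with everything else at current-practice
#' rates.
#'
#' @param params A \code{\link{model_params}} (supplies current uptake
#'   rates).
#' @param implementation_fraction Implementation fraction for the optimized
#'   strategies (1 in the primary analysis; 0.6-0.9 in the imperfect-
#'   implementation scenarios).
#' @param dose_dense Logical; build the dose-dense scenario variants of
#'   current practice and optimized implementation.
#' @return Named list of \code{\link{strategy_config}} objects.
#' @export
table1_strategies <- function(params, implementation_fraction = 1,
                              dose_dense = FALSE) {
  list(current_practice = strategy_current_practice(params, dose_dense),
       optimized = strategy_optimized(params, implementation_fraction,
                                      dose_dense),
       optimized_ip = strategy_component(params, "ip"),
       optimized_bev = strategy_component(params, "bev"),
       optimized_hipec = strategy_component(params, "hipec"))
}

#' @rdname table1_strategies
#' @export
strategy_current_practice <- function(params, dose_dense = FALSE) {
  strategy_config("current_practice", cp_assignment(params, dose_dense),
                  dose_dense_mode = dose_dense)
}

#' @rdname table1_strategies
#' @export
strategy_optimized <- function(params, implementation_fraction = 1,
                               dose_dense = FALSE) {
  a <- list(
    PCS = list(
      COMPLETE_OPTIMAL = c(IP_IV = 1),
      SUBOPTIMAL = if (dose_dense) c(DOSE_DENSE_IV = 1) else c(BEV_IV = 1)),
    NACT_ICS = list(
      COMPLETE_OPTIMAL = c(HIPEC_IV = 1),
      SUBOPTIMAL = c(STANDARD_IV = 1)))
  strategy_config("optimized", a,
                  implementation_fraction = implementation_fraction,
                  dose_dense_mode = dose_dense)
}

#' @rdname table1_strategies
#' @param component One of \code{"ip"}, \code{"bev"}, \code{"hipec"}: the
#'   single cell set to 100\% uptake, all else at current practice.
#' @export
strategy_component <- function(params, component = c("ip", "bev", "hipec")) {
  component <- match.arg(component)
  a <- cp_assignment(params)
  if (component == "ip") {
    a$PCS$COMPLETE_OPTIMAL <- c(IP_IV = 1)
  } else if (component == "bev") {
    a$PCS$SUBOPTIMAL <- c(BEV_IV = 1)
  } else {
    a$NACT_ICS$COMPLETE_OPTIMAL <- c(HIPEC_IV = 1)
  }
  strategy_config(paste0("optimized_", component), a)
}

#' Enumerate the decision-tree pathways of a strategy
#'
#' Expands the full decision tree for one strategy into its leaves. For PCS:
#' 90-day surgical mortality, then continuation to adjuvant chemotherapy
#' (non-continuers receive partial treatment), then cytoreduction status,
#' then regimen. For NACT: continuation to ICS (non-continuers receive
#' partial treatment without surgery), then 90-day surgical mortality, then
#' cytoreduction status, then regimen. Each treated leaf's total hazard
#' multiplier is the pathway hazard ratio for its (arm, cytoreduction) cell
#' times the regimen hazard ratio; partial-treatment leaves carry the shared
#' partial-treatment multiplier and no regimen.
#'
#' @param params A \code{\link{model_params}} with pathway hazard ratios set
#'   (calibrated or supplied).
#' @param strategy A \code{\link{strategy_config}}.
#' @return Data frame with one row per leaf: \code{arm}, \code{cytoreduction},
#'   \code{regimen}, \code{kind} (\code{SURGICAL_DEATH}, \code{TREATED} or
#'   \code{PARTIAL}), \code{probability}, \code{hr_total}. Probabilities sum
#'   to 1.
#' @export
enumerate_pathways <- function(params, strategy) {
  ph <- params$pathway_hr
  if (anyNA(ph) || is.na(params$p_opt_nact))
    stop("pathway hazard ratios / NACT cytoreduction split are unset; ",
         "run calibrate() or supply them explicitly")
  arm_v <- character(0); cy_v <- character(0); reg_v <- character(0)
  kind_v <- character(0); prob_v <- numeric(0); hr_v <- numeric(0)
  add <- function(arm, cy, reg, kind, prob, hr) {
    arm_v[length(arm_v) + 1L] <<- arm
    cy_v[length(cy_v) + 1L] <<- cy
    reg_v[length(reg_v) + 1L] <<- reg
    kind_v[length(kind_v) + 1L] <<- kind
    prob_v[length(prob_v) + 1L] <<- prob
    hr_v[length(hr_v) + 1L] <<- hr
  }

  treated_rows <- function(arm, reach, p_cyto) {
    for (cy in CYTO) {
      key <- paste(arm, cy, sep = ".")
      if (!key %in% names(ph)) stop("missing pathway_hr key: ", key)
      cell <- assign_regimen(strategy, arm, cy)
      for (reg in names(cell))
        add(arm, cy, reg, "TREATED", reach * p_cyto[[cy]] * cell[[reg]],
            unname(ph[[key]] * params$regimen_hr[[reg]]))
    }
  }

  # PCS arm: surgery -> 90-day mortality -> continuation -> cytoreduction
  p_pcs_surv <- params$p_pcs * (1 - params$surg_mort_pcs)
  add("PCS", NA_character_, NA_character_, "SURGICAL_DEATH",
      params$p_pcs * params$surg_mort_pcs, NA_real_)
  add("PCS", NA_character_, NA_character_, "PARTIAL",
      p_pcs_surv * (1 - params$p_continue_pcs), ph[["PARTIAL"]])
  treated_rows("PCS", p_pcs_surv * params$p_continue_pcs,
               list(COMPLETE_OPTIMAL = 1 - params$p_subopt_pcs,
                    SUBOPTIMAL = params$p_subopt_pcs))

  # NACT arm: continuation to ICS -> 90-day mortality -> cytoreduction
  add("NACT_ICS", NA_character_, NA_character_, "PARTIAL",
      params$p_nact * (1 - params$p_continue_nact), ph[["PARTIAL"]])
  p_ics <- params$p_nact * params$p_continue_nact
  add("NACT_ICS", NA_character_, NA_character_, "SURGICAL_DEATH",
      p_ics * params$surg_mort_ics, NA_real_)
  treated_rows("NACT_ICS", p_ics * (1 - params$surg_mort_ics),
               list(COMPLETE_OPTIMAL = params$p_opt_nact,
                    SUBOPTIMAL = 1 - params$p_opt_nact))

  out <- data.frame(arm = arm_v, cytoreduction = cy_v, regimen = reg_v,
                    kind = kind_v, probability = prob_v, hr_total = hr_v,
                    stringsAsFactors = FALSE)
  if (abs(sum(out$probability) - 1) > 1e-12)
    stop("internal error: pathway probabilities do not sum to 1")
  out
}
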