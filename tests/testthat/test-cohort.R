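test_that("single-pathway tree reproduces that pathway's statistics", {
  p <- test_params(p_pcs = 1, surg_mort_pcs = 0, p_continue_pcs = 1,
                   p_subopt_pcs = 0)
  s <- strategy_optimized(p)
  r <- solve_strategy(p, s)
  path <- enumerate_pathways(p, s)
  path <- path[path$probability > 0, ][1, ]
  cv <- pathway_curve(path, p)
  expect_equal(r$le_months, life_expectancy(cv))
  expect_equal(r$median_months, median_survival(cv))
  expect_equal(curve_vals(r$curve), curve_vals(cv))
})

test_that("mixture LE equals the probability-weighted pathway LEs", {
  p <- test_params()
  for (s in table1_strategies(p)) {
    r <- solve_strategy(p, s)
    expect_equal(r$le_months,
                 sum(r$pathway_table$probability * r$pathway_table$le_months),
                 tolerance = 1e-9)
  }
})

test_that("two-pathway exponential mixture matches the closed-form mean", {
  # degenerate strategy: only complete/optimal PCS treated leaves survive,
  # with an exponential baseline (shape 1, no plateau) and no cure/background
  lt <- flat_lifetable(0, 60, 130)
  lam <- 1 / 40
  p <- test_params(p_pcs = 1, surg_mort_pcs = 0, p_continue_pcs = 1,
                   p_subopt_pcs = 0.5, entry_age = 60, lifetable = lt,
                   cure_years = 70,
                   baseline_theta = list(scale = 1 / lam, shape = 1,
                                         cure_fraction = 0),
                   pathway_hr = c(PCS.COMPLETE_OPTIMAL = 1,
                                  PCS.SUBOPTIMAL = 2,
                                  NACT_ICS.COMPLETE_OPTIMAL = 1,
                                  NACT_ICS.SUBOPTIMAL = 1, PARTIAL = 1))
  s <- strategy_config("two_leaf", list(
    PCS = list(COMPLETE_OPTIMAL = c(STANDARD_IV = 1),
               SUBOPTIMAL = c(STANDARD_IV = 1)),
    NACT_ICS = list(COMPLETE_OPTIMAL = c(STANDARD_IV = 1),
                    SUBOPTIMAL = c(STANDARD_IV = 1))))
  r <- solve_strategy(p, s)
  # mixture of exp(lam) and exp(2 lam) with weights 0.5/0.5
  expect_equal(r$le_months, 0.5 / lam + 0.5 / (2 * lam), tolerance = 0.01)
})

test_that("comparison table is zero for current practice and invariant at HR 1", {
  p <- test_params()
  cmp <- compare_strategies(p)
  cp <- cmp[cmp$strategy == "current_practice", ]
  expect_equal(cp$delta_le, 0)
  expect_equal(cp$delta_median, 0)
  # all regimen HRs = 1: chemotherapy choice becomes irrelevant
  p1 <- test_params(regimen_hr = c(STANDARD_IV = 1, IP_IV = 1, BEV_IV = 1,
                                   HIPEC_IV = 1, DOSE_DENSE_IV = 1))
  cmp1 <- compare_strategies(p1)
  expect_equal(cmp1$delta_le, rep(0, nrow(cmp1)), tolerance = 1e-12)
  expect_equal(cmp1$delta_median, rep(0, nrow(cmp1)))
  expect_equal(length(unique(round(cmp1$le_months, 9))), 1L)
})

test_that("LE is monotone non-increasing in every hazard ratio", {
  p <- test_params()
  base <- solve_strategy(p, strategy_optimized(p))$le_months
  keys <- c("regimen_hr.IP_IV", "regimen_hr.HIPEC_IV",
            "pathway_hr.PCS.COMPLETE_OPTIMAL", "pathway_hr.PARTIAL")
  bases <- c(p$regimen_hr[["IP_IV"]], p$regimen_hr[["HIPEC_IV"]],
             p$pathway_hr[["PCS.COMPLETE_OPTIMAL"]],
             p$pathway_hr[["PARTIAL"]])
  for (i in seq_along(keys)) {
    key <- keys[i]
    up <- do.call(set_params,
                  stats::setNames(list(p, bases[i] * 1.3), c("params", key)))
    dn <- do.call(set_params,
                  stats::setNames(list(p, bases[i] * 0.7), c("params", key)))
    expect_lt(solve_strategy(up, strategy_optimized(up))$le_months, base)
    expect_gt(solve_strategy(dn, strategy_optimized(dn))$le_months, base)
  }
})

test_that("solver output is invariant to pathway leaf ordering", {
  p <- test_params()
  s <- strategy_current_practice(p)
  paths <- enumerate_pathways(p, s)
  cache <- ovcsim:::curve_cache(p)
  perm <- rev(seq_len(nrow(paths)))
  curves <- ovcsim:::pathway_curves_matrix(paths[perm, ], cache)
  mix <- survival_curve(as.vector(curves %*% paths$probability[perm]))
  r <- solve_strategy(p, s)
  expect_equal(curve_vals(mix), curve_vals(r$curve), tolerance = 1e-12)
})

test_that("results directory contains headers and per-strategy curves", {
  p <- test_params()
  dir <- withr::local_tempdir()
  cmp <- compare_strategies(p)
  write_results(p, cmp, dir)
  lines <- readLines(file.path(dir, "strategies.csv"))
  expect_true(any(grepl("^# ovcsim parameters", lines)))
  back <- utils::read.csv(file.path(dir, "strategies.csv"), comment.char = "#")
  expect_equal(back$le_months, cmp$le_months, tolerance = 1e-6)
  cv <- read_curve(file.path(dir, "curve_current_practice.csv"))
  expect_equal(curve_vals(cv), curve_vals(solve_strategy(p, strategy_current_practice(p))$curve),
               tolerance = 1e-6)
})
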