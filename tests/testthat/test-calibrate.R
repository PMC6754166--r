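test_that("baseline curve family evaluates its closed form", {
  th <- list(scale = 40, shape = 1.2, cure_fraction = 0.2)
  cv <- baseline_curve(th, 120)
  expect_equal(curve_vals(cv)[1], 1)
  expect_equal(curve_vals(cv)[41], 0.2 + 0.8 * exp(-1))
  # no plateau, shape 1 reduces to the exponential
  ex <- baseline_curve(list(scale = 20, shape = 1, cure_fraction = 0), 60)
  expect_equal(curve_vals(ex), exp(-(0:60) / 20), tolerance = 1e-12)
  expect_error(baseline_curve(list(scale = -1, shape = 1, cure_fraction = 0),
                              10), "positive")
  expect_error(baseline_curve(list(scale = NA, shape = 1, cure_fraction = 0),
                              10), "unset")
})

test_that("a single free scale parameter matches a single LE target exactly", {
  truth <- test_params(baseline_theta = list(scale = 52, shape = 1.4,
                                             cure_fraction = 0.03))
  target_le <- solve_strategy(truth, strategy_current_practice(truth))$le_months
  targets <- data.frame(strategy = "current_practice", statistic = "LE",
                        value = target_le, weight = 1)
  est <- test_params()  # same params, scale to be recovered
  fix <- c(shape = 1.4, cure_fraction = 0.03, hr_pcs_opt = 0.9,
           hr_pcs_sub = 1.3, hr_nact_sub = 2.6, hr_partial = 0.6,
           p_opt_nact = 0.8)
  cal <- calibrate(est, targets,
                   starts = list(c(scale = 30), c(scale = 70)), fix = fix,
                   tol = 0.05)
  expect_true(cal$converged)
  expect_equal(cal$estimates[["scale"]], 52, tolerance = 1e-3)
  expect_equal(cal$residuals$fitted, target_le, tolerance = 1e-4)
})

test_that("calibration reproduces targets generated from known parameters", {
  truth <- test_params(baseline_theta = list(scale = 47, shape = 1.4,
                                             cure_fraction = 0))
  cmp <- compare_strategies(truth)
  targets <- data.frame(
    strategy = rep(cmp$strategy, each = 2),
    statistic = rep(c("LE", "median"), nrow(cmp)),
    value = as.vector(rbind(cmp$le_months, cmp$median_months)),
    weight = rep(c(1, 0.5), nrow(cmp)))
  cal <- calibrate(model_params(), targets)
  le_res <- cal$residuals[cal$residuals$statistic == "LE", ]
  expect_lt(max(abs(le_res$residual)), 0.01)
  med_res <- cal$residuals[cal$residuals$statistic == "median", ]
  expect_equal(med_res$fitted, med_res$value)
})

test_that("calibration is deterministic and surfaces sensitivities", {
  targets <- primary_targets()[1:2, ]  # one LE + one median target
  fix <- c(shape = 1.4, cure_fraction = 0, hr_pcs_sub = 1.3,
           hr_nact_sub = 2.6, hr_partial = 0.6, p_opt_nact = 0.8)
  starts <- list(c(scale = 40, hr_pcs_opt = 1),
                 c(scale = 60, hr_pcs_opt = 1.5))
  a <- calibrate(model_params(), targets, starts = starts, fix = fix)
  b <- calibrate(model_params(), targets, starts = starts, fix = fix)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$residuals, b$residuals)
  # objective trace of best-so-far values is non-increasing
  expect_true(all(diff(a$trace) <= 0))
  J <- a$jacobian
  expect_equal(dim(J), c(2L, 8L))
  # LE responds to the baseline scale; fixed plateau column is reported too
  expect_gt(abs(J["current_practice:LE", "scale"]), 0)
})

test_that("infeasible targets are rejected, not silently fitted", {
  bad <- data.frame(strategy = "current_practice", statistic = "LE",
                    value = 1e5, weight = 1)
  expect_error(calibrate(model_params(), bad), "horizon")
})

test_that("targets round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(primary_targets(), path, row.names = FALSE)
  expect_equal(read_targets(path), primary_targets())
  bad <- data.frame(strategy = "x", statistic = "mean", value = 1, weight = 1)
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_targets(path), "LE")
})
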