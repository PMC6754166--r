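test_that("scenario runs leave the base parameters untouched", {
  p <- test_params()
  snapshot <- unclass(p)
  invisible(run_hr_sensitivity(p))
  invisible(run_structural_sensitivity(p))
  invisible(run_partial_implementation(p))
  invisible(run_dose_dense(p))
  expect_identical(unclass(p), snapshot)
})

test_that("hazard-ratio sensitivity agrees with the primary run at base values", {
  p <- test_params()
  primary <- run_primary(p)
  gain <- primary$delta_le[primary$strategy == "optimized"]
  sens <- run_hr_sensitivity(p, bounds = list(IP_IV = c(0.75, 0.75)))
  expect_equal(sens$delta_le[sens$bound == "low"], gain, tolerance = 1e-9)
  # null bevacizumab must lower the gain relative to base (BEV HR < 1)
  bev <- run_hr_sensitivity(p, bounds = list(BEV_IV = c(0.74, 0.96)))
  expect_lt(bev$delta_le[bev$bound == "null"], gain)
  # lower HR bound gives the larger gain
  ip <- run_hr_sensitivity(p, bounds = list(IP_IV = c(0.59, 0.97)))
  expect_gt(ip$delta_le[ip$bound == "low"], ip$delta_le[ip$bound == "high"])
})

test_that("structural sensitivity reverts to the primary analysis at base values", {
  p <- test_params()
  primary <- run_primary(p)
  gain <- primary$delta_le[primary$strategy == "optimized"]
  # uptake scenario evaluated at 100% of base equals the primary gain
  p100 <- set_params(p, current_ip_uptake = p$current_ip_uptake)
  s <- run_structural_sensitivity(p100)
  expect_true(all(c("cure_8y", "cure_16y", "ip_uptake_50", "ip_uptake_150")
                  %in% s$scenario))
  # higher current uptake shrinks the headroom for optimization
  expect_lt(s$delta_le[s$scenario == "ip_uptake_150"],
            s$delta_le[s$scenario == "ip_uptake_50"])
  expect_lt(abs(gain - mean(s$delta_le[grepl("uptake", s$scenario)])), 3)
})

test_that("partial implementation interpolates monotonically to full optimization", {
  p <- test_params()
  tab <- run_partial_implementation(p, fractions = c(0, 0.3, 0.6, 0.9, 1))
  expect_true(all(diff(tab$le_months) > 0))
  expect_true(all(diff(tab$delta_le) > 0))
  primary <- run_primary(p)
  expect_equal(tab$le_months[tab$fraction == 1],
               primary$le_months[primary$strategy == "optimized"])
  # f = 0: every treated patient on standard IV; gain can be negative but
  # must equal the all-standard strategy exactly
  cell <- c(STANDARD_IV = 1)
  allstd <- strategy_config("all_standard", list(
    PCS = list(COMPLETE_OPTIMAL = cell, SUBOPTIMAL = cell),
    NACT_ICS = list(COMPLETE_OPTIMAL = cell, SUBOPTIMAL = cell)))
  expect_equal(tab$le_months[tab$fraction == 0],
               solve_strategy(p, allstd)$le_months)
})

test_that("dose-dense scenario reverts toward base when its HR is 1", {
  p <- test_params()
  primary <- run_primary(p)
  dd <- run_dose_dense(p)
  p1 <- set_params(p, regimen_hr.DOSE_DENSE_IV = 1)
  dd1 <- run_dose_dense(p1)
  expect_equal(dd1$le_months[dd1$strategy == "current_practice"],
               primary$le_months[primary$strategy == "current_practice"],
               tolerance = 1e-9)
  # with a real benefit (HR 0.79 < 1) current practice improves
  expect_gt(dd$le_months[dd$strategy == "current_practice"],
            primary$le_months[primary$strategy == "current_practice"])
})

test_that("experiment tables are identical across reruns", {
  p <- test_params()
  expect_identical(run_primary(p), run_primary(p))
  expect_identical(run_hr_sensitivity(p), run_hr_sensitivity(p))
  expect_identical(run_partial_implementation(p),
                   run_partial_implementation(p))
})
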