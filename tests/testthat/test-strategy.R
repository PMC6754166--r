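test_that("strategy cells reproduce the published assignment table", {
  p <- test_params()
  st <- table1_strategies(p)
  expect_equal(assign_regimen(st$current_practice, "PCS", "COMPLETE_OPTIMAL"),
               c(IP_IV = 0.41, STANDARD_IV = 0.59))
  expect_equal(assign_regimen(st$current_practice, "PCS", "SUBOPTIMAL"),
               c(BEV_IV = 0.04, STANDARD_IV = 0.96))
  expect_equal(assign_regimen(st$optimized, "NACT_ICS", "SUBOPTIMAL"),
               c(STANDARD_IV = 1))
  expect_equal(assign_regimen(st$optimized, "PCS", "COMPLETE_OPTIMAL"),
               c(IP_IV = 1))
  expect_equal(assign_regimen(st$optimized_hipec, "NACT_ICS",
                              "COMPLETE_OPTIMAL"),
               c(HIPEC_IV = 1))
})

test_that("implementation fraction scales non-standard regimens toward standard IV", {
  p <- test_params()
  s06 <- strategy_optimized(p, implementation_fraction = 0.6)
  expect_equal(assign_regimen(s06, "PCS", "SUBOPTIMAL"),
               c(BEV_IV = 0.6, STANDARD_IV = 0.4))
  expect_equal(assign_regimen(s06, "NACT_ICS", "COMPLETE_OPTIMAL"),
               c(HIPEC_IV = 0.6, STANDARD_IV = 0.4))
  # f = 1 recovers the published cells
  s1 <- strategy_optimized(p, implementation_fraction = 1)
  expect_equal(assign_regimen(s1, "PCS", "SUBOPTIMAL"), c(BEV_IV = 1))
  # f = 0 collapses to all-standard treatment
  s0 <- strategy_optimized(p, implementation_fraction = 0)
  for (arm in c("PCS", "NACT_ICS"))
    for (cy in c("COMPLETE_OPTIMAL", "SUBOPTIMAL"))
      expect_equal(assign_regimen(s0, arm, cy), c(STANDARD_IV = 1))
  expect_error(strategy_optimized(p, implementation_fraction = 1.2),
               "\\[0, 1\\]")
})

test_that("pathway enumeration follows the stated branch order", {
  p <- test_params()
  paths <- enumerate_pathways(p, strategy_current_practice(p))
  expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
  # hand-multiplied branch product for the bevacizumab leaf
  bev <- paths[paths$kind == "TREATED" & paths$regimen == "BEV_IV", ]
  expect_equal(bev$probability, 0.745 * (1 - 0.040) * 0.907 * 0.11 * 0.04)
  expect_equal(bev$hr_total, 1.3 * 0.85)
  # surgical-death mass: PCS 4.0% plus ICS 2.3% among continuers
  expect_equal(sum(paths$probability[paths$kind == "SURGICAL_DEATH"]),
               0.745 * 0.04 + 0.255 * 0.821 * 0.023)
  # partial-treatment leaves use the shared partial multiplier, no regimen
  part <- paths[paths$kind == "PARTIAL", ]
  expect_equal(nrow(part), 2L)
  expect_true(all(part$hr_total == 0.6))
  expect_true(all(is.na(part$regimen)))
})

test_that("degenerate tree collapses to a single pathway", {
  p <- test_params(p_pcs = 1, surg_mort_pcs = 0, p_continue_pcs = 1,
                   p_subopt_pcs = 0)
  paths <- enumerate_pathways(p, strategy_optimized(p))
  paths <- paths[paths$probability > 0, ]
  expect_equal(nrow(paths), 1L)
  expect_equal(paths$probability, 1)
  expect_equal(paths$hr_total, 0.9 * 0.75)  # PCS-complete pathway HR x IP HR
})

test_that("pathway probabilities sum to one across random parameter draws", {
  set.seed(42)
  for (i in 1:20) {
    p <- test_params(p_pcs = runif(1), p_continue_pcs = runif(1),
                     p_continue_nact = runif(1),
                     surg_mort_pcs = runif(1, 0, 0.2),
                     surg_mort_ics = runif(1, 0, 0.2),
                     p_subopt_pcs = runif(1), p_opt_nact = runif(1))
    for (s in table1_strategies(p))
      expect_equal(sum(enumerate_pathways(p, s)$probability), 1,
                   tolerance = 1e-12)
  }
})

test_that("dose-dense substitution draws the target share from the standard pool", {
  p <- test_params()
  s <- strategy_current_practice(p, dose_dense = TRUE)
  paths <- enumerate_pathways(p, s)
  dd <- sum(paths$probability[paths$regimen == "DOSE_DENSE_IV" &
                                !is.na(paths$regimen)])
  # 15.2% of all PCS patients receive dose-dense chemotherapy
  expect_equal(dd / p$p_pcs, 0.152, tolerance = 1e-12)
  # drawn only from the standard-IV pool: IP and bevacizumab mass unchanged
  base <- enumerate_pathways(p, strategy_current_practice(p))
  for (reg in c("IP_IV", "BEV_IV")) {
    expect_equal(sum(paths$probability[paths$regimen == reg & !is.na(paths$regimen)]),
                 sum(base$probability[base$regimen == reg & !is.na(base$regimen)]))
  }
  # optimized variant: suboptimal PCS patients get dose-dense instead of bev
  so <- strategy_optimized(p, dose_dense = TRUE)
  expect_equal(assign_regimen(so, "PCS", "SUBOPTIMAL"), c(DOSE_DENSE_IV = 1))
})

test_that("surgical-death pathway curve is uniform over months 1-3", {
  p <- test_params()
  paths <- enumerate_pathways(p, strategy_current_practice(p))
  surg <- paths[paths$kind == "SURGICAL_DEATH", ][1, ]
  cv <- pathway_curve(surg, p)
  expect_equal(unclass(cv)[1:5], c(1, 2 / 3, 1 / 3, 0, 0))
  expect_equal(life_expectancy(cv), 1.5)
})
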