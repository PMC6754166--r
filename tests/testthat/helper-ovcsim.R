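# Shared fixtures. test_params() is a fully specified parameter set with
# hand-chosen (not calibrated) survival inputs, so engine tests are fast and
# independent of the calibration stage. cached_calibration() runs the real
# calibration once per test session and memoizes it.

test_params <- function(...) {
  p <- model_params(
    p_opt_nact = 0.8,
    pathway_hr = c(PCS.COMPLETE_OPTIMAL = 0.9, PCS.SUBOPTIMAL = 1.3,
                   NACT_ICS.COMPLETE_OPTIMAL = 1, NACT_ICS.SUBOPTIMAL = 2.6,
                   PARTIAL = 0.6),
    baseline_theta = list(scale = 47, shape = 1.4, cure_fraction = 0.03))
  set_params(p, ...)
}

.ovcsim_test_env <- new.env(parent = emptyenv())

cached_calibration <- function() {
  if (is.null(.ovcsim_test_env$cal))
    .ovcsim_test_env$cal <- calibrate(model_params())
  .ovcsim_test_env$cal
}

# Small lifetable with constant annual mortality, handy for closed-form
# background-mortality oracles.
flat_lifetable <- function(q = 0, min_age = 60L, max_age = 80L) {
  qx <- rep(q, max_age - min_age + 1L)
  qx[length(qx)] <- 1
  lifetable(seq(min_age, max_age), qx)
}

expon_curve <- function(lambda, horizon) survival_curve(exp(-lambda * 0:horizon))

# strip class/attributes for value comparisons
curve_vals <- function(x) as.vector(unclass(x))
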