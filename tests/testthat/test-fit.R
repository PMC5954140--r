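noiseless_curve <- function(model, n_lags = 64, lo = -5, hi = -1,
                            kind = "gg") {
  lags <- 10^seq(lo, hi, length.out = n_lags)
  new_curve(kind, lags, model_eval(model, lags))
}

test_that("noiseless curves are inverted to machine precision", {
  truth <- fccs_model(N = 5, tau = 2e-4, s = 5)
  cu <- noiseless_curve(truth)
  ft <- suppressWarnings(fit_curve(cu, components = 1, s = 5,
                                   drop_first = 0))
  expect_true(ft$converged)
  expect_rel(coef(ft)["N"], 5, 1e-6)
  expect_rel(coef(ft)["tau1"], 2e-4, 1e-6)
  expect_lt(ft$reduced_chi_square, 1e-12)

  # two components plus triplet, all free except s
  truth2 <- fccs_model(N = 2, tau = c(1e-4, 5e-3), fractions = c(0.4, 0.6),
                       s = 5, triplet_fraction = 0.15, triplet_time = 3e-6)
  cu2 <- noiseless_curve(truth2, n_lags = 96, lo = -6.5, hi = -0.5)
  ft2 <- suppressWarnings(fit_curve(cu2, components = 2, s = 5,
                                    triplet = TRUE, drop_first = 0))
  expect_true(ft2$converged)
  for (p in c("N", "tau1", "tau2", "F1", "T", "tauT")) {
    truth_val <- c(N = 2, tau1 = 1e-4, tau2 = 5e-3, F1 = 0.4,
                   T = 0.15, tauT = 3e-6)[p]
    expect_rel(coef(ft2)[p], truth_val, 1e-5)
  }
})

test_that("refitting from the optimum does not move the estimates", {
  truth <- fccs_model(N = 5, tau = 2e-4, s = 5)
  cu <- noiseless_curve(truth)
  # start somewhere wrong, then refit from the optimum
  ft <- suppressWarnings(fit_curve(cu, components = 1, s = 5, drop_first = 0,
                                   init = fccs_model(N = 50, tau = 1e-2,
                                                     s = 5)))
  ft2 <- suppressWarnings(fit_curve(cu, components = 1, s = 5,
                                    drop_first = 0, init = ft$model))
  expect_lt(max(abs(coef(ft2)[ft2$free] / coef(ft)[ft$free] - 1)), 1e-9)
})

test_that("fixed parameters are honoured and reported", {
  truth <- fccs_model(N = 5, tau = 2e-4, s = 5)
  cu <- noiseless_curve(truth)
  ft <- suppressWarnings(fit_curve(cu, components = 1, s = 5,
                                   fixed = list(N = 4), drop_first = 0))
  expect_identical(unname(coef(ft)["N"]), 4)
  expect_false("N" %in% ft$free)
  expect_true("s" %in% names(ft$fixed))
})

test_that("overfitting a 1-component truth is detected as degeneracy", {
  truth <- fccs_model(N = 5, tau = 1e-3, s = 5)
  cu <- noiseless_curve(truth, n_lags = 96)
  ft <- suppressWarnings(fit_curve(cu, components = 2, s = 5,
                                   drop_first = 0))
  fr <- ft$model$fractions
  taus <- ft$model$tau
  expect_true(max(fr) >= 0.95 || max(taus) / min(taus) < 2)
  expect_true(summary(ft)$degenerate)
})

test_that("parameters are recovered from simulated single-species traces", {
  hits <- sapply(61:64, function(sd) {
    cfg <- quick_config(seed = sd, mean_count = 300, duration = 4,
                        box = c(6, 6, 6), diffusion = 50)
    tr <- simulate_trace(cfg)
    cu <- segment_errors(tr, "gg", n_segments = 10)
    ft <- fit_curve(cu, components = 1, s = 5)
    n_eff <- effective_particle_number(cfg$species[[1]], cfg$optics,
                                       cfg$box)
    c(N_ok = abs(coef(ft)["N"] / n_eff - 1) < 0.15,
      tau_ok = abs(coef(ft)["tau1"] / tau_d_true(50) - 1) < 0.2)
  })
  expect_gte(sum(hits["N_ok.N", ]), 3)
  expect_gte(sum(hits["tau_ok.tau1", ]), 3)
})

test_that("weighted fits fall back to unweighted with a warning", {
  truth <- fccs_model(N = 5, tau = 2e-4, s = 5)
  cu <- noiseless_curve(truth)
  expect_warning(fit_curve(cu, components = 1, s = 5, drop_first = 0),
                 "unweighted")
  cu0 <- new_curve("gg", cu$lags, cu$values,
                   stderr = rep(0, length(cu$lags)))
  expect_warning(fit_curve(cu0, components = 1, s = 5, drop_first = 0),
                 "unweighted")
})

test_that("structure-parameter calibration inverts noiseless dye curves", {
  truth <- fccs_model(N = 3, tau = 4e-5, s = 5)
  cu <- noiseless_curve(truth, lo = -6.5, hi = -2)
  cal <- suppressWarnings(calibrate_structure_parameter(cu, known_D = 400,
                                                        drop_first = 0))
  expect_rel(cal$s, 5, 1e-6)
  expect_rel(cal$tau_d, 4e-5, 1e-6)
  # w0 = sqrt(4 D tauD): halving D shrinks w0 by sqrt(2), s unchanged
  expect_equal(cal$w0, sqrt(4 * 400 * 4e-5), tolerance = 1e-6)
  cal2 <- suppressWarnings(calibrate_structure_parameter(cu, known_D = 200,
                                                         drop_first = 0))
  expect_equal(cal2$w0, cal$w0 / sqrt(2), tolerance = 1e-6)
  expect_equal(cal2$s, cal$s, tolerance = 1e-6)
})

test_that("a floating baseline absorbs a constant curve depression", {
  truth <- fccs_model(N = 2, tau = 4e-4, s = 5)
  lags <- 10^seq(-5, -1.5, length.out = 72)
  depressed <- model_eval(truth, lags) - 0.004   # finite-length offset
  cu <- new_curve("gg", lags, depressed)
  plain <- suppressWarnings(fit_curve(cu, components = 1, s = NULL,
                                      drop_first = 0))
  with_base <- suppressWarnings(fit_curve(cu, components = 1, s = NULL,
                                          drop_first = 0,
                                          offset_free = TRUE))
  expect_equal(unname(coef(with_base)["G_inf"]), 0.996, tolerance = 1e-5)
  expect_rel(coef(with_base)["N"], 2, 1e-4)
  expect_rel(coef(with_base)["s"], 5, 1e-3)
  # without the baseline the offset corrupts the structure parameter
  expect_gt(abs(coef(plain)["s"] / 5 - 1),
            abs(coef(with_base)["s"] / 5 - 1))
})

test_that("fit methods expose the usual modelling interface", {
  truth <- fccs_model(N = 5, tau = 2e-4, s = 5)
  cu <- noiseless_curve(truth)
  ft <- suppressWarnings(fit_curve(cu, components = 1, s = 5,
                                   drop_first = 0))
  expect_equal(predict(ft), fitted(ft))
  expect_equal(unname(predict(ft, 0)), 1 + 1 / coef(ft)[["N"]],
               tolerance = 1e-9)
  expect_equal(residuals(ft), ft$values - fitted(ft))
  expect_lt(deviance(ft), 1e-10)
  expect_equal(dim(vcov(ft)), c(2L, 2L))
  expect_output(print(summary(ft)), "reduced chi-square")
  sims <- simulate(ft, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "fccs_curve")
})
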