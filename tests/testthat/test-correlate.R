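test_that("hand-computed correlation values are reproduced", {
  # constant trace: fluctuations vanish, G = 1 at every lag
  cu <- correlate_direct(tiny_trace(c(5, 5, 5, 5)), "gg", max_lag_bins = 1)
  expect_identical(cu$values, c(1, 1))
  # two-bin green trace: mean 2, dI = (-1, +1), G(0) = 1 + 1/4
  cu <- correlate_direct(tiny_trace(c(1, 3)), "gg", max_lag_bins = 0)
  expect_equal(cu$values, 1.25)
  # perfect anticorrelation between channels at lag 0
  cu <- correlate_direct(tiny_trace(c(1, 3), c(3, 1)), "gr",
                         max_lag_bins = 0)
  expect_equal(cu$values, 0.75)
})

test_that("zero-mean channels and oversized lags are rejected", {
  expect_error(correlate_direct(tiny_trace(c(0, 0, 0, 0)), "gg",
                                max_lag_bins = 1), "zero-mean")
  expect_error(correlate_direct(tiny_trace(c(1, 2, 3, 4)), "gg",
                                max_lag_bins = 2), "max_lag")
})

test_that("cross-correlation is symmetric in the channel order", {
  tr <- simulate_trace(mixture_config(0.5, seed = 4, duration = 0.5))
  swapped <- tiny_trace(tr$counts_red, tr$counts_green,
                        bin_time = tr$bin_time)
  a <- correlate_direct(tr, "gr", max_lag_bins = 50)
  b <- correlate_direct(swapped, "gr", max_lag_bins = 50)
  expect_lt(abs(a$values[1] - b$values[1]), 1e-9)   # lag 0 exactly shared
  expect_lt(max(abs(a$values[-1] - b$values[-1])), 5 * sd(a$values[-1]))
})

test_that("multi-tau values equal the direct estimator at shared lags", {
  tr <- simulate_trace(quick_config(seed = 12, duration = 0.5))
  mt <- correlate_multitau(tr, "gg")
  dir_max <- max(mt$lags) / tr$bin_time
  dr <- correlate_direct(tr, "gg", max_lag_bins = dir_max)
  shared <- match(round(mt$lags / tr$bin_time), round(dr$lags / tr$bin_time))
  rel <- abs(mt$values - dr$values[shared]) /
    pmax(abs(dr$values[shared]), 1e-12)
  expect_lt(max(rel), 1e-12)
})

test_that("multi-tau lag grid is quasi-logarithmic and bounded", {
  ks <- fccs:::multitau_grid(1e4, points_per_stage = 16)
  expect_true(all(diff(ks) > 0))
  expect_lt(max(ks), 5e3)
  # spacings are powers of two of the base bin and non-decreasing
  spacing <- unique(diff(ks))
  expect_true(all(log2(spacing) == round(log2(spacing))))
  expect_true(all(diff(diff(ks)) >= 0))
  expect_error(fccs:::multitau_grid(100, 16, n_stages = 5), "too short")
})

test_that("shot-noise-only traces show no correlation above the noise floor", {
  # background only: Poisson white noise, so |G - 1| < 5/sqrt(n) at all
  # lags >= 1 bin
  cfg <- fccs_sim_config(list(), test_optics(background_green = 5e5,
                                             background_red = 5e5),
                         c(5, 5, 5), duration = 1, bin_time = 1e-5,
                         seed = 13)
  tr <- simulate_trace(cfg)
  n <- length(tr$counts_green)
  for (k in c("gg", "gr")) {
    cu <- correlate_multitau(tr, k, min_lag_bins = 1, n_stages = 9)
    expect_lt(max(abs(cu$values - 1)), 5 / sqrt(n))
  }
})

test_that("permuting bins destroys temporal correlation", {
  cfg <- fccs_sim_config(
    fccs_species("green_only", diffusion = 25, mean_count = 2000,
                 brightness_green = 2.5e5),
    test_optics(), c(5, 5, 5), duration = 0.5, bin_time = 5e-5, seed = 14)
  tr <- simulate_trace(cfg)
  set.seed(1)
  idx <- sample.int(length(tr$counts_green))
  shuf <- tiny_trace(tr$counts_green[idx], tr$counts_green[idx],
                     bin_time = tr$bin_time)
  cu <- correlate_multitau(shuf, "gg", min_lag_bins = 1, n_stages = 6)
  expect_lt(mean(abs(cu$values - 1)), 3 / sqrt(length(shuf$counts_green)))
})

test_that("segment errors behave like standard errors", {
  # constant trace: mean exactly 1, stderr exactly 0
  cu <- segment_errors(tiny_trace(rep(7, 3000)), "gg", n_segments = 3)
  expect_true(all(cu$values == 1))
  expect_true(all(cu$stderr == 0))
  # mean curve consistent with the unsegmented estimator
  tr <- simulate_trace(quick_config(seed = 15, duration = 1))
  seg <- segment_errors(tr, "gg", n_segments = 10)
  full <- correlate_direct(tr, "gg",
                           max_lag_bins = max(seg$lags) / tr$bin_time)
  shared <- match(round(seg$lags / tr$bin_time),
                  round(full$lags / tr$bin_time))
  ok <- abs(seg$values - full$values[shared]) <=
    2 * pmax(seg$stderr, 1e-6) + 0.02 * abs(full$values[shared] - 1) + 1e-3
  expect_gt(mean(ok), 0.9)
  # error floor shrinks when the trace gets longer at fixed segment count
  med_se <- function(sd, dur) {
    tr <- simulate_trace(quick_config(seed = sd, duration = dur))
    median(segment_errors(tr, "gg", n_segments = 5,
                          n_stages = 5)$stderr)
  }
  shorter <- sapply(41:50, med_se, dur = 0.5)
  longer <- sapply(41:50, med_se, dur = 2)
  expect_true(all(longer < shorter))
  expect_error(segment_errors(tiny_trace(rep(3, 200)), "gg",
                              n_segments = 10), ">= 100 bins")
})

test_that("pooled curves average values and propagate errors", {
  tr1 <- simulate_trace(quick_config(seed = 17, duration = 1))
  tr2 <- simulate_trace(quick_config(seed = 18, duration = 1))
  c1 <- segment_errors(tr1, "gg", n_segments = 5)
  c2 <- segment_errors(tr2, "gg", n_segments = 5)
  pooled <- pool_curves(list(c1, c2))
  expect_equal(pooled$values, (c1$values + c2$values) / 2)
  expect_equal(pooled$stderr, sqrt((c1$stderr^2 + c2$stderr^2) / 2 / 2))
  truncated <- new_curve("gg", c2$lags[-1], c2$values[-1])
  expect_error(pool_curves(list(c1, truncated)), "share")
})

test_that("full-trace curve values reduce segment normalization bias", {
  # segment-mean values sit below the full-trace estimate by an
  # offset that scales with 1/segment length
  tr <- simulate_trace(quick_config(seed = 19, duration = 2,
                                    mean_count = 300))
  seg <- segment_errors(tr, "gg", n_segments = 10)
  full <- segment_errors(tr, "gg", n_segments = 10, values = "full")
  expect_identical(full$lags, seg$lags)
  expect_identical(full$stderr, seg$stderr)
  # same grid, nearly identical at short lags, segment-mean lower on
  # average (the finite-segment bias is negative)
  expect_lt(mean(seg$values - full$values), 0)
  # the full values equal the plain multi-tau estimate on that grid
  mt <- correlate_multitau(tr, "gg")
  shared <- match(round(full$lags / tr$bin_time),
                  round(mt$lags / tr$bin_time))
  expect_equal(full$values, mt$values[shared], tolerance = 1e-12)
})

test_that("single-species amplitude obeys G(0) - 1 = 1/N_eff", {
  cfg <- quick_config(seed = 16, mean_count = 300, duration = 4,
                      box = c(6, 6, 6), diffusion = 50)
  tr <- simulate_trace(cfg)
  cu <- segment_errors(tr, "gg", n_segments = 10)
  n_eff <- effective_particle_number(cfg$species[[1]], cfg$optics, cfg$box)
  amp <- cu$values[2] - 1          # first lag beyond the shot-noise bin
  # allow for the Poisson draw of the realized particle number too
  n_real <- sum(tr$meta$realized_counts)
  amp_expected <- 1 / (n_eff * n_real / 300)
  expect_lt(abs(amp - amp_expected), 3 * cu$stderr[2] + 0.05 * amp_expected)
  expect_rel(amp, 1 / n_eff, 0.25)
})
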