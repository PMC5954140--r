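test_that("configuration invariants are enforced", {
  sp <- fccs_species("green_only", mean_count = 10)
  expect_error(fccs_species("green_only", diffusion = -1), "positive")
  expect_error(fccs_species("green_only", brightness_red = 10),
               "brightness_red")
  expect_error(fccs_species("dual", brightness_red = 0), "dual")
  expect_error(fccs_species("green_only", triplet_fraction = 1), "triplet")
  expect_error(fccs_optics(w0 = 0), "positive")
  expect_error(fccs_optics(crosstalk_green_into_red = 1), "crosstalk")
  # non-integral bin/step ratio
  expect_error(fccs_sim_config(sp, duration = 1, bin_time = 1e-4,
                               time_step = 3e-5), "integer multiple")
  # fewer than 100 bins
  expect_error(fccs_sim_config(sp, duration = 1e-4, bin_time = 1e-5),
               "100 bins")
  # box too small relative to the detection volume
  expect_error(fccs_sim_config(sp, box = c(3, 3, 3), duration = 1,
                               bin_time = 1e-4), "100 x V_eff")
})

test_that("effective particle number follows the V_eff formula", {
  op <- test_optics()
  sp <- fccs_species("green_only", mean_count = 1000)
  expect_equal(effective_particle_number(sp, op, c(10, 10, 10)),
               1000 * pi^1.5 * 0.25^2 * 1.25 / 1000, tolerance = 1e-12)
  sp0 <- fccs_species("green_only", mean_count = 0)
  expect_identical(effective_particle_number(sp0, op, c(10, 10, 10)), 0)
  sp2 <- fccs_species("green_only", mean_count = 2000)
  expect_equal(effective_particle_number(sp2, op, c(10, 10, 10)),
               2 * effective_particle_number(sp, op, c(10, 10, 10)))
})

test_that("zero species and zero background give an all-zero trace", {
  cfg <- fccs_sim_config(list(), box = c(5, 5, 5), duration = 0.01,
                         bin_time = 1e-5, seed = 3)
  tr <- simulate_trace(cfg)
  expect_true(all(tr$counts_green == 0L))
  expect_true(all(tr$counts_red == 0L))
})

test_that("identical configs give bit-identical traces", {
  cfg <- quick_config(seed = 5, duration = 0.05)
  t1 <- simulate_trace(cfg)
  t2 <- simulate_trace(cfg)
  expect_identical(t1$counts_green, t2$counts_green)
  expect_identical(t1$counts_red, t2$counts_red)
  t3 <- simulate_trace(quick_config(seed = 6, duration = 0.05))
  expect_false(identical(t1$counts_green, t3$counts_green))
})

test_that("mean count rate matches the analytic box average of the profile", {
  # <rate> = brightness * mean_count * (pi/2)^(3/2) w0^2 z0 / V_box
  rates <- sapply(1:10, function(sd) {
    cfg <- fccs_sim_config(
      fccs_species("green_only", diffusion = 1, brightness_green = 1e4,
                   mean_count = 100),
      test_optics(), c(10, 10, 10), duration = 0.2, bin_time = 1e-4,
      seed = sd)
    tr <- simulate_trace(cfg)
    mean(tr$counts_green) / cfg$bin_time
  })
  expected <- 1e4 * 100 * (pi / 2)^1.5 * 0.25^2 * 1.25 / 1000
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - expected), 3 * se + 1e-9)
})

test_that("an immobile centred emitter yields Poisson bin counts", {
  cfg <- fccs_sim_config(
    fccs_species("green_only", diffusion = 1e-9, brightness_green = 1e5,
                 mean_count = 1),
    test_optics(), c(5, 5, 5), duration = 1.2, bin_time = 1e-4,
    seed = 2, fixed_counts = TRUE,
    init_positions = list(matrix(c(2.5, 2.5, 2.5), 1)))
  tr <- simulate_trace(cfg)
  expect_gte(length(tr$counts_green), 1e4)
  expect_rel(mean(tr$counts_green), 1e5 * 1e-4, 0.05)
  vmr <- var(tr$counts_green) / mean(tr$counts_green)
  expect_gt(vmr, 0.9)
  expect_lt(vmr, 1.1)
})

test_that("crosstalk redistributes expected rate without creating any", {
  base <- function(ct) {
    cfg <- fccs_sim_config(
      mixture_species(0.3), test_optics(crosstalk_green_into_red = ct,
                                        crosstalk_red_into_green = ct / 2),
      c(5, 5, 5), duration = 0.05, bin_time = 5e-5, seed = 9)
    simulate_trace(cfg, keep_rates = TRUE)
  }
  tr <- base(0.1)
  expect_equal(rowSums(tr$expected_counts),
               rowSums(tr$expected_counts_raw), tolerance = 1e-12)
  # and without crosstalk the mixed rates equal the raw ones
  tr0 <- base(0)
  expect_equal(unname(tr0$expected_counts[, 1]),
               unname(tr0$expected_counts_raw[, 1]), tolerance = 1e-12)
})

test_that("co-diffusing dual labels produce correlated channels at lag 0", {
  cfg <- fccs_sim_config(
    fccs_species("dual", diffusion = 25, mean_count = 50),
    test_optics(), c(5, 5, 5), duration = 2, bin_time = 5e-5, seed = 21)
  tr <- simulate_trace(cfg)
  expect_gt(cor(tr$counts_green, tr$counts_red), 0)
})

test_that("triplet blinking reduces the mean rate by the dark fraction", {
  rate_with_T <- function(Tf, sd) {
    cfg <- fccs_sim_config(
      fccs_species("green_only", diffusion = 25, mean_count = 200,
                   triplet_fraction = Tf, triplet_time = 2e-5),
      test_optics(), c(5, 5, 5), duration = 0.5, bin_time = 5e-5, seed = sd,
      fixed_counts = TRUE)
    mean(simulate_trace(cfg)$counts_green)
  }
  r0 <- mean(sapply(31:33, function(s) rate_with_T(0, s)))
  r2 <- mean(sapply(31:33, function(s) rate_with_T(0.2, s)))
  expect_rel(r2 / r0, 0.8, 0.1)
})

test_that("trace occupancy matches the analytic average over a long run", {
  # time-averaged detection-profile sum over a long trace: expected
  # counts per bin / brightness / bin_time vs analytic box mean
  cfg <- fccs_sim_config(
    fccs_species("green_only", diffusion = 50, brightness_green = 1e4,
                 mean_count = 50),
    test_optics(), c(5, 5, 5), duration = 2, bin_time = 1e-4,
    seed = 8, fixed_counts = TRUE)
  tr <- simulate_trace(cfg, keep_rates = TRUE)
  occ <- mean(tr$expected_counts_raw[, 1]) / (1e4 * 1e-4)
  expected <- 50 * (pi / 2)^1.5 * 0.25^2 * 1.25 / 125
  per_bin <- tr$expected_counts_raw[, 1] / (1e4 * 1e-4)
  se <- sd(per_bin) / sqrt(length(per_bin) / 20)  # ~20-bin correlation time
  expect_lt(abs(occ - expected), 3 * se)
})
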