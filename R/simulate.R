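#' Describe a diffusing fluorescent species
#'
#' A species is a population of point emitters with a common diffusion
#' coefficient and molecular brightness. Dual-labelled species (e.g. a
#' GFP-tagged protein bound to an mCherry-tagged partner) emit into both
#' detection channels and are what dual-color FCCS detects as a positive
#' cross-correlation.
#'
#' @param kind One of `"green_only"`, `"red_only"`, `"dual"`.
#' @param diffusion Diffusion coefficient D in um^2/s (> 0). Nuclear
#'   proteins are typically 1--30 um^2/s; free organic dyes 300--500.
#' @param brightness_green,brightness_red Molecular brightness in
#'   counts/s per molecule at the centre of the detection volume (>= 0).
#'   Defaults: 5e4 for the labelled channel(s), 0 otherwise.
#' @param mean_count Mean number of particles of this species in the
#'   simulation box (> 0); the realised number is Poisson-distributed
#'   unless `fixed_counts` is set in [fccs_sim_config()].
#' @param triplet_fraction Stationary dark-state (triplet) probability in
#'   `[0, 1)`; 0 disables blinking.
#' @param triplet_time Mean dark-state residence time in seconds (> 0
#'   when `triplet_fraction > 0`).
#' @return An object of class `fccs_species`.
#' @examples
#' fccs_species("dual", diffusion = 25, mean_count = 30)
#' @export
fccs_species <- function(kind = c("green_only", "red_only", "dual"),
                         diffusion = 25,
                         brightness_green = NULL,
                         brightness_red = NULL,
                         mean_count = 100,
                         triplet_fraction = 0,
                         triplet_time = 5e-6) {
  kind <- match.arg(kind)
  if (is.null(brightness_green))
    brightness_green <- if (kind %in% c("green_only", "dual")) 5e4 else 0
  if (is.null(brightness_red))
    brightness_red <- if (kind %in% c("red_only", "dual")) 5e4 else 0
  if (!is_scalar_number(diffusion) || diffusion <= 0)
    abort_config("diffusion coefficient must be a finite positive number")
  if (!is_scalar_number(brightness_green) || brightness_green < 0 ||
      !is_scalar_number(brightness_red) || brightness_red < 0)
    abort_config("brightness must be a finite non-negative rate (counts/s)")
  if (kind == "green_only" && brightness_red != 0)
    abort_config("green_only species must have brightness_red = 0")
  if (kind == "red_only" && brightness_green != 0)
    abort_config("red_only species must have brightness_green = 0")
  if (kind == "dual" && (brightness_green <= 0 || brightness_red <= 0))
    abort_config("dual species need positive brightness in both channels")
  if (!is_scalar_number(mean_count) || mean_count < 0)
    abort_config("mean_count must be >= 0")
  if (!is_scalar_number(triplet_fraction) ||
      triplet_fraction < 0 || triplet_fraction >= 1)
    abort_config("triplet_fraction must lie in [0, 1)")
  if (triplet_fraction > 0 &&
      (!is_scalar_number(triplet_time) || triplet_time <= 0))
    abort_config("triplet_time must be > 0 when triplet_fraction > 0")
  structure(
    list(kind = kind, diffusion = diffusion,
         brightness_green = brightness_green,
         brightness_red = brightness_red,
         mean_count = mean_count,
         triplet_fraction = triplet_fraction,
         triplet_time = triplet_time),
    class = "fccs_species")
}

#' Describe the detection optics of a dual-channel confocal setup
#'
#' Both channels share one 3D-Gaussian detection volume of radial waist
#' `w0` and axial half-length `z0` (structure parameter s = z0/w0).
#' Spectral crosstalk redistributes a fraction of each channel's expected
#' rate into the other channel; background adds an uncorrelated Poisson
#' rate per channel.
#'
#' @param w0 Radial 1/e^2 waist in um (> 0).
#' @param z0 Axial 1/e^2 half-length in um (> 0).
#' @param crosstalk_green_into_red,crosstalk_red_into_green Fraction of
#'   the donor channel's rate detected in the other channel, in `[0, 1)`.
#' @param background_green,background_red Uncorrelated background count
#'   rates in counts/s (>= 0).
#' @return An object of class `fccs_optics` with derived fields
#'   `structure_parameter` (= z0/w0) and `v_eff` (= pi^(3/2) w0^2 z0, um^3).
#' @examples
#' fccs_optics(w0 = 0.25, z0 = 1.25)
#' @export
fccs_optics <- function(w0 = 0.25, z0 = 1.25,
                        crosstalk_green_into_red = 0,
                        crosstalk_red_into_green = 0,
                        background_green = 0,
                        background_red = 0) {
  if (!is_scalar_number(w0) || w0 <= 0 || !is_scalar_number(z0) || z0 <= 0)
    abort_config("w0 and z0 must be positive lengths (um)")
  for (ct in list(crosstalk_green_into_red, crosstalk_red_into_green))
    if (!is_scalar_number(ct) || ct < 0 || ct >= 1)
      abort_config("crosstalk fractions must lie in [0, 1)")
  for (bgr in list(background_green, background_red))
    if (!is_scalar_number(bgr) || bgr < 0)
      abort_config("background rates must be >= 0")
  s <- z0 / w0
  if (s <= 0) abort_config("structure parameter must be > 0")
  structure(
    list(w0 = w0, z0 = z0,
         crosstalk_green_into_red = crosstalk_green_into_red,
         crosstalk_red_into_green = crosstalk_red_into_green,
         background_green = background_green,
         background_red = background_red,
         structure_parameter = s,
         v_eff = pi^1.5 * w0^2 * z0),
    class = "fccs_optics")
}

#' Configure a synthetic FCCS acquisition
#'
#' Bundles species, optics, box geometry and timing into a validated,
#' fully seeded description of one simulated measurement. Refuses
#' configurations whose statistics would be unreliable: fewer than 100
#' bins, or a box smaller than 100 effective detection volumes (boundary
#' artifacts).
#'
#' @param species A single [fccs_species()] or a list of them.
#' @param optics An [fccs_optics()].
#' @param box Numeric length-3 edge lengths of the periodic box in um;
#'   each edge must exceed twice `max(w0, z0)`.
#' @param duration Trace duration in s (> 0).
#' @param bin_time Width of a count bin in s (> 0); must be an integer
#'   multiple of `time_step`.
#' @param time_step Brownian-dynamics step in s; defaults to `bin_time`.
#' @param seed Integer RNG seed; identical configs give identical traces.
#' @param fixed_counts If `TRUE`, use exactly `round(mean_count)`
#'   particles per species instead of a Poisson draw. The Poisson
#'   (open-volume) default makes the amplitude law G(0) - 1 = 1/N exact.
#' @param init_positions Optional list (one element per species) of
#'   n x 3 matrices of initial positions in um, overriding the uniform
#'   draw; mainly for controlled tests such as an immobile emitter at
#'   the volume centre.
#' @return An object of class `fccs_sim_config`.
#' @export
fccs_sim_config <- function(species, optics = fccs_optics(),
                            box = c(5, 5, 5),
                            duration = 10, bin_time = 1e-5,
                            time_step = bin_time,
                            seed = 1L, fixed_counts = FALSE,
                            init_positions = NULL) {
  if (inherits(species, "fccs_species")) species <- list(species)
  if (!is.list(species) ||
      !all(vapply(species, inherits, logical(1), "fccs_species")))
    abort_config("species must be fccs_species objects")
  if (!inherits(optics, "fccs_optics"))
    abort_config("optics must be an fccs_optics object")
  if (!is.numeric(box) || length(box) != 3L || any(!is.finite(box)) ||
      any(box <= 0))
    abort_config("box must be three positive edge lengths (um)")
  if (min(box) < 2 * max(optics$w0, optics$z0))
    abort_config("box edges must exceed twice the detection volume size")
  if (!is_scalar_number(duration) || duration <= 0)
    abort_config("duration must be > 0")
  if (!is_scalar_number(bin_time) || bin_time <= 0 ||
      !is_scalar_number(time_step) || time_step <= 0)
    abort_config("bin_time and time_step must be > 0")
  ratio <- bin_time / time_step
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1)
    abort_config("bin_time must be a positive integer multiple of time_step")
  n_bins <- floor(duration / bin_time + 1e-9)
  if (n_bins < 100)
    abort_config("duration must cover at least 100 bins (got %d)", n_bins)
  v_box <- prod(box)
  if (v_box < 100 * optics$v_eff)
    abort_config("box volume must be at least 100 x V_eff (%.3g < %.3g um^3)",
                 v_box, 100 * optics$v_eff)
  if (!is_count_scalar(seed)) abort_config("seed must be an integer")
  if (!is.null(init_positions)) {
    if (!is.list(init_positions) || length(init_positions) != length(species))
      abort_config("init_positions must be a list with one entry per species")
  }
  structure(
    list(species = species, optics = optics, box = box,
         duration = duration, bin_time = bin_time, time_step = time_step,
         n_bins = as.integer(n_bins),
         steps_per_bin = as.integer(round(ratio)),
         seed = as.integer(seed), fixed_counts = isTRUE(fixed_counts),
         init_positions = init_positions),
    class = "fccs_sim_config")
}

#' Expected number of particles in the effective detection volume
#'
#' Converts a species' mean particle count in the simulation box to the
#' mean occupancy of the effective detection volume
#' V_eff = pi^(3/2) w0^2 z0. This is the ground-truth value that the
#' fitted particle number N of the diffusion model must recover, since
#' the correlation amplitude obeys G(0) - 1 = 1/N.
#'
#' @param species An [fccs_species()].
#' @param optics An [fccs_optics()].
#' @param box Length-3 box edges in um.
#' @return Mean particle number in V_eff (dimensionless).
#' @examples
#' sp <- fccs_species("green_only", mean_count = 1000)
#' effective_particle_number(sp, fccs_optics(0.25, 1.25), c(10, 10, 10))
#' @export
effective_particle_number <- function(species, optics, box) {
  if (!is.numeric(box) || length(box) != 3L || any(box <= 0) ||
      prod(box) == 0)
    abort_config("box must have positive volume")
  species$mean_count * optics$v_eff / prod(box)
}

# Mean of the 3D-Gaussian detection profile over the box:
# integral exp(-2r^2/w0^2 - 2z^2/z0^2) dV / V_box = (pi/2)^(3/2) w0^2 z0 / V_box
mean_profile_over_box <- function(optics, box) {
  (pi / 2)^1.5 * optics$w0^2 * optics$z0 / prod(box)
}

#' Simulate a two-channel FCCS photon-count trace
#'
#' Brownian dynamics of all configured species through the shared
#' 3D-Gaussian detection volume. Per time step every coordinate of every
#' particle receives an independent Gaussian increment of standard
#' deviation sqrt(2 D dt) with periodic boundaries; the expected
#' molecular detection rate is brightness * exp(-2(x^2+y^2)/w0^2
#' - 2z^2/z0^2), gated by the triplet state. Expected rates are summed
#' over each bin, mixed by the crosstalk fractions (conserving the total
#' rate), augmented by background, and Poisson-sampled into counts.
#'
#' @param config An [fccs_sim_config()].
#' @param keep_rates If `TRUE` the returned trace carries the expected
#'   (pre-Poisson, post-crosstalk) per-bin count matrix in
#'   `$expected_counts` and the pre-crosstalk matrix in
#'   `$expected_counts_raw`.
#' @return An object of class `fccs_trace`: `bin_time`, integer vectors
#'   `counts_green` and `counts_red`, and `meta` (seed, optics, species,
#'   realised particle numbers).
#' @examples
#' cfg <- fccs_sim_config(fccs_species("green_only", mean_count = 20),
#'                        box = c(5, 5, 5), duration = 0.01,
#'                        bin_time = 1e-5, seed = 7)
#' tr <- simulate_trace(cfg)
#' mean(tr$counts_green) / cfg$bin_time   # realised count rate, counts/s
#' @export
simulate_trace <- function(config, keep_rates = FALSE) {
  if (!inherits(config, "fccs_sim_config"))
    abort_config("config must be an fccs_sim_config")
  op <- config$optics
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  pos <- matrix(numeric(0), 0, 3)
  bg <- br <- ssd <- pdark <- pbright <- numeric(0)
  dark0 <- integer(0)
  realized <- integer(length(config$species))
  for (k in seq_along(config$species)) {
    sp <- config$species[[k]]
    n_k <- if (config$fixed_counts) as.integer(round(sp$mean_count))
           else rpois(1, sp$mean_count)
    realized[k] <- n_k
    if (n_k == 0) next
    p_k <- if (!is.null(config$init_positions) &&
               !is.null(config$init_positions[[k]])) {
      m <- config$init_positions[[k]]
      if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != n_k)
        abort_config("init_positions[[%d]] must be a %d x 3 matrix", k, n_k)
      m
    } else {
      cbind(runif(n_k, 0, config$box[1]),
            runif(n_k, 0, config$box[2]),
            runif(n_k, 0, config$box[3]))
    }
    pos <- rbind(pos, p_k)
    bg <- c(bg, rep(sp$brightness_green, n_k))
    br <- c(br, rep(sp$brightness_red, n_k))
    ssd <- c(ssd, rep(sqrt(2 * sp$diffusion * config$time_step), n_k))
    if (sp$triplet_fraction > 0) {
      # exact discretization of the two-state telegraph process: with
      # relaxation time tau_rel = (1 - T) * tau_T the one-step transition
      # probabilities T*q and (1-T)*q (q = 1 - exp(-dt/tau_rel)) keep the
      # stationary dark fraction at T for any step size
      Tf <- sp$triplet_fraction
      q <- 1 - exp(-config$time_step / ((1 - Tf) * sp$triplet_time))
      pdark <- c(pdark, rep(Tf * q, n_k))
      pbright <- c(pbright, rep((1 - Tf) * q, n_k))
      dark0 <- c(dark0, as.integer(runif(n_k) < Tf))
    } else {
      pdark <- c(pdark, rep(0, n_k))
      pbright <- c(pbright, rep(0, n_k))
      dark0 <- c(dark0, rep(0L, n_k))
    }
  }

  # seed for the C++ stream, drawn from R's (seeded) RNG
  core_seed <- floor(runif(1) * 2^53)
  raw <- bd_expected_counts(config$n_bins, config$steps_per_bin,
                            config$time_step, pos, bg, br, ssd,
                            config$box, op$w0, op$z0,
                            dark0, pdark, pbright, core_seed)

  # crosstalk redistributes rate between channels, conserving the sum
  cgr <- op$crosstalk_green_into_red
  crg <- op$crosstalk_red_into_green
  exp_g <- (1 - cgr) * raw[, 1] + crg * raw[, 2] +
    op$background_green * config$bin_time
  exp_r <- (1 - crg) * raw[, 2] + cgr * raw[, 1] +
    op$background_red * config$bin_time

  counts_g <- rpois(config$n_bins, exp_g)
  counts_r <- rpois(config$n_bins, exp_r)

  out <- structure(
    list(bin_time = config$bin_time,
         counts_green = as.integer(counts_g),
         counts_red = as.integer(counts_r),
         meta = list(seed = config$seed, optics = op,
                     species = config$species,
                     realized_counts = realized,
                     duration = config$duration,
                     time_step = config$time_step)),
    class = "fccs_trace")
  if (isTRUE(keep_rates)) {
    out$expected_counts <- cbind(green = exp_g, red = exp_r)
    out$expected_counts_raw <- raw
  }
  out
}

#' @export
print.fccs_trace <- function(x, ...) {
  n <- length(x$counts_green)
  cat(sprintf("Two-channel FCCS trace: %d bins of %.3g s (%.3g s total)\n",
              n, x$bin_time, n * x$bin_time))
  cat(sprintf("  mean rates: green %.4g counts/s, red %.4g counts/s\n",
              mean(x$counts_green) / x$bin_time,
              mean(x$counts_red) / x$bin_time))
  if (!is.null(x$meta$seed)) cat(sprintf("  seed: %d\n", x$meta$seed))
  invisible(x)
}

# internal: validated trace constructor used by readers and tests
new_trace <- function(counts_green, counts_red, bin_time, meta = list(),
                      min_bins = 2L) {
  if (length(counts_green) != length(counts_red))
    abort_format("channel lengths differ (%d vs %d)",
                 length(counts_green), length(counts_red))
  if (length(counts_green) < min_bins)
    abort_format("trace must have at least %d bins", min_bins)
  for (v in list(counts_green, counts_red)) {
    if (any(!is.finite(v)) || any(v < 0))
      abort_format("counts must be finite and non-negative")
    if (any(abs(v - round(v)) > 0))
      abort_format("non-integer counts")
  }
  structure(list(bin_time = bin_time,
                 counts_green = as.integer(round(counts_green)),
                 counts_red = as.integer(round(counts_red)),
                 meta = meta),
            class = "fccs_trace")
}
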