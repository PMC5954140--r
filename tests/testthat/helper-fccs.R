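# Shared fixtures: small, fast simulation configurations built in code.

# a bare trace object for hand-calculated correlator examples
tiny_trace <- function(g, r = g, bin_time = 1) {
  structure(list(bin_time = bin_time, counts_green = as.integer(g),
                 counts_red = as.integer(r), meta = list()),
            class = "fccs_trace")
}

# default optics used throughout: w0 = 0.25 um, z0 = 1.25 um (s = 5)
test_optics <- function(...) fccs_optics(w0 = 0.25, z0 = 1.25, ...)

# one mobile green species in a small box; cheap but physical
quick_config <- function(seed, mean_count = 100, diffusion = 25,
                         duration = 2, bin_time = 5e-5, box = c(5, 5, 5),
                         optics = test_optics(), ...) {
  fccs_sim_config(
    fccs_species("green_only", diffusion = diffusion,
                 mean_count = mean_count),
    optics, box, duration = duration, bin_time = bin_time, seed = seed, ...)
}

# species mix for an interaction experiment with a given dual-labelled
# share p: 100*(1-p) green-only + 100*(1-p) red-only + 100*p dual
mixture_species <- function(p, total = 100, diffusion = 25) {
  sp <- list()
  if (p < 1) {
    sp <- c(sp, list(
      fccs_species("green_only", diffusion = diffusion,
                   mean_count = total * (1 - p)),
      fccs_species("red_only", diffusion = diffusion,
                   mean_count = total * (1 - p))))
  }
  if (p > 0)
    sp <- c(sp, list(fccs_species("dual", diffusion = diffusion,
                                  mean_count = total * p)))
  sp
}

mixture_config <- function(p, seed, duration = 10, bin_time = 5e-5,
                           box = c(5, 5, 5), optics = test_optics(), ...) {
  fccs_sim_config(mixture_species(p), optics, box, duration = duration,
                  bin_time = bin_time, seed = seed, ...)
}

# true diffusion time for the default optics
tau_d_true <- function(diffusion, w0 = 0.25) w0^2 / (4 * diffusion)

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}

# exact permutation p-value for a two-sample mean difference (the
# independent oracle for the t-test checks)
perm_pvalue <- function(a, b) {
  pool <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pool), n_a)
  obs <- abs(mean(a) - mean(b))
  diffs <- apply(idx, 2, function(i)
    abs(mean(pool[i]) - mean(pool[-i])))
  mean(diffs >= obs - 1e-12)
}
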