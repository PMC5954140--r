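#' Multi-component 3D diffusion model for FCS/FCCS curves
#'
#' The correlation model for free 3D diffusion through a 3D-Gaussian
#' detection volume,
#' \deqn{G(\tau) = 1 + \frac{1}{N} \sum_i F_i
#'   \left(1 + \tau/\tau_i\right)^{-1}
#'   \left(1 + \tau/(s^2 \tau_i)\right)^{-1/2} \cdot
#'   \left(1 + \frac{T}{1-T} e^{-\tau/\tau_T}\right),}
#' with mean particle number `N` in the detection volume, up to three
#' diffusing components with fractions `F_i` (summing to 1) and
#' diffusion times `tau_i` (s), structure parameter `s = z0/w0`, and an
#' optional multiplicative triplet-blinking factor with dark fraction
#' `T` and relaxation time `tau_T`. The amplitude obeys
#' G(0) - 1 = (1/N)(1 + T/(1-T)).
#'
#' @param N Mean particle number in the detection volume (> 0).
#' @param tau Diffusion times in s, one per component (1 to 3); stored
#'   sorted increasing.
#' @param fractions Component fractions, same length as `tau`, summing
#'   to 1 (renormalized if within 1e-8, rejected otherwise).
#' @param s Structure parameter z0/w0 (> 0).
#' @param triplet_fraction Dark-state fraction T in `[0, 1)`.
#' @param triplet_time Triplet relaxation time in s (> 0 when T > 0).
#' @param offset Baseline G(Inf), normally exactly 1. Short traces
#'   depress the whole measured curve by a constant (the segment-mean
#'   normalization bias), and fits may float this nuisance baseline to
#'   absorb it (see `offset_free` in [fit_curve()]).
#' @return An object of class `fccs_model`.
#' @examples
#' m <- fccs_model(N = 2, tau = 1e-3, s = 5)
#' model_eval(m, c(0, 1e-3))
#' @export
fccs_model <- function(N, tau, fractions = rep(1 / length(tau), length(tau)),
                       s = 5, triplet_fraction = 0, triplet_time = NA_real_,
                       offset = 1) {
  if (!is_scalar_number(N) || N <= 0)
    abort_config("N must be a positive number")
  k <- length(tau)
  if (k < 1 || k > 3)
    abort_config("between 1 and 3 diffusion components are supported")
  if (any(!is.finite(tau)) || any(tau <= 0))
    abort_config("diffusion times must be positive")
  if (length(fractions) != k || any(!is.finite(fractions)) ||
      any(fractions < 0))
    abort_config("fractions must be non-negative, one per component")
  tot <- sum(fractions)
  if (abs(tot - 1) > 1e-8)
    abort_config("fractions must sum to 1 (got %.10g)", tot)
  fractions <- fractions / tot
  ord <- order(tau)
  tau <- tau[ord]
  fractions <- fractions[ord]
  if (k > 1 && any(diff(tau) <= 0))
    abort_config("diffusion times must be distinct")
  if (!is_scalar_number(s) || s <= 0)
    abort_config("structure parameter must be > 0")
  if (!is_scalar_number(triplet_fraction) || triplet_fraction < 0 ||
      triplet_fraction >= 1)
    abort_config("triplet_fraction must lie in [0, 1)")
  if (triplet_fraction > 0 &&
      (!is_scalar_number(triplet_time) || triplet_time <= 0))
    abort_config("triplet_time must be > 0 when triplet_fraction > 0")
  if (!is_scalar_number(offset) || abs(offset - 1) > 0.5)
    abort_config("offset must be close to 1")
  structure(list(N = N, tau = as.numeric(tau),
                 fractions = as.numeric(fractions), s = s,
                 triplet_fraction = triplet_fraction,
                 triplet_time = triplet_time, offset = offset),
            class = "fccs_model")
}

#' Evaluate a diffusion model at given lag times
#'
#' @param model An [fccs_model()].
#' @param lags Lag times in s (>= 0).
#' @return Model values G(lags); G -> 1 as lags -> Inf.
#' @export
model_eval <- function(model, lags) {
  if (!inherits(model, "fccs_model"))
    abort_config("model must be an fccs_model")
  if (any(!is.finite(lags)) || any(lags < 0))
    abort_numeric("lags must be finite and non-negative")
  diff_part <- rep(0, length(lags))
  for (i in seq_along(model$tau)) {
    ti <- model$tau[i]
    diff_part <- diff_part + model$fractions[i] *
      (1 + lags / ti)^(-1) * (1 + lags / (model$s^2 * ti))^(-0.5)
  }
  trip <- if (model$triplet_fraction > 0) {
    Tf <- model$triplet_fraction
    1 + Tf / (1 - Tf) * exp(-lags / model$triplet_time)
  } else 1
  base <- if (is.null(model$offset)) 1 else model$offset
  base + diff_part * trip / model$N
}

#' @export
predict.fccs_model <- function(object, lags, ...) model_eval(object, lags)

#' @export
print.fccs_model <- function(x, ...) {
  cat(sprintf("3D diffusion model: N = %.4g, s = %.4g\n", x$N, x$s))
  for (i in seq_along(x$tau))
    cat(sprintf("  component %d: F = %.4g, tau_D = %.4g s\n",
                i, x$fractions[i], x$tau[i]))
  if (x$triplet_fraction > 0)
    cat(sprintf("  triplet: T = %.4g, tau_T = %.4g s\n",
                x$triplet_fraction, x$triplet_time))
  cat(sprintf("  amplitude G(0) - 1 = %.4g\n",
              (1 + if (x$triplet_fraction > 0)
                x$triplet_fraction / (1 - x$triplet_fraction) else 0) / x$N))
  invisible(x)
}

#' Data-driven starting values for a diffusion-model fit
#'
#' The particle number is initialised from the amplitude law,
#' N0 = 1 / (G(first fitted lag) - 1); the diffusion time from the lag
#' at which G - 1 first falls below half its initial value; fractions
#' are uniform, with multi-component diffusion times spread
#' geometrically around the half-decay lag.
#'
#' @param curve An `fccs_curve`.
#' @param components Number of diffusion components (1--3).
#' @param s Structure parameter for the returned model.
#' @param first_lag_index Index of the first lag used for the amplitude
#'   (default 1; fits use 2 for auto-correlations).
#' @return An [fccs_model()].
#' @export
initial_guess <- function(curve, components = 1L, s = 5,
                          first_lag_index = 1L) {
  if (!inherits(curve, "fccs_curve"))
    abort_config("curve must be an fccs_curve")
  v <- curve$values[first_lag_index:length(curve$values)]
  l <- curve$lags[first_lag_index:length(curve$lags)]
  g0 <- v[1] - 1
  if (!is.finite(g0) || g0 <= 0)
    abort_numeric("no correlated signal: amplitude G - 1 <= 0")
  below <- which(v - 1 < g0 / 2)
  tau0 <- if (length(below)) max(l[below[1]], min(l[l > 0]))
          else max(l) / 2
  k <- as.integer(components)
  taus <- tau0 * 4^(seq_len(k) - (k + 1) / 2)
  fccs_model(N = 1 / g0, tau = taus, fractions = rep(1 / k, k), s = s)
}
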