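# Parameter vocabulary for the fit: N, tau1..tau3, F1..F2 (the last
# fraction is 1 minus the rest), s, T, tauT.

param_names <- function(components, s_free, triplet, offset_free = FALSE) {
  nm <- c("N", paste0("tau", seq_len(components)))
  if (components > 1) nm <- c(nm, paste0("F", seq_len(components - 1)))
  if (s_free) nm <- c(nm, "s")
  if (triplet) nm <- c(nm, "T", "tauT")
  if (offset_free) nm <- c(nm, "G_inf")
  nm
}

params_to_model <- function(p, components, s_fixed_value = NULL) {
  taus <- unname(p[paste0("tau", seq_len(components))])
  # guard against exactly coincident diffusion times during optimization
  if (components > 1 && any(diff(sort(taus)) <= 0))
    taus <- taus * (1 + 1e-9 * seq_len(components))
  if (components > 1) {
    fr <- unname(p[paste0("F", seq_len(components - 1))])
    fr <- c(fr, 1 - sum(fr))
  } else fr <- 1
  s_val <- if (is.null(s_fixed_value)) unname(p["s"]) else s_fixed_value
  trip <- "T" %in% names(p)
  fccs_model(N = unname(p["N"]), tau = taus,
             fractions = pmax(fr, 0) / sum(pmax(fr, 0)), s = s_val,
             triplet_fraction = if (trip) unname(p["T"]) else 0,
             triplet_time = if (trip) unname(p["tauT"]) else NA_real_,
             offset = if ("G_inf" %in% names(p)) unname(p["G_inf"]) else 1)
}

#' Fit a multi-component 3D diffusion model to a correlation curve
#'
#' Weighted nonlinear least squares: minimizes
#' sum(((G_obs - G_model)/stderr)^2) over the free parameters of the
#' diffusion model using bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm]). Per-lag standard errors (from
#' [segment_errors()]) provide the weights; curves without them are
#' fitted unweighted with a warning. The structure parameter `s` is
#' fixed to its calibrated value by default (pass `s = NULL` to float
#' it, as [calibrate_structure_parameter()] does); further parameters
#' can be pinned through `fixed`.
#'
#' For auto-correlation curves (`gg`, `rr`) the first lag point is
#' excluded by default because the zero-lag bin carries shot noise;
#' cross-correlation curves are fitted from their first lag.
#'
#' @param curve An `fccs_curve`.
#' @param components Number of diffusion components (1, 2 or 3).
#' @param s Structure parameter to fix, or `NULL` to fit it.
#' @param triplet If `TRUE`, include the triplet factor (adds free
#'   parameters `T` and `tauT`).
#' @param fixed Named list of parameters to hold fixed, e.g.
#'   `list(tau1 = 1e-3)`. Names follow `N`, `tau1..tau3`, `F1..F2`,
#'   `s`, `T`, `tauT`.
#' @param init Optional [fccs_model()] with starting values; default
#'   [initial_guess()] (with a weak-signal fallback for flat curves,
#'   so cross-correlations of non-interacting pairs remain fittable).
#' @param drop_first Number of leading lag points to exclude;
#'   `NULL` (default) excludes 1 for auto-correlations, 0 for `gr`.
#' @param weights `"stderr"` (default) or `"none"`.
#' @param control Passed to [minpack.lm::nls.lm.control()]; defaults
#'   use ftol = ptol = gtol = 1e-10.
#' @param offset_free If `TRUE`, float the baseline G(Inf) as a
#'   nuisance parameter `G_inf` (bounds 0.9--1.1). Short measurements
#'   depress the whole curve by a constant (segment-mean normalization
#'   bias ~ 1/T_segment); floating the baseline absorbs it. Off by
#'   default.
#' @return An object of class `fccs_fit` with components `model` (the
#'   fitted [fccs_model()]), `estimates`, `stderr`, `fixed`,
#'   `reduced_chi_square`, `residuals`, `fitted`, `lags`, `converged`,
#'   `info`, `message`, `n_evals`, `weighted` and the input `curve`.
#'   Methods: `print`, `summary`, `coef`, `vcov`, `predict`,
#'   `residuals`, `fitted`, `deviance`, `plot`, `simulate`.
#' @examples
#' m <- fccs_model(N = 5, tau = 2e-4, s = 5)
#' lags <- 10^seq(-5, -1, length.out = 64)
#' curve <- new_curve("gg", lags, model_eval(m, lags))
#' fit <- fit_curve(curve, components = 1, s = 5, drop_first = 0)
#' coef(fit)[c("N", "tau1")]
#' @export
fit_curve <- function(curve, components = 1L, s = NULL, triplet = FALSE,
                      fixed = list(), init = NULL, drop_first = NULL,
                      weights = c("stderr", "none"), control = NULL,
                      offset_free = FALSE) {
  if (!inherits(curve, "fccs_curve"))
    abort_config("curve must be an fccs_curve")
  weights <- match.arg(weights)
  components <- as.integer(components)
  if (!components %in% 1:3)
    abort_config("components must be 1, 2 or 3")
  if (!is.null(s)) {
    if (!is_scalar_number(s) || s <= 0) abort_config("s must be > 0")
    fixed$s <- s
  }
  s_free <- !("s" %in% names(fixed))

  if (is.null(drop_first))
    drop_first <- if (curve$kind %in% c("gg", "rr")) 1L else 0L
  keep <- seq_along(curve$lags) > drop_first
  lags <- curve$lags[keep]
  vals <- curve$values[keep]
  errs <- curve$stderr[keep]

  use_w <- weights == "stderr" && any(is.finite(errs) & errs > 0)
  if (weights == "stderr" && !use_w)
    warning("curve has no usable stderr; fitting unweighted",
            call. = FALSE)
  w <- if (use_w) {
    e <- errs
    pos <- is.finite(e) & e > 0
    e[!pos] <- min(e[pos])       # floor missing/zero errors
    e
  } else rep(1, length(vals))

  all_names <- param_names(components, s_free, triplet, offset_free)
  free_names <- setdiff(all_names, names(fixed))
  if (length(lags) < 3 * length(free_names))
    abort_config("need at least 3 lags per free parameter (%d free, %d lags)",
                 length(free_names), length(lags))

  # starting model
  if (is.null(init)) {
    init <- tryCatch(
      initial_guess(curve, components,
                    s = if (s_free) 5 else fixed$s,
                    first_lag_index = drop_first + 1L),
      fccs_numeric_error = function(e) {
        # weak-signal fallback: near-flat curves (e.g. the cross-correlation
        # of a non-interacting pair) start from a tiny amplitude
        k <- components
        tau0 <- exp(mean(log(range(lags[lags > 0]))))
        fccs_model(N = 1e3, tau = tau0 * 4^(seq_len(k) - (k + 1) / 2),
                   fractions = rep(1 / k, k),
                   s = if (s_free) 5 else fixed$s)
      })
  }
  if (!inherits(init, "fccs_model"))
    abort_config("init must be an fccs_model")

  p_full <- c(N = init$N,
              setNames(rep(init$tau, length.out = components),
                       paste0("tau", seq_len(components))))
  if (components > 1)
    p_full <- c(p_full,
                setNames(rep(init$fractions, length.out = components)[
                  seq_len(components - 1)],
                  paste0("F", seq_len(components - 1))))
  if (s_free) p_full <- c(p_full, s = init$s)
  if (triplet)
    p_full <- c(p_full,
                T = max(init$triplet_fraction, 0.05),
                tauT = if (is.finite(init$triplet_time)) init$triplet_time
                       else max(min(lags[lags > 0]) / 2, 1e-7))
  if (offset_free)
    p_full <- c(p_full,
                G_inf = if (is.null(init$offset)) 1 else init$offset)
  for (nm in names(fixed)) p_full[nm] <- fixed[[nm]]

  bin_t <- if (is.finite(curve$bin_time)) curve$bin_time
           else min(lags[lags > 0])
  lo_full <- c(N = 1e-3,
               setNames(rep(bin_t / 10, components),
                        paste0("tau", seq_len(components))))
  hi_full <- c(N = 1e6,
               setNames(rep(10 * max(lags), components),
                        paste0("tau", seq_len(components))))
  if (components > 1) {
    lo_full <- c(lo_full, setNames(rep(0, components - 1),
                                   paste0("F", seq_len(components - 1))))
    hi_full <- c(hi_full, setNames(rep(1, components - 1),
                                   paste0("F", seq_len(components - 1))))
  }
  if (s_free) { lo_full <- c(lo_full, s = 0.3); hi_full <- c(hi_full, s = 1e7) }
  if (triplet) {
    lo_full <- c(lo_full, T = 0, tauT = 1e-8)
    hi_full <- c(hi_full, T = 0.4999, tauT = 0.1)
  }
  if (offset_free) {
    lo_full <- c(lo_full, G_inf = 0.9)
    hi_full <- c(hi_full, G_inf = 1.1)
  }
  p0 <- pmin(pmax(p_full[free_names], lo_full[free_names]),
             hi_full[free_names])

  s_fixed_value <- if (s_free) NULL else unname(p_full["s"])
  resid_fn <- function(p) {
    names(p) <- free_names
    full <- p_full
    full[free_names] <- p
    m <- params_to_model(full, components, s_fixed_value)
    r <- (model_eval(m, lags) - vals) / w
    if (components > 2) {
      last_f <- 1 - sum(full[paste0("F", seq_len(components - 1))])
      if (last_f < 0) r <- r * (1 + 1e4 * abs(last_f))
    }
    r
  }

  ctrl <- do.call(minpack.lm::nls.lm.control,
                  modifyList(list(ftol = 1e-10, ptol = 1e-10, gtol = 1e-10,
                                  maxiter = 1000),
                             if (is.null(control)) list() else control))
  fit <- minpack.lm::nls.lm(par = p0, lower = unname(lo_full[free_names]),
                            upper = unname(hi_full[free_names]),
                            fn = resid_fn, control = ctrl)
  n_evals <- length(fit$rsstrace)
  # restart from the current point when the iteration budget ran out
  # (near-flat directions, e.g. the diffusion time of a zero-amplitude
  # cross-correlation, advance slowly; a restart settles them)
  restarts <- 0L
  while (fit$info == 5 && restarts < 2L) {
    fit <- minpack.lm::nls.lm(par = fit$par,
                              lower = unname(lo_full[free_names]),
                              upper = unname(hi_full[free_names]),
                              fn = resid_fn, control = ctrl)
    n_evals <- n_evals + length(fit$rsstrace)
    restarts <- restarts + 1L
  }

  est_free <- setNames(as.numeric(fit$par), free_names)
  full <- p_full
  full[free_names] <- est_free
  model <- params_to_model(full, components, s_fixed_value)

  n_obs <- length(vals)
  n_par <- length(free_names)
  dof <- max(n_obs - n_par, 1)
  red_chi2 <- fit$deviance / dof
  se <- tryCatch({
    covar <- solve(fit$hessian)
    sqrt(pmax(diag(covar), 0) * red_chi2)
  }, error = function(e) rep(NA_real_, n_par))
  se <- setNames(as.numeric(se), free_names)

  converged <- fit$info %in% 1:4
  fitted_vals <- model_eval(model, lags)

  # report estimates in the component order of the model (tau ascending)
  ord <- order(unname(full[paste0("tau", seq_len(components))]))
  estimates <- full
  if (components > 1 && any(ord != seq_len(components))) {
    taus <- full[paste0("tau", seq_len(components))][ord]
    frs <- c(full[paste0("F", seq_len(components - 1))],
             1 - sum(full[paste0("F", seq_len(components - 1))]))[ord]
    estimates[paste0("tau", seq_len(components))] <- taus
    estimates[paste0("F", seq_len(components - 1))] <-
      frs[seq_len(components - 1)]
    se_tau <- se[paste0("tau", seq_len(components))]
    if (all(paste0("tau", seq_len(components)) %in% names(se)))
      se[paste0("tau", seq_len(components))] <- se_tau[ord]
  }

  structure(
    list(model = model, estimates = estimates, stderr = se,
         fixed = fixed, free = free_names, components = components,
         reduced_chi_square = red_chi2,
         residuals = vals - fitted_vals, fitted = fitted_vals,
         lags = lags, values = vals, weights_used = w,
         weighted = use_w, converged = converged, info = fit$info,
         message = fit$message, n_evals = n_evals,
         curve = curve, drop_first = drop_first),
    class = "fccs_fit")
}

#' Diffusion amplitude of a fitted model
#'
#' The triplet-stripped zero-lag amplitude 1/N of a fitted (or
#' constructed) diffusion model; the quantity the RCA statistic is
#' built from.
#'
#' @param x An `fccs_fit` or `fccs_model`.
#' @return The amplitude G(0) - 1 with the triplet factor removed.
#' @export
fit_amplitude <- function(x) {
  m <- if (inherits(x, "fccs_fit")) x$model else x
  if (!inherits(m, "fccs_model")) abort_config("not a fitted model")
  1 / m$N
}

#' Calibrate the structure parameter from a reference-dye curve
#'
#' Fits a one-component model with the structure parameter free to the
#' auto-correlation of a dye of known diffusion coefficient (the
#' classical Rhodamine-6G calibration), and converts the fitted
#' diffusion time to a beam waist via w0 = sqrt(4 D tauD). The
#' returned `s` is then held fixed in all cell-curve fits.
#'
#' The fitted structure parameter responds strongly to any constant
#' depression of the measured curve, so calibrations should pool
#' repeated dye runs ([pool_curves()]) with full-trace curve values
#' (`values = "full"` in [segment_errors()]), which keeps the
#' finite-measurement normalization bias negligible. For short
#' single-run measurements where that bias is material, the baseline
#' can be floated instead (`offset_free = TRUE`) — at the price of a
#' weak degeneracy with the axial decay that inflates the scatter of
#' the fitted s.
#'
#' @param reference_curve `fccs_curve` from a single-species dye
#'   measurement.
#' @param known_D Dye diffusion coefficient in um^2/s (> 0).
#' @param offset_free Float the baseline; see [fit_curve()].
#' @param ... Passed to [fit_curve()].
#' @return List of class `fccs_calibration`: `s`, `tau_d`, `w0` (um),
#'   `z0` (um) and the underlying `fit`.
#' @export
calibrate_structure_parameter <- function(reference_curve, known_D,
                                          offset_free = FALSE, ...) {
  if (!is_scalar_number(known_D) || known_D <= 0)
    abort_config("known_D must be > 0")
  fit <- fit_curve(reference_curve, components = 1L, s = NULL,
                   offset_free = offset_free, ...)
  if (!fit$converged)
    abort_numeric("calibration fit did not converge: %s", fit$message)
  tau_d <- fit$model$tau[1]
  w0 <- sqrt(4 * known_D * tau_d)
  structure(list(s = fit$model$s, tau_d = tau_d, w0 = w0,
                 z0 = fit$model$s * w0, fit = fit),
            class = "fccs_calibration")
}

#' @export
print.fccs_calibration <- function(x, ...) {
  cat(sprintf(
    "Structure-parameter calibration: s = %.4g (tau_D = %.4g s, w0 = %.4g um)\n",
    x$s, x$tau_d, x$w0))
  invisible(x)
}

# ---- fccs_fit methods -------------------------------------------------

#' @export
print.fccs_fit <- function(x, ...) {
  cat(sprintf("FCCS diffusion-model fit (%d component%s%s), curve kind %s\n",
              x$components, if (x$components > 1) "s" else "",
              if (x$model$triplet_fraction > 0) " + triplet" else "",
              x$curve$kind))
  print(x$model)
  cat(sprintf("  reduced chi-square: %.4g (%sweighted), converged: %s\n",
              x$reduced_chi_square, if (x$weighted) "" else "un",
              x$converged))
  invisible(x)
}

#' @export
coef.fccs_fit <- function(object, ...) {
  out <- object$estimates
  attr(out, "free") <- object$free
  out
}

#' @export
vcov.fccs_fit <- function(object, ...) {
  se <- object$stderr
  diag(se^2, nrow = length(se))
}

#' @export
predict.fccs_fit <- function(object, lags = NULL, ...) {
  if (is.null(lags)) lags <- object$lags
  model_eval(object$model, lags)
}

#' @export
residuals.fccs_fit <- function(object, type = c("raw", "weighted"), ...) {
  type <- match.arg(type)
  if (type == "raw") object$residuals
  else object$residuals / object$weights_used
}

#' @export
fitted.fccs_fit <- function(object, ...) object$fitted

#' @export
deviance.fccs_fit <- function(object, ...)
  sum((object$residuals / object$weights_used)^2)

#' @export
summary.fccs_fit <- function(object, ...) {
  est <- object$estimates[object$free]
  tab <- cbind(Estimate = est,
               `Std. Error` = object$stderr[object$free])
  degenerate <- FALSE
  if (object$components > 1) {
    fr <- object$model$fractions
    taus <- object$model$tau
    degenerate <- max(fr) >= 0.95 || max(taus) / min(taus) < 2
  }
  structure(list(coefficients = tab, fixed = object$fixed,
                 reduced_chi_square = object$reduced_chi_square,
                 converged = object$converged, info = object$info,
                 message = object$message, weighted = object$weighted,
                 degenerate = degenerate, components = object$components,
                 model = object$model),
            class = "summary.fccs_fit")
}

#' @export
print.summary.fccs_fit <- function(x, ...) {
  cat(sprintf("FCCS diffusion-model fit, %d component(s)\n", x$components))
  print(round(x$coefficients, 6))
  if (length(x$fixed))
    cat("fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                        collapse = ", "), "\n")
  cat(sprintf("reduced chi-square: %.4g; converged: %s (%s)\n",
              x$reduced_chi_square, x$converged, x$message))
  if (x$degenerate)
    cat("note: components poorly separated",
        "(near-degenerate fractions or diffusion times)\n")
  invisible(x)
}

#' @export
plot.fccs_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  keep <- x$lags > 0
  plot(x$lags[keep], x$values[keep], log = "x",
       xlab = expression(tau ~ "(s)"), ylab = expression(G(tau)),
       main = sprintf("Fit (%s, %d component(s))", x$curve$kind,
                      x$components), ...)
  graphics::lines(x$lags[keep], x$fitted[keep], col = "red3", lwd = 2)
  abline(h = 1, lty = 3)
  plot(x$lags[keep], x$residuals[keep], log = "x", type = "h",
       xlab = expression(tau ~ "(s)"), ylab = "residual")
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Parametric-bootstrap correlation curves from a fitted model
#'
#' Draws synthetic curves on the fitted lag grid: the fitted model plus
#' Gaussian noise with the per-lag standard errors of the input curve
#' (or the residual SD when no errors are available). Useful for
#' visualising fit uncertainty and for quick resampling checks.
#'
#' @param object An `fccs_fit`.
#' @param nsim Number of curves.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of `fccs_curve` objects.
#' @export
simulate.fccs_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  noise_sd <- if (object$weighted) object$weights_used
              else rep(sd(object$residuals), length(object$lags))
  lapply(seq_len(nsim), function(i) {
    new_curve(object$curve$kind, object$lags,
              object$fitted + rnorm(length(object$lags), 0, noise_sd),
              stderr = noise_sd, bin_time = object$curve$bin_time,
              estimator = "simulated")
  })
}
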