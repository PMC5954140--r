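#' @rdname correlate_direct
#' @export
new_curve <- function(kind, lags, values, stderr = NULL,
                      n_segments = NA_integer_, bin_time = NA_real_,
                      estimator = "direct") {
  kind <- match.arg(kind, c("gg", "rr", "gr"))
  if (length(lags) != length(values))
    abort_format("lags and values differ in length")
  if (any(!is.finite(values)))
    abort_format("correlation values must be finite")
  if (any(lags < 0) || any(diff(lags) <= 0))
    abort_format("lags must be non-negative and strictly increasing")
  if (!is.null(stderr)) {
    if (length(stderr) != length(values) || any(stderr < 0, na.rm = TRUE))
      abort_format("stderr must be non-negative, one per lag")
  }
  structure(list(kind = kind, lags = as.numeric(lags),
                 values = as.numeric(values),
                 stderr = if (is.null(stderr)) rep(NA_real_, length(values))
                          else as.numeric(stderr),
                 n_segments = n_segments, bin_time = bin_time,
                 estimator = estimator),
            class = "fccs_curve")
}

#' @export
print.fccs_curve <- function(x, ...) {
  cat(sprintf(
    "FCCS correlation curve [%s], %d lags (%.3g .. %.3g s), estimator %s\n",
    x$kind, length(x$lags), min(x$lags), max(x$lags), x$estimator))
  amp_idx <- if (x$lags[1] == 0 && length(x$lags) > 1) 2L else 1L
  cat(sprintf("  amplitude G(%.3g s) - 1 = %.4g\n",
              x$lags[amp_idx], x$values[amp_idx] - 1))
  invisible(x)
}

#' @export
plot.fccs_curve <- function(x, ..., log = "x") {
  keep <- x$lags > 0
  plot(x$lags[keep], x$values[keep], log = log,
       xlab = expression(tau ~ "(s)"), ylab = expression(G(tau)),
       main = sprintf("Correlation curve (%s)", x$kind), ...)
  if (any(is.finite(x$stderr[keep]))) {
    suppressWarnings(arrows(x$lags[keep], x$values[keep] - x$stderr[keep],
                            x$lags[keep], x$values[keep] + x$stderr[keep],
                            angle = 90, code = 3, length = 0.02,
                            col = "grey60"))
  }
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Pool repeated correlation measurements into one curve
#'
#' Averages curves from repeated measurements of the same system on a
#' common lag grid (e.g. several reference-dye runs before a
#' calibration fit). Values are the per-lag means; standard errors
#' combine the per-curve errors as sqrt(mean(se^2)/n) when available,
#' falling back to the spread across curves.
#'
#' @param curves List of `fccs_curve` objects with identical kind and
#'   lag grids.
#' @return A single `fccs_curve`.
#' @export
pool_curves <- function(curves) {
  if (!length(curves) || !all(vapply(curves, inherits, logical(1),
                                     "fccs_curve")))
    abort_config("curves must be a non-empty list of fccs_curve objects")
  lags <- curves[[1]]$lags
  kind <- curves[[1]]$kind
  for (cu in curves) {
    if (!identical(cu$kind, kind) || length(cu$lags) != length(lags) ||
        max(abs(cu$lags - lags)) > 1e-12)
      abort_config("curves must share one kind and lag grid")
  }
  n <- length(curves)
  vals <- do.call(rbind, lapply(curves, `[[`, "values"))
  ses <- do.call(rbind, lapply(curves, `[[`, "stderr"))
  se <- if (all(is.finite(ses))) sqrt(colMeans(ses^2) / n)
        else if (n > 1) apply(vals, 2, sd) / sqrt(n)
        else rep(NA_real_, length(lags))
  new_curve(kind, lags, colMeans(vals), stderr = se,
            n_segments = n, bin_time = curves[[1]]$bin_time,
            estimator = "pooled")
}

# channel pair for a curve kind; the cross-correlation leads with the red
# channel (i = r) and lags the green one (j = g)
channels_for_kind <- function(trace, kind) {
  switch(kind,
         gg = list(x = as.numeric(trace$counts_green),
                   y = as.numeric(trace$counts_green)),
         rr = list(x = as.numeric(trace$counts_red),
                   y = as.numeric(trace$counts_red)),
         gr = list(x = as.numeric(trace$counts_red),
                   y = as.numeric(trace$counts_green)),
         abort_config("kind must be one of gg, rr, gr"))
}

# Single-lag normalized correlation with symmetric normalization: channel
# means are computed over the same overlapping window as the product, which
# removes the dominant finite-trace bias.
corr_at_lag <- function(x, y, k) {
  n <- length(x)
  xs <- if (k == 0) x else x[1:(n - k)]
  ys <- if (k == 0) y else y[(k + 1):n]
  mx <- mean(xs)
  my <- mean(ys)
  1 + (mean(xs * ys) - mx * my) / (mx * my)
}

check_trace_kind <- function(trace, kind) {
  ch <- channels_for_kind(trace, kind)
  if (mean(ch$x) <= 0 || mean(ch$y) <= 0)
    abort_numeric(
      "zero-mean channel: correlation undefined (no correlated signal)")
  ch
}

#' Correlation estimators for two-channel traces
#'
#' `correlate_direct()` evaluates the normalized correlation function
#' G(tau) = 1 + <dI_i(t) dI_j(t+tau)> / (<I_i><I_j>) at every integer lag
#' up to `max_lag_bins`. `correlate_multitau()` evaluates the same
#' estimator on a quasi-logarithmic multi-tau lag grid
#' (`points_per_stage` linearly spaced lags per stage, lag spacing
#' doubling per stage), which covers decades of lag time at a fraction
#' of the cost and is the grid commercial hardware correlators use.
#' Channel means are taken over the overlapping window of each lag
#' (symmetric normalization). Kind `"gg"` auto-correlates the green
#' channel, `"rr"` the red one, and `"gr"` cross-correlates red against
#' lagged green.
#'
#' Lag zero is included by default (`min_lag_bins = 0`) but carries shot
#' noise in the auto-correlations; model fits drop it by default.
#'
#' @param trace An `fccs_trace`.
#' @param kind `"gg"`, `"rr"` or `"gr"`.
#' @param max_lag_bins Largest lag in bins (< half the trace length).
#' @param min_lag_bins Smallest lag in bins (default 0).
#' @param points_per_stage Linear lags per multi-tau stage (default 16).
#' @param n_stages Number of stages; default: as many as the trace
#'   length allows.
#' @return An object of class `fccs_curve` with fields `lags` (s),
#'   `values`, `stderr` (NA unless estimated, see [segment_errors()]),
#'   `bin_time` and `estimator`.
#' @seealso [segment_errors()] for per-lag uncertainties.
#' @export
correlate_direct <- function(trace, kind = c("gg", "rr", "gr"),
                             max_lag_bins, min_lag_bins = 0L) {
  kind <- match.arg(kind)
  ch <- check_trace_kind(trace, kind)
  n <- length(ch$x)
  if (!is_count_scalar(max_lag_bins) || max_lag_bins < min_lag_bins)
    abort_config("max_lag_bins must be an integer >= min_lag_bins")
  if (max_lag_bins >= n / 2)
    abort_config("max_lag_bins must be < trace length / 2 (%d)", floor(n / 2))
  ks <- seq.int(min_lag_bins, max_lag_bins)
  vals <- vapply(ks, function(k) corr_at_lag(ch$x, ch$y, k), numeric(1))
  new_curve(kind, ks * trace$bin_time, vals, bin_time = trace$bin_time,
            estimator = "direct")
}

# the multi-tau lag grid in bins: stage 0 covers 0/1..(m-1); stage s >= 1
# covers (m/2 .. m-1) * 2^s
multitau_grid <- function(n, points_per_stage = 16L, n_stages = NULL,
                          min_lag_bins = 0L) {
  m <- as.integer(points_per_stage)
  if (m < 4 || m %% 2L != 0L)
    abort_config("points_per_stage must be an even integer >= 4")
  if (is.null(n_stages)) {
    n_stages <- 1L
    while ((m - 1) * 2^n_stages < n / 2 &&
           n >= 2^(n_stages + 1) * m) n_stages <- n_stages + 1L
  }
  if (n < 2^n_stages * m)
    abort_config(
      "trace too short for %d stages: need at least %d bins, have %d",
      n_stages, 2^n_stages * m, n)
  ks <- seq.int(min_lag_bins, m - 1L)
  if (n_stages > 1) {
    for (s in seq_len(n_stages - 1L)) {
      ks <- c(ks, seq.int(m / 2L, m - 1L) * 2^s)
    }
  }
  ks <- ks[ks < n / 2]
  sort(unique(ks))
}

#' @rdname correlate_direct
#' @export
correlate_multitau <- function(trace, kind = c("gg", "rr", "gr"),
                               points_per_stage = 16L, n_stages = NULL,
                               min_lag_bins = 0L) {
  kind <- match.arg(kind)
  ch <- check_trace_kind(trace, kind)
  n <- length(ch$x)
  ks <- multitau_grid(n, points_per_stage, n_stages, min_lag_bins)
  vals <- vapply(ks, function(k) corr_at_lag(ch$x, ch$y, k), numeric(1))
  new_curve(kind, ks * trace$bin_time, vals, bin_time = trace$bin_time,
            estimator = "multitau")
}

#' Correlation curve with segment-resampling uncertainties
#'
#' Splits the trace into `n_segments` equal contiguous segments, computes
#' the correlation curve of each segment on a common lag grid, and
#' returns the mean curve with per-lag standard errors
#' (sample SD / sqrt(n_segments)). These are the weights the model fit
#' uses.
#'
#' @inheritParams correlate_direct
#' @param n_segments Number of segments (>= 3, each >= 100 bins).
#' @param estimator `"multitau"` (default) or `"direct"`.
#' @param values `"segments"` (default) reports the mean of the
#'   per-segment curves; `"full"` reports the full-trace estimate on
#'   the same lag grid and uses the segments only for the standard
#'   errors. The full-trace estimate carries about n_segments times
#'   less finite-length normalization bias (which scales as one over
#'   the correlated length), at the price of lags being limited by the
#'   segment grid; the dye calibration uses it.
#' @param ... Passed to the underlying estimator
#'   (`points_per_stage`, `n_stages` or `max_lag_bins`).
#' @return An `fccs_curve` with populated `stderr` and `n_segments`.
#' @export
segment_errors <- function(trace, kind = c("gg", "rr", "gr"),
                           n_segments = 10L,
                           estimator = c("multitau", "direct"),
                           min_lag_bins = 0L,
                           values = c("segments", "full"), ...) {
  kind <- match.arg(kind)
  estimator <- match.arg(estimator)
  values <- match.arg(values)
  if (!is_count_scalar(n_segments) || n_segments < 3)
    abort_config("n_segments must be an integer >= 3")
  n <- length(trace$counts_green)
  seg_len <- floor(n / n_segments)
  if (seg_len < 100)
    abort_config("segments must have >= 100 bins (have %d)", seg_len)
  check_trace_kind(trace, kind)

  sub_curve <- function(i) {
    idx <- ((i - 1) * seg_len + 1):(i * seg_len)
    sub <- structure(list(bin_time = trace$bin_time,
                          counts_green = trace$counts_green[idx],
                          counts_red = trace$counts_red[idx]),
                     class = "fccs_trace")
    if (estimator == "multitau")
      correlate_multitau(sub, kind, min_lag_bins = min_lag_bins, ...)
    else
      correlate_direct(sub, kind, min_lag_bins = min_lag_bins, ...)
  }
  curves <- lapply(seq_len(n_segments), sub_curve)
  vals <- do.call(rbind, lapply(curves, `[[`, "values"))
  se <- apply(vals, 2, sd) / sqrt(n_segments)
  if (values == "segments") {
    out_vals <- colMeans(vals)
    lags <- curves[[1]]$lags
  } else {
    grid_bins <- round(curves[[1]]$lags / trace$bin_time)
    full <- if (estimator == "multitau") {
      ks <- grid_bins
      ch <- channels_for_kind(trace, kind)
      vapply(ks, function(k) corr_at_lag(ch$x, ch$y, k), numeric(1))
    } else {
      correlate_direct(trace, kind, max_lag_bins = max(grid_bins),
                       min_lag_bins = min_lag_bins)$values[
                         match(grid_bins,
                               seq.int(min_lag_bins, max(grid_bins)))]
    }
    out_vals <- full
    lags <- curves[[1]]$lags
  }
  new_curve(kind, lags, out_vals, stderr = se,
            n_segments = as.integer(n_segments),
            bin_time = trace$bin_time,
            estimator = paste0(estimator, "+segments",
                               if (values == "full") "+fullvalues" else ""))
}
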