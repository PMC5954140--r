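#' Bundle the three curves and fits of one FCCS measurement
#'
#' One dual-color measurement yields a green auto-correlation (`gg`),
#' a red auto-correlation (`rr`) and a cross-correlation (`gr`), each
#' with its fitted diffusion model.
#'
#' @param curve_gg,curve_rr,curve_gr `fccs_curve` objects.
#' @param fit_gg,fit_rr,fit_gr Matching `fccs_fit` objects.
#' @param cell_id Identifier of the measured cell.
#' @param condition Experimental condition label.
#' @return An object of class `fccs_measurement`.
#' @export
fccs_measurement <- function(curve_gg, curve_rr, curve_gr,
                             fit_gg, fit_rr, fit_gr,
                             cell_id = NA_character_,
                             condition = NA_character_) {
  for (cu in list(curve_gg, curve_rr, curve_gr))
    if (!inherits(cu, "fccs_curve")) abort_config("curves must be fccs_curve")
  for (ft in list(fit_gg, fit_rr, fit_gr))
    if (!inherits(ft, "fccs_fit")) abort_config("fits must be fccs_fit")
  structure(list(curve_gg = curve_gg, curve_rr = curve_rr,
                 curve_gr = curve_gr, fit_gg = fit_gg, fit_rr = fit_rr,
                 fit_gr = fit_gr, cell_id = cell_id, condition = condition),
            class = "fccs_measurement")
}

#' Relative cross-correlation amplitude from fitted amplitudes
#'
#' Core arithmetic of the interaction statistic. Amplitudes are the
#' triplet-stripped diffusion amplitudes G(0) - 1 = 1/N of the fitted
#' models. The relative cross-correlation amplitude is
#' RCA = (Gc(0) - 1) / (Gr(0) - 1) under the default red normalization,
#' which by the ideal identities Gc(0) - 1 = Nc/(Ng Nr) and
#' Gx(0) - 1 = 1/Nx equals the bound fraction Nc/Ng (the fraction of
#' green-labelled molecules in complexes). Green normalization yields
#' Nc/Nr; `"min_amplitude"` divides by the smaller auto-correlation
#' amplitude, i.e. normalizes to the more abundant channel.
#'
#' @param amp_c,amp_r,amp_g Cross, red-auto and green-auto amplitudes.
#' @param normalization `"red"` (default), `"green"` or
#'   `"min_amplitude"`.
#' @return An object of class `fccs_interaction` with fields `rca`,
#'   `normalization`, `nc_over_ng`, `nc_over_nr` and `amplitudes`.
#' @examples
#' rca_from_amplitudes(0.3, 1, 1)   # 30 % bound fraction
#' @export
rca_from_amplitudes <- function(amp_c, amp_r, amp_g,
                                normalization = c("red", "green",
                                                  "min_amplitude")) {
  normalization <- match.arg(normalization)
  for (a in list(amp_c, amp_r, amp_g))
    if (!is_scalar_number(a)) abort_numeric("amplitudes must be finite")
  denom <- switch(normalization,
                  red = amp_r,
                  green = amp_g,
                  min_amplitude = min(amp_r, amp_g))
  if (denom <= 0)
    abort_numeric("no autocorrelation signal: denominator amplitude <= 0")
  structure(list(rca = amp_c / denom,
                 normalization = normalization,
                 nc_over_ng = amp_c / amp_r,
                 nc_over_nr = amp_c / amp_g,
                 amplitudes = c(cross = amp_c, red = amp_r, green = amp_g)),
            class = "fccs_interaction")
}

#' Relative cross-correlation amplitude of a measurement
#'
#' Extrapolates the three fitted models of a measurement to zero lag
#' (triplet factor removed, so the amplitudes are the pure diffusion
#' amplitudes 1/N) and forms the RCA and both bound fractions; see
#' [rca_from_amplitudes()] for the arithmetic and normalization
#' options.
#'
#' @param measurement An [fccs_measurement()].
#' @param normalization `"red"` (default), `"green"` or
#'   `"min_amplitude"`.
#' @return An `fccs_interaction` carrying `cell_id` and `condition`
#'   from the measurement.
#' @export
compute_rca <- function(measurement,
                        normalization = c("red", "green",
                                          "min_amplitude")) {
  if (!inherits(measurement, "fccs_measurement"))
    abort_config("measurement must be an fccs_measurement")
  for (nm in c("fit_gg", "fit_rr", "fit_gr"))
    if (!measurement[[nm]]$converged)
      abort_numeric("%s did not converge; cannot form RCA", nm)
  out <- rca_from_amplitudes(fit_amplitude(measurement$fit_gr),
                             fit_amplitude(measurement$fit_rr),
                             fit_amplitude(measurement$fit_gg),
                             normalization)
  out$cell_id <- measurement$cell_id
  out$condition <- measurement$condition
  out
}

#' @export
print.fccs_interaction <- function(x, ...) {
  cat(sprintf("RCA = %.4g (%s normalization)\n", x$rca, x$normalization))
  cat(sprintf("  bound fractions: Nc/Ng = %.4g, Nc/Nr = %.4g\n",
              x$nc_over_ng, x$nc_over_nr))
  if (!is.null(x$condition) && !is.na(x$condition))
    cat(sprintf("  condition: %s\n", x$condition))
  invisible(x)
}

#' Full per-trace analysis: correlate, fit, interaction statistic
#'
#' Convenience wrapper running the standard chain on one trace:
#' segment-averaged correlation curves for `gg`, `rr` and `gr`, a
#' diffusion-model fit per curve with the structure parameter fixed,
#' and the RCA. This is the per-cell unit of a group comparison.
#'
#' @param trace An `fccs_trace`.
#' @param s Calibrated structure parameter (fixed in all three fits).
#' @param components Diffusion components per fit (default 1).
#' @param n_segments Segments for error estimation (default 10).
#' @param normalization RCA normalization channel.
#' @param cell_id,condition Labels carried into the result.
#' @param ... Passed to [segment_errors()].
#' @return An [fccs_measurement()] with an extra `interaction` element.
#' @export
analyze_trace <- function(trace, s, components = 1L, n_segments = 10L,
                          normalization = "red",
                          cell_id = NA_character_,
                          condition = NA_character_, ...) {
  curves <- lapply(c(gg = "gg", rr = "rr", gr = "gr"), function(k)
    segment_errors(trace, k, n_segments = n_segments, ...))
  fits <- lapply(curves, fit_curve, components = components, s = s)
  m <- fccs_measurement(curves$gg, curves$rr, curves$gr,
                        fits$gg, fits$rr, fits$gr,
                        cell_id = cell_id, condition = condition)
  m$interaction <- compute_rca(m, normalization = normalization)
  m
}

#' Compare interaction amplitudes between two groups
#'
#' Two-sample Student's t-test (equal variances by default; set
#' `welch = TRUE` for the unequal-variance form) on per-cell RCA
#' values, with the conventional significance stars
#' (* p < 0.05, ** p < 0.01, *** p < 0.005, **** p < 0.001).
#' Degenerate zero-variance input is resolved by convention: equal
#' means give p = 1, distinct means p = 0 (with a message).
#'
#' @param rcas_a,rcas_b Numeric vectors of RCA values (n >= 2 each).
#' @param labels Group labels for printing.
#' @param welch Use the Welch correction instead of pooled variance.
#' @return An object of class `fccs_group_comparison`: group summaries,
#'   `t_statistic`, `df`, `p_value`, `stars`.
#' @examples
#' compare_groups(c(0.28, 0.33, 0.30), c(0.02, 0.04, 0.05))
#' @export
compare_groups <- function(rcas_a, rcas_b, labels = c("A", "B"),
                           welch = FALSE) {
  for (v in list(rcas_a, rcas_b)) {
    if (length(v) < 2) abort_config("each group needs n >= 2")
    if (any(!is.finite(v))) abort_config("group values must be finite")
  }
  n_a <- length(rcas_a); n_b <- length(rcas_b)
  pooled_var <- (sum((rcas_a - mean(rcas_a))^2) +
                   sum((rcas_b - mean(rcas_b))^2)) / (n_a + n_b - 2)
  if (pooled_var == 0 && !welch) {
    equal <- isTRUE(all.equal(mean(rcas_a), mean(rcas_b)))
    message("zero pooled variance; p set by convention")
    t_stat <- if (equal) 0 else Inf * sign(mean(rcas_a) - mean(rcas_b))
    p <- if (equal) 1 else 0
    df <- n_a + n_b - 2
  } else {
    ht <- t.test(rcas_a, rcas_b, var.equal = !welch)
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  structure(list(labels = labels,
                 n = c(n_a, n_b),
                 means = c(mean(rcas_a), mean(rcas_b)),
                 sds = c(sd(rcas_a), sd(rcas_b)),
                 t_statistic = t_stat, df = df, p_value = p,
                 stars = p_stars(p), welch = welch),
            class = "fccs_group_comparison")
}

# significance stars: * < 0.05, ** < 0.01, *** < 0.005, **** < 0.001
p_stars <- function(p) {
  if (p < 0.001) "****"
  else if (p < 0.005) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' @export
print.fccs_group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s t-test)\n",
              if (x$welch) "Welch" else "Student's"))
  for (i in 1:2)
    cat(sprintf("  %s: n = %d, mean RCA = %.4g, sd = %.4g\n",
                x$labels[i], x$n[i], x$means[i], x$sds[i]))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g %s\n",
              x$t_statistic, x$df, x$p_value, x$stars))
  invisible(x)
}

#' Summarize interaction amplitudes per condition
#'
#' Per-condition mean, SD and n of the RCA, as one would tabulate a
#' bar-chart summary of interaction amplitudes across co-expression
#' conditions. Accepts a list of analyzed measurements (with
#' `interaction` elements or paired with `rca` values) or a data frame
#' with columns `condition` and `rca`.
#'
#' @param measurements List of [fccs_measurement()] objects carrying
#'   `interaction` results, list of `fccs_interaction` objects, or a
#'   data frame with `condition` and `rca` columns.
#' @return Data frame with columns `condition`, `n`, `mean_rca`,
#'   `sd_rca` (NA when n = 1).
#' @export
summarize_condition <- function(measurements) {
  if (is.data.frame(measurements)) {
    df <- measurements
    if (!all(c("condition", "rca") %in% names(df)))
      abort_config("data frame needs columns 'condition' and 'rca'")
  } else if (is.list(measurements)) {
    rows <- lapply(measurements, function(m) {
      it <- if (inherits(m, "fccs_interaction")) m
            else if (inherits(m, "fccs_measurement")) m$interaction
            else abort_config("unsupported element in measurements list")
      data.frame(condition = if (is.null(it$condition) || is.na(it$condition))
                   "unlabelled" else it$condition,
                 rca = it$rca, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else abort_config("unsupported measurements input")
  all_conditions <- unique(as.character(df$condition))
  df <- df[is.finite(df$rca), , drop = FALSE]
  empty <- setdiff(all_conditions, as.character(df$condition))
  if (length(empty))
    warning("omitting condition(s) without finite RCA values: ",
            paste(empty, collapse = ", "), call. = FALSE)
  agg <- lapply(split(df$rca, df$condition), function(v)
    c(n = length(v), mean_rca = mean(v),
      sd_rca = if (length(v) > 1) sd(v) else NA_real_))
  out <- data.frame(condition = names(agg),
                    do.call(rbind, agg),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$n <- as.integer(out$n)
  out
}
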