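# Text formats, all documented in inst/FORMATS.md:
#   trace: CSV `bin_index,counts_green,counts_red` + sidecar YAML metadata
#   curve: CSV `lag_s,value,stderr` with `#`-prefixed header comments
#   fit:   JSON (estimates, stderr, fixed, chi-square, residuals)
# Numeric fields are written with %.17g so a write/read round trip is
# exact to the double.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read and write two-channel traces, curves and fit results
#'
#' Lossless plain-text serialization of the pipeline's intermediate
#' artifacts. Traces are CSV files with columns
#' `bin_index,counts_green,counts_red` plus a YAML sidecar
#' (`<path>.meta.yaml`) holding `bin_time`, optics, seed and species
#' ground truth; curves are CSV `lag_s,value,stderr` with commented
#' header metadata; fits are JSON. Readers validate the formats and
#' report the offending line or row on failure.
#'
#' @param trace,curve,fit Object to write.
#' @param path File path.
#' @param bin_time Bin width in s, required by `read_trace()` when no
#'   metadata sidecar exists.
#' @return Readers return the reconstructed object; writers return
#'   `path` invisibly.
#' @name fccs_io
NULL

#' @rdname fccs_io
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "fccs_trace")) abort_config("not an fccs_trace")
  n <- length(trace$counts_green)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("bin_index,counts_green,counts_red", con)
  writeLines(paste(seq_len(n) - 1L, trace$counts_green, trace$counts_red,
                   sep = ","), con)
  meta <- list(bin_time = trace$bin_time, seed = trace$meta$seed)
  if (!is.null(trace$meta$optics))
    meta$optics <- unclass(trace$meta$optics)
  if (!is.null(trace$meta$species))
    meta$species <- lapply(trace$meta$species, unclass)
  if (!is.null(trace$meta$realized_counts))
    meta$realized_counts <- trace$meta$realized_counts
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15L)
  invisible(path)
}

#' @rdname fccs_io
#' @export
read_trace <- function(path, bin_time = NULL) {
  if (!file.exists(path)) abort_format("no such file: %s", path)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "bin_index,counts_green,counts_red") &&
      !identical(trimws(header), "bin_index\tcounts_green\tcounts_red"))
    abort_format("line 1: expected header 'bin_index,counts_green,counts_red'")
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.csv(path, sep = sep)
  for (col in c("counts_green", "counts_red")) {
    v <- df[[col]]
    if (!is.numeric(v)) abort_format("column %s is not numeric", col)
    bad <- which(abs(v - round(v)) > 0 | v < 0)
    if (length(bad))
      abort_format("non-integer counts in column %s (line %d)",
                   col, bad[1] + 1L)
  }
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  bt <- if (!is.null(bin_time)) bin_time else meta$bin_time
  if (is.null(bt))
    abort_config("bin_time not given and no metadata sidecar found")
  if (!is.null(meta$optics)) {
    meta$optics <- do.call(fccs_optics, meta$optics[
      intersect(names(meta$optics), names(formals(fccs_optics)))])
  }
  if (!is.null(meta$species)) {
    meta$species <- lapply(meta$species, function(sp)
      do.call(fccs_species, sp[
        intersect(names(sp), names(formals(fccs_species)))]))
  }
  new_trace(df$counts_green, df$counts_red, bt, meta = meta)
}

#' @rdname fccs_io
#' @export
write_curve <- function(curve, path) {
  if (!inherits(curve, "fccs_curve")) abort_config("not an fccs_curve")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", curve$kind),
               sprintf("# bin_time: %s", fmt_num(curve$bin_time)),
               sprintf("# estimator: %s", curve$estimator),
               sprintf("# n_segments: %s", curve$n_segments),
               "lag_s,value,stderr"), con)
  writeLines(paste(fmt_num(curve$lags), fmt_num(curve$values),
                   fmt_num(curve$stderr), sep = ","), con)
  invisible(path)
}

#' @rdname fccs_io
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) abort_format("no such file: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || trimws(body[1]) != "lag_s,value,stderr")
    abort_format("expected header 'lag_s,value,stderr' after comments")
  df <- read.csv(text = body)
  if (nrow(df) < 1) abort_format("empty curve file")
  inc <- diff(df$lag_s)
  if (any(inc <= 0))
    abort_format("lags not strictly increasing at row %d",
                 which(inc <= 0)[1] + 1L)
  kind <- get_meta("kind")
  if (!kind %in% c("gg", "rr", "gr"))
    abort_format("missing or invalid '# kind:' header comment")
  n_seg <- suppressWarnings(as.integer(get_meta("n_segments")))
  new_curve(kind, df$lag_s, df$value,
            stderr = if (all(is.na(df$stderr))) NULL else df$stderr,
            n_segments = if (is.na(n_seg)) NA_integer_ else n_seg,
            bin_time = suppressWarnings(as.numeric(get_meta("bin_time"))),
            estimator = get_meta("estimator"))
}

#' @rdname fccs_io
#' @export
write_fit <- function(fit, path) {
  if (!inherits(fit, "fccs_fit")) abort_config("not an fccs_fit")
  payload <- list(
    estimates = as.list(fit$estimates),
    stderr = as.list(fit$stderr),
    fixed = fit$fixed,
    free = fit$free,
    components = fit$components,
    triplet = fit$model$triplet_fraction > 0,
    kind = fit$curve$kind,
    reduced_chi_square = fit$reduced_chi_square,
    converged = fit$converged,
    info = fit$info,
    message = fit$message,
    weighted = fit$weighted,
    drop_first = fit$drop_first,
    lags = fit$lags,
    values = fit$values,
    residuals = fit$residuals)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname fccs_io
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) abort_format("no such file: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  est <- unlist(p$estimates)
  components <- as.integer(p$components)
  s_fixed <- if ("s" %in% names(p$fixed)) p$fixed$s else NULL
  model <- params_to_model(est, components, s_fixed)
  lags <- as.numeric(p$lags)
  vals <- as.numeric(p$values)
  structure(
    list(model = model, estimates = est, stderr = unlist(p$stderr),
         fixed = p$fixed, free = unlist(p$free), components = components,
         reduced_chi_square = p$reduced_chi_square,
         residuals = as.numeric(p$residuals),
         fitted = vals - as.numeric(p$residuals),
         lags = lags, values = vals,
         weights_used = rep(1, length(lags)),
         weighted = isTRUE(p$weighted), converged = isTRUE(p$converged),
         info = p$info, message = p$message, n_evals = NA_integer_,
         curve = new_curve(p$kind, lags, vals,
                           bin_time = if (length(lags) > 1)
                             min(diff(lags)) else NA_real_,
                           estimator = "from-file"),
         drop_first = p$drop_first),
    class = "fccs_fit")
}
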