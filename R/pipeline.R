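#' Read, validate and write pipeline configurations
#'
#' A pipeline configuration is a YAML document (or the equivalent named
#' list) describing a full in-silico experiment: the shared optics and
#' acquisition settings, one or more named conditions (each a species
#' mixture measured in `n_cells` cells), correlator / fit / RCA
#' settings, the group comparisons to run, a global `seed` and an
#' `output` directory. `read_config()` parses and validates (fail-fast,
#' before any stage runs); `write_config()` serializes with enough
#' precision that `read_config(write_config(x))` reproduces `x`.
#'
#' @param path YAML file path.
#' @param config A pipeline configuration list.
#' @return `read_config()`: validated configuration of class
#'   `fccs_pipeline_config`; `write_config()`: `path`, invisibly.
#' @name fccs_config
NULL

#' @rdname fccs_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_format("no such file: %s", path)
  as_pipeline_config(yaml::read_yaml(path))
}

#' @rdname fccs_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(strip_config(config), path, precision = 15L)
  invisible(path)
}

strip_config <- function(config) {
  x <- unclass(config)
  x$optics <- unclass(x$optics)
  x$optics$structure_parameter <- NULL
  x$optics$v_eff <- NULL
  x$conditions <- lapply(x$conditions, function(cn) {
    cn$species <- lapply(cn$species, unclass)
    cn
  })
  x
}

#' @rdname fccs_config
#' @export
as_pipeline_config <- function(config) {
  if (inherits(config, "fccs_pipeline_config")) return(config)
  if (!is.list(config)) abort_config("config must be a list")
  need <- c("seed", "conditions")
  miss <- setdiff(need, names(config))
  if (length(miss))
    abort_config("config missing field(s): %s", paste(miss, collapse = ", "))
  if (is.null(config$output)) config$output <- "fccs-out"
  if (is.null(config$compare)) config$compare <- list()
  defaults <- list(
    simulation = list(duration = 2, bin_time = 5e-5, time_step = NULL,
                      box = c(5, 5, 5)),
    optics = list(w0 = 0.25, z0 = 1.25),
    correlate = list(estimator = "multitau", n_segments = 10L,
                     points_per_stage = 16L),
    fit = list(components = 1L, s = NULL, triplet = FALSE),
    rca = list(normalization = "red"))
  for (nm in names(defaults)) {
    config[[nm]] <- modifyList(defaults[[nm]],
                               if (is.null(config[[nm]])) list()
                               else config[[nm]])
  }
  if (!is_count_scalar(config$seed)) abort_config("seed must be an integer")

  op_args <- config$optics[intersect(names(config$optics),
                                     names(formals(fccs_optics)))]
  config$optics <- do.call(fccs_optics, op_args)
  if (is.null(config$fit$s))
    config$fit$s <- config$optics$structure_parameter
  if (!config$rca$normalization %in% c("red", "green", "min_amplitude"))
    abort_config("rca normalization must be red, green or min_amplitude")
  if (!config$correlate$estimator %in% c("multitau", "direct"))
    abort_config("correlate estimator must be multitau or direct")

  if (!length(config$conditions)) abort_config("no conditions defined")
  config$conditions <- lapply(config$conditions, function(cn) {
    if (is.null(cn$name)) abort_config("every condition needs a name")
    if (is.null(cn$n_cells)) cn$n_cells <- 1L
    if (!is_count_scalar(cn$n_cells) || cn$n_cells < 1)
      abort_config("condition %s: n_cells must be a positive integer",
                   cn$name)
    if (is.null(cn$species)) abort_config("condition %s: no species", cn$name)
    cn$species <- lapply(cn$species, function(sp) {
      if (inherits(sp, "fccs_species")) return(sp)
      do.call(fccs_species, sp[intersect(names(sp),
                                         names(formals(fccs_species)))])
    })
    cn
  })
  for (cmp in config$compare) {
    if (length(cmp) != 2)
      abort_config("each compare entry must name two conditions")
    known <- vapply(config$conditions, `[[`, character(1), "name")
    if (!all(unlist(cmp) %in% known))
      abort_config("compare names unknown condition: %s",
                   paste(setdiff(unlist(cmp), known), collapse = ", "))
  }
  # fail-fast: every per-cell simulation config must construct cleanly
  sim <- config$simulation
  ts <- if (is.null(sim$time_step)) sim$bin_time else sim$time_step
  for (cn in config$conditions) {
    invisible(fccs_sim_config(cn$species, config$optics, sim$box,
                              duration = sim$duration,
                              bin_time = sim$bin_time, time_step = ts,
                              seed = config$seed))
  }
  config$simulation$time_step <- ts
  structure(config, class = "fccs_pipeline_config")
}

# deterministic per-cell seed derived from the global seed
derive_seed <- function(seed, condition_index, cell_index) {
  as.integer((as.numeric(seed) * 1009 + condition_index * 101 +
                cell_index) %% .Machine$integer.max)
}

#' Run the full FCCS pipeline
#'
#' Executes `simulate -> correlate -> fit -> rca -> compare` for every
#' condition and cell of a configuration, writing every intermediate
#' artifact (traces, curves, fits, the per-cell interaction table, the
#' group-comparison JSON), a manifest with per-stage inputs, outputs,
#' MD5 checksums and seeds, and a log. All randomness derives from the
#' global seed, so a rerun with the same configuration reproduces
#' byte-identical result tables. Any stage error aborts the run with
#' the stage name; the manifest marks the failed stage.
#'
#' @param config An `fccs_pipeline_config`, a plain list, or a YAML
#'   file path.
#' @param out_dir Output directory (default: `config$output`).
#' @param seed Optional override of the configuration seed.
#' @return Invisibly, a list with the interaction table (`rca_table`),
#'   the comparisons, the manifest and the output paths.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- as_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(out_dir)) out_dir <- config$output
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logln <- function(...) writeLines(sprintf(...), log_con)
  logln("fccs pipeline, package version %s",
        as.character(utils::packageVersion("fccs")))
  logln("config seed: %d", config$seed)

  manifest <- list(seed = config$seed, stages = list())
  manifest_path <- file.path(out_dir, "manifest.json")
  flush_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  record <- function(stage, status, outputs = character(), error = NULL) {
    entry <- list(status = status, outputs = as.list(outputs))
    if (length(outputs)) {
      sums <- tools::md5sum(outputs)
      entry$md5 <- as.list(unname(sums))
    }
    if (!is.null(error)) entry$error <- error
    manifest$stages[[stage]] <<- entry
    flush_manifest()
  }
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      record(stage, "failed", error = conditionMessage(res))
      logln("stage %s FAILED: %s", stage, conditionMessage(res))
      abort_numeric("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(res))
    }
    logln("stage %s complete (%.2f s)", stage,
          proc.time()[["elapsed"]] - t0)
    res
  }

  sim <- config$simulation
  cells <- list()
  for (ci in seq_along(config$conditions)) {
    cn <- config$conditions[[ci]]
    for (cell in seq_len(cn$n_cells)) {
      cells[[length(cells) + 1L]] <- list(
        condition = cn$name, condition_index = ci, cell_index = cell,
        species = cn$species,
        seed = derive_seed(config$seed, ci, cell),
        id = sprintf("%s_cell%02d", cn$name, cell))
    }
  }

  traces <- run_stage("simulate", function() {
    out <- list()
    for (cl in cells) {
      cfg <- fccs_sim_config(cl$species, config$optics, sim$box,
                             duration = sim$duration,
                             bin_time = sim$bin_time,
                             time_step = sim$time_step, seed = cl$seed)
      tr <- simulate_trace(cfg)
      p <- file.path(out_dir, paste0("trace_", cl$id, ".csv"))
      write_trace(tr, p)
      logln("  %s: realized counts %s", cl$id,
            paste(tr$meta$realized_counts, collapse = "/"))
      out[[cl$id]] <- list(trace = tr, path = p, cell = cl)
    }
    record("simulate", "complete",
           unlist(lapply(out, `[[`, "path")))
    out
  })

  curves <- run_stage("correlate", function() {
    out <- list()
    paths <- character()
    for (id in names(traces)) {
      tr <- traces[[id]]$trace
      cs <- lapply(c(gg = "gg", rr = "rr", gr = "gr"), function(k)
        segment_errors(tr, k,
                       n_segments = config$correlate$n_segments,
                       estimator = config$correlate$estimator,
                       points_per_stage = config$correlate$points_per_stage))
      for (k in names(cs)) {
        p <- file.path(out_dir, sprintf("curve_%s_%s.csv", id, k))
        write_curve(cs[[k]], p)
        paths <- c(paths, p)
      }
      out[[id]] <- cs
    }
    record("correlate", "complete", paths)
    out
  })

  fits <- run_stage("fit", function() {
    out <- list()
    paths <- character()
    for (id in names(curves)) {
      fs <- lapply(curves[[id]], fit_curve,
                   components = config$fit$components,
                   s = config$fit$s, triplet = isTRUE(config$fit$triplet))
      for (k in names(fs)) {
        p <- file.path(out_dir, sprintf("fit_%s_%s.json", id, k))
        write_fit(fs[[k]], p)
        paths <- c(paths, p)
      }
      out[[id]] <- fs
    }
    record("fit", "complete", paths)
    out
  })

  rca_table <- run_stage("rca", function() {
    rows <- lapply(names(fits), function(id) {
      m <- fccs_measurement(curves[[id]]$gg, curves[[id]]$rr,
                            curves[[id]]$gr, fits[[id]]$gg,
                            fits[[id]]$rr, fits[[id]]$gr,
                            cell_id = id,
                            condition = traces[[id]]$cell$condition)
      it <- compute_rca(m, normalization = config$rca$normalization)
      data.frame(cell_id = id, condition = it$condition, rca = it$rca,
                 nc_over_ng = it$nc_over_ng,
                 normalization = it$normalization,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    p <- file.path(out_dir, "rca_table.csv")
    con <- file(p, "w")
    writeLines("cell_id,condition,rca,nc_over_ng,normalization", con)
    writeLines(paste(tab$cell_id, tab$condition, fmt_num(tab$rca),
                     fmt_num(tab$nc_over_ng), tab$normalization,
                     sep = ","), con)
    close(con)
    record("rca", "complete", p)
    tab
  })

  comparisons <- run_stage("compare", function() {
    out <- list()
    paths <- character()
    for (cmp in config$compare) {
      cmp <- unlist(cmp)
      a <- rca_table$rca[rca_table$condition == cmp[1]]
      b <- rca_table$rca[rca_table$condition == cmp[2]]
      gc_res <- compare_groups(a, b, labels = cmp)
      p <- file.path(out_dir,
                     sprintf("compare_%s_vs_%s.json", cmp[1], cmp[2]))
      jsonlite::write_json(
        list(groups = cmp, n = gc_res$n, means = gc_res$means,
             sds = gc_res$sds, t = gc_res$t_statistic, df = gc_res$df,
             p_value = gc_res$p_value, stars = gc_res$stars),
        p, auto_unbox = TRUE, digits = NA)
      paths <- c(paths, p)
      out[[paste(cmp, collapse = "_vs_")]] <- gc_res
    }
    if (length(paths)) record("compare", "complete", paths)
    else record("compare", "complete")
    out
  })

  invisible(list(rca_table = rca_table, comparisons = comparisons,
                 manifest = manifest, out_dir = out_dir,
                 summary = summarize_condition(
                   rca_table[, c("condition", "rca")])))
}
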