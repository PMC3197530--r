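#' Output writers
#'
#' Plain-text outputs only: timeseries and measurement CSVs, summary /
#' fit / manifest JSON, and space-separated grid snapshots with a JSON
#' sidecar.  Every output file is regenerable from its manifest (config
#' echo plus seeds).
#'
#' @name io
NULL

#' Write a replicate timeseries to CSV
#'
#' Columns: step, day, tumor_cells, tumor_area_mm2, per-type censuses,
#' effector/infiltration counts, molecule totals and per-step event
#' counts.
#'
#' @param result a `sim_result`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(result, path) {
  utils::write.csv(result$timeseries, path, row.names = FALSE)
  invisible(path)
}

#' Read back a timeseries CSV
#'
#' @param path CSV path written by [write_timeseries()].
#' @return A data frame.
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path)
}

# config echo stripped of derived parameter objects (kept reproducible:
# every scalar key survives)
config_echo <- function(cfg) {
  keep <- !vapply(cfg, is.list, TRUE)
  out <- unclass(cfg)[keep]
  out
}

#' Write a run manifest
#'
#' The manifest records the fully-resolved configuration, the base seed,
#' per-replicate seeds and the output file inventory — sufficient to
#' regenerate any output file exactly.
#'
#' @param x a `sim_result` or `sim_experiment`.
#' @param path output JSON path.
#' @param files optional character vector of produced files to inventory.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(x, path, files = character(0)) {
  if (inherits(x, "sim_result")) {
    seeds <- x$seed; base <- x$seed
  } else {
    seeds <- x$base_seed + seq_along(x$results) - 1L; base <- x$base_seed
  }
  manifest <- list(
    package = "b16ovasim",
    version = as.character(utils::packageVersion("b16ovasim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    base_seed = base,
    replicate_seeds = seeds,
    config = config_echo(x$config),
    files = files)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write an experiment summary to JSON
#'
#' @param experiment a `sim_experiment`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(experiment, path) {
  out <- list(
    arm = experiment$config$arm,
    treatment_day = experiment$config$treatment_day,
    n_reps = length(experiment$results),
    outcomes = as.list(experiment$outcomes),
    near_rejection_days = experiment$near_rejection_days,
    per_day = experiment$summary)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Write a Gompertz fit to JSON
#'
#' @param fit a `gompertz_fit`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(a = fit$a, b = fit$b, K = fit$K, x0 = fit$x0,
                            residual_norm = fit$residual_norm,
                            n_measurements = nrow(fit$series)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a grid snapshot
#'
#' One integer per site, space-separated, one lattice row per line, plus a
#' `<path>.json` sidecar with the timestep, entity filter and lattice
#' metadata.
#'
#' @param snap one element of a `sim_result`'s `snapshots` list.
#' @param what `"tumor"` or `"tc"`.
#' @param path output text path.
#' @return Invisibly, `path`.
#' @export
write_snapshot <- function(snap, what = c("tumor", "tc"), path) {
  what <- match.arg(what)
  m <- snap[[what]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(m, 1, paste, collapse = " "), con)
  jsonlite::write_json(list(day = snap$day, entity = what,
                            L = nrow(m), format = "sites per row, row-major"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a grid snapshot back
#'
#' @param path text path written by [write_snapshot()].
#' @return An integer matrix.
#' @export
read_snapshot <- function(path) {
  rows <- strsplit(readLines(path), " ", fixed = TRUE)
  do.call(rbind, lapply(rows, as.integer))
}

#' Write a measurement series to CSV
#'
#' @param series data frame with columns `day`, `diameter_mm`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(series, path) {
  utils::write.csv(series[, c("day", "diameter_mm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a measurement series CSV
#'
#' @param path CSV with columns `day`, `diameter_mm`.
#' @return A data frame suitable for [fit_gompertz()].
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("day", "diameter_mm") %in% names(df)))
    stop("measurement CSV needs columns day, diameter_mm")
  df
}
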