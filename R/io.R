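# File I/O: pulse traces and series as CSV (single-file and
# directory-of-CSVs dialects), configurations as JSON or YAML.

#' Read or write a single pulse trace as CSV
#'
#' Columns `time_ps, amplitude_mV`.
#'
#' @param trace A [pulse_trace()].
#' @param path File path.
#' @return `read_pulse_trace()` returns a [pulse_trace()];
#'   `write_pulse_trace()` returns `path` invisibly.
#' @export
write_pulse_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pulse_trace"))
  utils::write.csv(data.frame(time_ps = trace$time_ps,
                              amplitude_mV = trace$amplitude_mV),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pulse_trace
#' @export
read_pulse_trace <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_ps", "amplitude_mV") %in% names(d)))
    stop("pulse CSV must have columns time_ps, amplitude_mV: ", path,
         call. = FALSE)
  pulse_trace(d$time_ps, d$amplitude_mV)
}

#' Read or write a pulse series
#'
#' Two plain-text dialects. `"wide"` (a single CSV): first column
#' `time_ps`, remaining columns one pulse each, named `tau_<seconds>s`.
#' `"directory"`: a directory containing `taus.csv` (columns `index`,
#' `tau_s`) and one `pulse_<index>.csv` per trace in the single-trace
#' format; all traces must share one time grid.
#'
#' @param series A [pulse_series()].
#' @param path CSV file (`"wide"`) or directory (`"directory"`).
#' @param dialect `"wide"` or `"directory"`; on read, inferred from whether
#'   `path` is a directory.
#' @return `read_pulse_series()` returns a [pulse_series()];
#'   `write_pulse_series()` returns `path` invisibly.
#' @export
write_pulse_series <- function(series, path,
                               dialect = c("wide", "directory")) {
  stopifnot(inherits(series, "pulse_series"))
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    d <- data.frame(time_ps = series$time_ps, series$amplitudes)
    names(d) <- c("time_ps", sprintf("tau_%gs", series$tau_s))
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(index = seq_along(series$tau_s),
                                tau_s = series$tau_s),
                     file.path(path, "taus.csv"), row.names = FALSE)
    for (i in seq_along(series$tau_s))
      write_pulse_trace(series_trace(series, i),
                        file.path(path, sprintf("pulse_%04d.csv", i)))
  }
  invisible(path)
}

#' @rdname write_pulse_series
#' @export
read_pulse_series <- function(path) {
  if (dir.exists(path)) {
    tf <- file.path(path, "taus.csv")
    if (!file.exists(tf))
      stop("series directory lacks taus.csv: ", path, call. = FALSE)
    taus <- utils::read.csv(tf)
    if (nrow(taus) == 0L)
      stop("empty pulse series: taus.csv has no records", call. = FALSE)
    traces <- lapply(taus$index, function(i) {
      f <- file.path(path, sprintf("pulse_%04d.csv", i))
      if (!file.exists(f))
        stop("missing trace file for index ", i, ": ", f, call. = FALSE)
      read_pulse_trace(f)
    })
    t0 <- traces[[1L]]$time_ps
    for (k in seq_along(traces))
      if (length(traces[[k]]$time_ps) != length(t0) ||
          max(abs(traces[[k]]$time_ps - t0)) > 1e-9)
        stop("time-grid mismatch in trace file for index ", taus$index[k],
             call. = FALSE)
    return(pulse_series(taus$tau_s, traces))
  }
  d <- utils::read.csv(path)
  if (names(d)[1L] != "time_ps" || ncol(d) < 2L)
    stop("wide series CSV must start with time_ps plus one tau_<s>s column ",
         "per pulse: ", path, call. = FALSE)
  taus <- suppressWarnings(
    as.numeric(sub("s$", "", sub("^tau_", "", names(d)[-1L]))))
  if (any(is.na(taus)))
    stop("malformed tau column name in ", path, ": first offending column '",
         names(d)[-1L][which(is.na(taus))[1L]], "'", call. = FALSE)
  pulse_series(taus, as.matrix(d[, -1L, drop = FALSE]), time_ps = d$time_ps)
}

#' Read or write a run configuration (JSON or YAML)
#'
#' A structured-text rendering of [stack_config()], [fit_control()] and
#' [occlusion_scenario()] blocks under keys `stack`, `fit`, `scenario`
#' (each optional; omitted fields take the constructor defaults). Format
#' chosen by file extension: `.json` or `.yaml`/`.yml`.
#'
#' @param path File path.
#' @param config A list with any of `stack`, `fit`, `scenario` elements
#'   (classed objects are flattened to plain lists).
#' @return `read_run_config()` returns a list with validated `stack`
#'   ([stack_config()]), `fit` ([fit_control()]) and `scenario`
#'   ([occlusion_scenario()]) entries.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml: ", path, call. = FALSE)
  build <- function(block, fn, objclass) {
    args <- raw[[block]]
    if (is.null(args)) return(fn())
    if (block == "stack" && !is.null(args$water_model))
      args$water_model <- do.call(debye_model, args$water_model)
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop("unknown field(s) in '", block, "' block: ",
           paste(bad, collapse = ", "), call. = FALSE)
    do.call(fn, args)
  }
  list(stack = build("stack", stack_config),
       fit = build("fit", fit_control),
       scenario = build("scenario", occlusion_scenario))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  flat <- lapply(config, function(b) {
    b <- unclass(b)
    if (!is.null(b$water_model)) b$water_model <- unclass(b$water_model)
    b[!vapply(b, is.null, TRUE)]
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(flat, path)
  }
  invisible(path)
}
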