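# Trace file format and run configuration.
#
# Canonical trace format: a plain-text CSV preceded by a '#'-prefixed header
# block declaring the format version, sampling rate, channel order, units,
# device id, and applied pressure. Units may be "ohm" (resistance channels)
# or "volt" (per-zone voltages plus a common current column `i_m`, converted
# to resistances on load via R_i = V_i / I_m, because all zones carry the
# same series current).

TRACE_FORMAT <- "visconps-trace v1"

#' Write / read a trace file
#'
#' @param trace Trace tibble (`t` plus one column per channel).
#' @param path File path.
#' @param sample_rate Sampling rate, Hz.
#' @param device_id Device identifier.
#' @param applied_pressure Driving pressure, Pa.
#' @param units `"ohm"` or `"volt"`.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the trace tibble (resistance units) with attributes `sample_rate`,
#'   `device_id`, `applied_pressure`.
#' @export
write_trace <- function(trace, path, sample_rate, device_id = "device",
                        applied_pressure = NA, units = "ohm") {
  stopifnot(is.data.frame(trace), "t" %in% names(trace))
  chans <- setdiff(names(trace), "t")
  header <- c(
    paste0("# ", TRACE_FORMAT),
    paste0("# device_id: ", device_id),
    paste0("# sample_rate: ", format(sample_rate, digits = 15)),
    paste0("# applied_pressure: ", format(applied_pressure, digits = 15)),
    paste0("# units: ", units),
    paste0("# channels: ", paste(chans, collapse = ",")))
  writeLines(header, path)
  readr::write_csv(trace, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @param geometry Optional [device_geometry()]; if given, the channel count
#'   is validated against it (pore + zones).
#' @export
read_trace <- function(path, geometry = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Trace file not found: %s", path), class = "nps_config_error")
  }
  lines <- readr::read_lines(path, n_max = 50)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || !grepl(TRACE_FORMAT, hdr[1], fixed = TRUE)) {
    abort("Not a recognized trace file (missing or mismatched format header).",
      class = "nps_parse_error")
  }
  kv <- sub("^#\\s*", "", hdr[-1])
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  meta <- setNames(as.list(vals), keys)
  as_num <- function(v) {
    if (is.null(v) || v %in% c("NA", "NaN", "")) NA_real_ else as.numeric(v)
  }
  sample_rate <- as_num(meta$sample_rate)
  units <- meta$units %||% "ohm"
  chans <- strsplit(meta$channels %||% "", ",")[[1]]

  trace <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
    progress = FALSE)
  got <- setdiff(names(trace), c("t", "i_m"))
  if (length(chans) && !identical(setdiff(chans, "i_m"), got)) {
    abort("Header channel list does not match the trace columns.",
      class = "nps_parse_error")
  }
  dt <- diff(trace$t)
  if (length(dt) && (max(dt) - min(dt)) > 0.01 / sample_rate) {
    abort("Non-uniform sampling detected.", class = "nps_parse_error")
  }
  if (identical(units, "volt")) {
    if (!"i_m" %in% names(trace)) {
      abort("Voltage-mode trace requires a current column `i_m`.",
        class = "nps_parse_error")
    }
    for (ch in got) trace[[ch]] <- trace[[ch]] / trace$i_m
    trace$i_m <- NULL
  }
  if (!is.null(geometry)) {
    nz <- nrow(geometry$zones)
    if (ncol(trace) - 1 != nz + 1) {
      abort(sprintf("Trace has %d channels but geometry expects %d.",
        ncol(trace) - 1, nz + 1), class = "nps_config_error")
    }
  }
  attr(trace, "sample_rate") <- sample_rate
  attr(trace, "device_id") <- meta$device_id
  attr(trace, "applied_pressure") <- as_num(meta$applied_pressure)
  trace
}

#' Read a run configuration file
#'
#' A YAML document with keys `geometry` (path to a geometry file, resolved
#' relative to the configuration file), optional `seed`, and optional
#' `simulate` and `pipeline` blocks whose keys are passed to [sim_config()]
#' and [nps_control()] respectively. Unknown keys are rejected.
#'
#' @param path Configuration file path.
#' @return A list with `geometry` (an `nps_geometry`), `seed`, `simulate`,
#'   `pipeline`, and `output_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "nps_config_error")
  }
  cfg <- yaml::read_yaml(path)
  known <- c("geometry", "seed", "simulate", "pipeline", "output_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort(sprintf("Unknown config keys: %s", paste(extra, collapse = ", ")),
      class = "nps_config_error")
  }
  if (is.null(cfg$geometry)) {
    abort("Config must name a `geometry` file.", class = "nps_config_error")
  }
  gpath <- cfg$geometry
  if (!file.exists(gpath)) gpath <- file.path(dirname(path), cfg$geometry)
  geometry <- read_geometry(gpath)
  ok_sim <- setdiff(names(formals(sim_config)), c("geometry", "moduli"))
  bad <- setdiff(names(cfg$simulate %||% list()), ok_sim)
  if (length(bad)) {
    abort(sprintf("Unknown simulate keys: %s", paste(bad, collapse = ", ")),
      class = "nps_config_error")
  }
  bad <- setdiff(names(cfg$pipeline %||% list()), names(formals(nps_control)))
  if (length(bad)) {
    abort(sprintf("Unknown pipeline keys: %s", paste(bad, collapse = ", ")),
      class = "nps_config_error")
  }
  list(geometry = geometry, seed = cfg$seed, simulate = cfg$simulate %||% list(),
    pipeline = cfg$pipeline %||% list(), output_dir = cfg$output_dir %||% ".")
}
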