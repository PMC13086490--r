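# CSV dialects and JSON reports. The dialects are defined by this package
# (proprietary logger/transmitter export formats are not published): each
# reader checks the documented header and skips malformed rows with a count.

check_header <- function(df, expected, path) {
  if (!identical(names(df), expected)) {
    stop("unexpected header in ", path, ": expected ",
         paste(expected, collapse = ","), " but found ",
         paste(names(df), collapse = ","))
  }
}

#' Read an oxygen-trace CSV
#'
#' Dialect: `time_s,do_percent,phase,speed_mps` (an optional trailing `cycle`
#' column is accepted).
#'
#' @param path CSV path.
#' @return Data frame with the trace columns.
#' @export
read_oxygen_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- c("time_s", "do_percent", "phase", "speed_mps")
  if (!identical(names(df)[seq_len(4)], base)) {
    check_header(df[seq_len(min(4, ncol(df)))], base, path)
  }
  if (!all(df$phase %in% c("acclimation", "measure", "flush"))) {
    stop("phase must be one of acclimation/measure/flush")
  }
  df
}

#' Read a respirometry config YAML
#'
#' Keys: `chamber_volume_l`, `do_max_mg_l`, `body_mass_kg`,
#' `speed_step_mps`, `step_duration_min`.
#'
#' @param path YAML path.
#' @return A [respiro_config()].
#' @export
read_respiro_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("chamber_volume_l", "do_max_mg_l", "body_mass_kg")
  if (!all(need %in% names(y))) {
    stop("config must define ", paste(need, collapse = ", "))
  }
  respiro_config(chamber_volume = y$chamber_volume_l, do_max = y$do_max_mg_l,
                 body_mass = y$body_mass_kg,
                 speed_step = y$speed_step_mps %||% 0.15,
                 step_duration = y$step_duration_min %||% 30)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a heart-rate logger export CSV
#'
#' Dialect: `timestamp,hr_bpm,qi` with ISO-8601 timestamps. Rows with an
#' invalid quality index (outside 0-3), unparseable timestamp, or
#' non-positive HR at QI < 3 are skipped with a warning reporting the count.
#'
#' @param path CSV path.
#' @return Data frame `timestamp, hr_bpm, qi, source`; attribute
#'   `n_skipped` carries the number of rejected rows.
#' @export
read_logger_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "numeric", "integer"))
  check_header(df, c("timestamp", "hr_bpm", "qi"), path)
  if (nrow(df) == 0) {
    out <- data.frame(timestamp = as.POSIXct(character()),
                      hr_bpm = numeric(), qi = integer(),
                      source = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  ok <- !is.na(ts) & df$qi %in% 0:3 &
    (df$qi == 3L | (is.finite(df$hr_bpm) & df$hr_bpm > 0))
  if (any(!ok)) {
    warning(sum(!ok), " malformed row(s) skipped in ", path)
  }
  out <- data.frame(timestamp = ts[ok], hr_bpm = df$hr_bpm[ok],
                    qi = as.integer(df$qi[ok]), source = "logger",
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Read a triaxial acceleration CSV
#'
#' Dialect: `time_s,ax_g,ay_g,az_g`.
#' @param path CSV path.
#' @return Data frame with the four columns.
#' @export
read_triaxial_csv <- function(path) {
  df <- utils::read.csv(path)
  check_header(df, c("time_s", "ax_g", "ay_g", "az_g"), path)
  df
}

#' Read a sentinel telemetry CSV
#'
#' Dialect:
#' `fish_id,timestamp,treatment,hr_bpm,ext_accel_mg,var_mg2,odba_ms2`.
#' @param path CSV path.
#' @return Data frame with parsed timestamps.
#' @export
read_sentinel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, c("fish_id", "timestamp", "treatment", "hr_bpm",
                     "ext_accel_mg", "var_mg2", "odba_ms2"), path)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S"))
  if (!all(df$treatment %in% c("steady", "unsteady"))) {
    stop("treatment must be steady or unsteady")
  }
  df
}

#' Read a flow-speed CSV
#'
#' Dialect: `time_s,speed_mps`.
#' @param path CSV path.
#' @return Data frame with the two columns.
#' @export
read_flow_csv <- function(path) {
  df <- utils::read.csv(path)
  check_header(df, c("time_s", "speed_mps"), path)
  df
}

#' Write an analysis report as JSON with provenance
#'
#' Serialises a report (e.g. an `energetics_report` or any named list of
#' results) to JSON together with a provenance block: package version, seed,
#' and an MD5 hash of the serialised configuration. The file round-trips
#' losslessly through [read_report()].
#'
#' @param report Named list of results.
#' @param path Output path.
#' @param seed Seed used for the run (recorded, not applied).
#' @param config Optional configuration object to hash into provenance.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, seed = NA_integer_, config = NULL) {
  if (is.null(report) || length(report) == 0) stop("report is empty")
  cfg_hash <- if (is.null(config)) NA_character_ else {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
    unname(tools::md5sum(tmp))
  }
  payload <- list(
    provenance = list(package = "swimtag",
                      version = as.character(utils::packageVersion("swimtag")),
                      seed = seed, config_md5 = cfg_hash),
    report = unclass(report)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path JSON path.
#' @return List with `provenance` and `report`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("provenance", "report") %in% names(payload))) {
    stop("not a swimtag report: missing provenance or report block")
  }
  payload
}
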