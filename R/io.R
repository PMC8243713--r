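#' Read a multiplexed logger CSV
#'
#' Reads one logger file into a tibble with one row per timestamped
#' measurement. The canonical header is `timestamp, chamber_id, co2_ref,
#' co2_sample, h2o_ref, h2o_sample, flow_velocity, temp_chamber, pressure,
#' ppfd_set, ppfd_transmitted, mode`. A `timestamp` column holding ISO-8601
#' datetimes is converted to float seconds since the first record; a numeric
#' column is used as-is.
#'
#' Row invariants (non-decreasing timestamps, non-negative concentrations,
#' pressure within 80-110 kPa, chamber id in 1..13) are enforced: violations
#' raise an error naming the row and field, or are dropped with a warning when
#' `on_invalid = "skip"`.
#'
#' @param path Path to the CSV file.
#' @param on_invalid Either `"error"` (default) or `"skip"`.
#' @return A tibble of logger records ordered as in the file.
#' @seealso [write_logger_csv()]
#' @export
read_logger_csv <- function(path, on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) {
    abort(paste0("logger file not found: ", path), class = "canopyflux_io_error")
  }
  hdr <- names(readr::spec_csv(path)$cols)
  missing <- setdiff(logger_columns(), hdr)
  if (length(missing) > 0) {
    abort(paste0("logger file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "canopyflux_schema_error")
  }
  ## read everything as text, then convert with base R's correctly-rounded
  ## strtod so 17-digit doubles round-trip bit-exactly
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  raw <- dplyr::select(raw, dplyr::all_of(logger_columns()))
  ts_iso <- nrow(raw) > 0 && grepl("[T:-]", raw$timestamp[[1]])
  num_cols <- setdiff(logger_columns(), c("mode", "chamber_id",
                                          if (ts_iso) "timestamp"))
  for (col in num_cols) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(paste0("unparseable numeric in ", path, ": row ", bad[[1]],
                   ", field '", col, "'"),
            class = "canopyflux_row_error")
    }
    raw[[col]] <- val
  }
  raw$chamber_id <- suppressWarnings(as.integer(raw$chamber_id))
  if (ts_iso) {
    ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M:%OS"))
    raw$timestamp <- as.numeric(ts) - as.numeric(ts[[1]])
  }
  validate_logger_records(raw, on_invalid = on_invalid)
}

## enforce LoggerRecord invariants with row-numbered diagnostics
validate_logger_records <- function(records, on_invalid = "error") {
  checks <- list(
    chamber_id = records$chamber_id %in% 1:13,
    co2_ref = records$co2_ref >= 0,
    co2_sample = records$co2_sample >= 0,
    h2o_ref = records$h2o_ref >= 0,
    h2o_sample = records$h2o_sample >= 0,
    pressure = records$pressure >= 80000 & records$pressure <= 110000,
    timestamp = c(TRUE, diff(records$timestamp) >= 0)
  )
  bad <- !Reduce(`&`, checks)
  bad[is.na(bad)] <- TRUE
  if (!any(bad)) return(tibble::as_tibble(records))
  row1 <- which(bad)[[1]]
  field1 <- names(checks)[[which(!purrr::map_lgl(checks, ~ isTRUE(.x[[row1]])))[[1]]]]
  if (on_invalid == "error") {
    abort(paste0("invalid logger record at row ", row1,
                 ": field '", field1, "' violates its invariant"),
          class = "canopyflux_row_error")
  }
  warn(paste0("dropping ", sum(bad), " invalid logger record(s); first at row ",
              row1, " (field '", field1, "')"))
  tibble::as_tibble(records[!bad, , drop = FALSE])
}

#' Write logger records to CSV
#'
#' Writes records in the canonical logger layout with full double precision,
#' so that [read_logger_csv()] recovers them exactly.
#'
#' @param records A tibble of logger records (see [read_logger_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(records, path) {
  records <- validate_logger_records(records)
  records <- dplyr::select(records, dplyr::all_of(logger_columns()))
  # 17 significant digits so doubles survive the text round-trip bit-exactly
  out <- dplyr::mutate(records, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Fit a linear sensor calibration
#'
#' Ordinary least squares of reference readings on raw sensor readings, as
#' used to calibrate the miniature air-flow transmitters against a reference
#' mass flow meter.
#'
#' @param raw Numeric vector of raw sensor readings.
#' @param reference Numeric vector of reference instrument readings.
#' @return A list of class `calibration_curve` with `slope` and `intercept`.
#' @examples
#' fit_linear_calibration(c(0, 1, 2), c(1, 3, 5)) # slope 2, intercept 1
#' @export
fit_linear_calibration <- function(raw, reference) {
  if (length(raw) != length(reference)) {
    abort("raw and reference must have equal length",
          class = "canopyflux_domain_error")
  }
  if (length(raw) < 2 || sd(raw) == 0) {
    abort("calibration needs n >= 2 points with nonzero variance in raw",
          class = "canopyflux_degenerate_error")
  }
  fit <- lm(reference ~ raw)
  structure(list(slope = unname(coef(fit)[["raw"]]),
                 intercept = unname(coef(fit)[["(Intercept)"]])),
            class = "calibration_curve")
}

#' Apply a linear calibration curve
#'
#' @param curve A `calibration_curve` from [fit_linear_calibration()].
#' @param raw Numeric vector of raw readings.
#' @return `slope * raw + intercept`.
#' @export
apply_calibration <- function(curve, raw) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$slope * raw + curve$intercept
}

#' Read a facility configuration file
#'
#' Configuration is a JSON file with optional sections `geometry`, `schedule`,
#' and `light`; values present override the package defaults.
#'
#' @param path Path to a JSON configuration file, or `NULL` for all defaults.
#' @return A list with `geometry`, `schedule`, `light` entries.
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else jsonlite::read_json(path, simplifyVector = TRUE)
  geometry <- do.call(chamber_geometry, as.list(cfg$geometry))
  schedule <- do.call(sampling_schedule, as.list(cfg$schedule))
  light <- do.call(light_config, as.list(cfg$light))
  list(geometry = geometry, schedule = schedule, light = light)
}
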