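#' Describe the on-disk dialect of a calorimetry export
#'
#' Metabolic-cage exports differ in delimiter, decimal mark, column naming
#' and timestamp format between facilities and software versions. A dialect
#' object captures those choices plus the lights-on wall-clock time, which
#' anchors Zeitgeber time (ZT 0). There is no sensible default lights-on
#' time: it is a property of the animal room and must be supplied.
#'
#' @param lights_on lights-on clock time as `"HH:MM"` (defines ZT 0).
#' @param delimiter field separator (default tab).
#' @param decimal_mark decimal mark, `"."` or `","`.
#' @param timestamp_format `strptime()` format for the timestamp column.
#' @param columns named character vector mapping the canonical trace fields
#'   (`mouse_id`, `cage_id`, `timestamp`, `d_o2`, `d_co2`, `d_h2`, `food_g`,
#'   `water_g`, `flow_lpm`) to the column names used in the file.
#' @param cadence_min expected spacing of consecutive records per cage, in
#'   minutes.
#'
#' @return an object of class `study_dialect`.
#' @export
#' @examples
#' study_dialect(lights_on = "07:00")
study_dialect <- function(lights_on,
                          delimiter = "\t",
                          decimal_mark = ".",
                          timestamp_format = "%Y-%m-%d %H:%M:%S",
                          columns = NULL,
                          cadence_min = 24) {
  if (missing(lights_on)) {
    stop("'lights_on' (lights-on clock time, \"HH:MM\") must be supplied; ",
         "it defines Zeitgeber time 0", call. = FALSE)
  }
  stopifnot(is.character(lights_on), length(lights_on) == 1L)
  if (!grepl("^\\d{1,2}:\\d{2}$", lights_on)) {
    stop("'lights_on' must be \"HH:MM\"", call. = FALSE)
  }
  canonical <- c("mouse_id", "cage_id", "timestamp", "d_o2", "d_co2",
                 "d_h2", "food_g", "water_g", "flow_lpm")
  if (is.null(columns)) columns <- setNames(canonical, canonical)
  missing_cols <- setdiff(canonical, names(columns))
  if (length(missing_cols)) {
    stop("dialect column map is missing mandatory field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(unname(columns[canonical]))) {
    stop("dialect maps two canonical fields onto the same file column",
         call. = FALSE)
  }
  if (!decimal_mark %in% c(".", ",")) {
    stop("'decimal_mark' must be '.' or ','", call. = FALSE)
  }
  stopifnot(cadence_min > 0)
  structure(
    list(lights_on = lights_on, delimiter = delimiter,
         decimal_mark = decimal_mark, timestamp_format = timestamp_format,
         columns = columns[canonical], cadence_min = cadence_min),
    class = "study_dialect"
  )
}

#' @export
print.study_dialect <- function(x, ...) {
  cat("<study_dialect>\n")
  cat("  lights-on:   ", x$lights_on, " (ZT 0)\n", sep = "")
  cat("  delimiter:   ", deparse(x$delimiter), "\n", sep = "")
  cat("  decimal mark:", x$decimal_mark, "\n")
  cat("  cadence:     ", x$cadence_min, " min\n", sep = "")
  invisible(x)
}

lights_on_hours <- function(lights_on) {
  parts <- as.integer(strsplit(lights_on, ":", fixed = TRUE)[[1]])
  parts[1] + parts[2] / 60
}
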