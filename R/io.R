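#' Convert clock time to Zeitgeber time
#'
#' Zeitgeber time (ZT) is hours elapsed since the most recent lights-on
#' event; ZT 0--12 is the light (resting/fasting) phase and ZT 12--24 the
#' dark (active/feeding) phase. Phases are half-open: ZT 12.0 belongs to
#' the dark phase.
#'
#' @param timestamp a `POSIXct` vector (or anything coercible by
#'   `as.POSIXct()`).
#' @param lights_on lights-on clock time, `"HH:MM"`.
#' @return numeric vector of hours in `[0, 24)`.
#' @export
#' @examples
#' to_zeitgeber(as.POSIXct("2022-03-01 12:00:00", tz = "UTC"), "07:00")  # 5
to_zeitgeber <- function(timestamp, lights_on) {
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  on_h <- lights_on_hours(lights_on)
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  clock_h <- lt$hour + lt$min / 60 + lt$sec / 3600
  (clock_h - on_h) %% 24
}

#' Classify Zeitgeber hours into circadian phases
#'
#' @param zt numeric hours in `[0, 24)`.
#' @return factor with levels `light` (ZT in \[0, 12)) and `dark`
#'   (ZT in \[12, 24)).
#' @export
zt_phase <- function(zt) {
  factor(ifelse(zt %% 24 < 12, "light", "dark"), levels = c("light", "dark"))
}

#' Read calorimetry trace records
#'
#' Parses a delimited metabolic-cage export under a [study_dialect()],
#' renames columns to the canonical trace schema, computes Zeitgeber time
#' and orders records by timestamp within mouse. Rows with unparseable
#' timestamps or missing mandatory values are rejected, not repaired; the
#' rejects and their reasons are attached as the `"rejected"` attribute so
#' ingest remains auditable.
#'
#' @param path file to read.
#' @param dialect a [study_dialect()].
#' @return a tibble of trace records (one row per 24-min cage measurement)
#'   with columns `mouse_id`, `cage_id`, `timestamp`, `zt`, `d_o2`, `d_co2`,
#'   `d_h2`, `food_g`, `water_g`, `flow_lpm`, `qc_flags` (empty string on
#'   ingest), and attribute `rejected` (tibble of row number + reason).
#' @export
read_traces <- function(path, dialect) {
  stopifnot(inherits(dialect, "study_dialect"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(
    path, header = TRUE, sep = dialect$delimiter,
    dec = dialect$decimal_mark, stringsAsFactors = FALSE,
    colClasses = "character", check.names = FALSE,
    comment.char = "", quote = "\""
  )
  cols <- dialect$columns
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols)) {
    stop("input file lacks mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- raw[, unname(cols), drop = FALSE]
  names(df) <- names(cols)

  num_fields <- c("d_o2", "d_co2", "d_h2", "food_g", "water_g", "flow_lpm")
  parse_num <- function(x) {
    if (dialect$decimal_mark == ",") x <- gsub(",", ".", x, fixed = TRUE)
    suppressWarnings(as.numeric(x))
  }
  for (f in num_fields) df[[f]] <- parse_num(df[[f]])
  ts <- as.POSIXct(strptime(df$timestamp, dialect$timestamp_format, tz = "UTC"))

  reason <- rep(NA_character_, nrow(df))
  reason[is.na(ts)] <- "unparseable timestamp"
  for (f in num_fields) {
    bad <- is.na(reason) & is.na(df[[f]])
    reason[bad] <- paste0("missing or non-numeric ", f)
  }
  bad_id <- is.na(reason) & (is.na(df$mouse_id) | df$mouse_id == "")
  reason[bad_id] <- "missing mouse_id"

  rejected <- tibble::tibble(row = which(!is.na(reason)),
                             reason = reason[!is.na(reason)])
  keep <- is.na(reason)
  out <- tibble::tibble(
    mouse_id = df$mouse_id[keep],
    cage_id = df$cage_id[keep],
    timestamp = ts[keep],
    zt = to_zeitgeber(ts[keep], dialect$lights_on),
    d_o2 = df$d_o2[keep],
    d_co2 = df$d_co2[keep],
    d_h2 = df$d_h2[keep],
    food_g = df$food_g[keep],
    water_g = df$water_g[keep],
    flow_lpm = df$flow_lpm[keep],
    qc_flags = ""
  )
  out <- out[order(out$mouse_id, out$timestamp), ]
  if (any(out$flow_lpm <= 0, na.rm = TRUE)) {
    warning("non-positive extraction flow in ", sum(out$flow_lpm <= 0),
            " record(s); gas volumes will be invalid", call. = FALSE)
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write calorimetry trace records
#'
#' Inverse of [read_traces()]: serialises the canonical trace columns under
#' the dialect's delimiter, decimal mark and timestamp format. `zt` and
#' `qc_flags` are derived/ephemeral and are not written.
#'
#' @param records tibble of trace records.
#' @param path output path.
#' @param dialect a [study_dialect()].
#' @return `path`, invisibly.
#' @export
write_traces <- function(records, path, dialect) {
  stopifnot(inherits(dialect, "study_dialect"))
  cols <- dialect$columns
  out <- data.frame(
    mouse_id = records$mouse_id,
    cage_id = records$cage_id,
    timestamp = format(records$timestamp, dialect$timestamp_format, tz = "UTC"),
    stringsAsFactors = FALSE
  )
  fmt_num <- function(x) {
    s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
    if (dialect$decimal_mark == ",") s <- gsub(".", ",", s, fixed = TRUE)
    s
  }
  for (f in c("d_o2", "d_co2", "d_h2", "food_g", "water_g", "flow_lpm")) {
    out[[f]] <- if (nrow(records)) fmt_num(records[[f]]) else character(0)
  }
  names(out) <- unname(cols[names(out)])
  utils::write.table(out, path, sep = dialect$delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
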