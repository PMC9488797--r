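#' Quality-control configuration for cage recordings
#'
#' Thresholds for the datapoint-discard rules. Defaults mirror common
#' practice for 24-min TSE-style recordings: the balance reports 0.01 g
#' spurious food events, intake outliers (leaky bottles, dropped pellets)
#' are cut at Q75 + 1.5 IQR, gas-differential dropouts (cage seal leaks,
#' clogged pre-analyzer filters) at Q25 - 1.5 IQR, and any mouse-day losing
#' more than 20 % of its expected datapoints is discarded wholesale so the
#' circadian grid stays comparable across days.
#'
#' @param food_noise_g sentinel food value treated as balance noise (g).
#' @param food_noise_tol_g half-width for matching the sentinel; floats
#'   stored through text round-trips need a tolerance (half the 0.001 g
#'   balance resolution by default).
#' @param iqr_multiplier multiplier k in the Q75 + k IQR / Q25 - k IQR rules.
#' @param day_removal_fraction a mouse-day is dropped when its removed
#'   fraction strictly exceeds this.
#' @param cadence_min recording cadence (minutes); fixes the expected
#'   datapoints per day (`24 * 60 / cadence_min`).
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(food_noise_g = 0.01,
                      food_noise_tol_g = 0.0005,
                      iqr_multiplier = 1.5,
                      day_removal_fraction = 0.20,
                      cadence_min = 24) {
  stopifnot(food_noise_g > 0, food_noise_tol_g > 0, iqr_multiplier > 0,
            day_removal_fraction > 0, day_removal_fraction < 1,
            cadence_min > 0)
  structure(list(food_noise_g = food_noise_g,
                 food_noise_tol_g = food_noise_tol_g,
                 iqr_multiplier = iqr_multiplier,
                 day_removal_fraction = day_removal_fraction,
                 cadence_min = cadence_min),
            class = "qc_config")
}

qc_rules <- c("food_noise", "negative_value", "intake_high_outlier",
              "gas_low_outlier", "incomplete_day")

new_qc_report <- function(input_n, surviving_n, rule_counts,
                          dropped_days = NULL, skipped_quartile_mice = character(0)) {
  if (is.null(dropped_days)) {
    dropped_days <- tibble::tibble(mouse_id = character(0), day = integer(0),
                                   removed_fraction = numeric(0))
  }
  structure(list(input_n = input_n, surviving_n = surviving_n,
                 rule_counts = rule_counts, dropped_days = dropped_days,
                 skipped_quartile_mice = skipped_quartile_mice,
                 pooling = "quartile thresholds pooled across all days per mouse"),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  input records:    ", x$input_n, "\n")
  cat("  surviving records:", x$surviving_n, "\n")
  cat("  removals by rule (first-triggered attribution):\n")
  for (r in names(x$rule_counts)) {
    cat(sprintf("    %-20s %d\n", r, x$rule_counts[[r]]))
  }
  if (nrow(x$dropped_days)) {
    cat("  dropped mouse-days:", nrow(x$dropped_days), "\n")
  }
  if (length(x$skipped_quartile_mice)) {
    cat("  quartile rules skipped (< 4 records):",
        paste(x$skipped_quartile_mice, collapse = ", "), "\n")
  }
  cat("  note:", x$pooling, "\n")
  invisible(x)
}

# per-mouse lights-on instant immediately preceding (or at) the first record
preceding_lights_on <- function(records) {
  sp <- split(records, records$mouse_id)
  stats::setNames(
    vapply(sp, function(d) {
      i <- which.min(d$timestamp)
      as.numeric(d$timestamp[i]) - d$zt[i] * 3600
    }, numeric(1)),
    names(sp)
  )
}

#' Assign an experiment-day index to each record
#'
#' Day 0 is the 24-h window starting at the lights-on instant that contains
#' each mouse's first record; each subsequent window increments the index.
#'
#' @param records trace records with `mouse_id`, `timestamp`, `zt`.
#' @return integer vector of day indices aligned with `records`.
#' @export
day_index <- function(records) {
  if (!nrow(records)) return(integer(0))
  t0 <- preceding_lights_on(records)
  elapsed_h <- (as.numeric(records$timestamp) - t0[records$mouse_id]) / 3600
  as.integer(floor((elapsed_h + 1e-9) / 24))
}

#' Discard records taken before the first ZT 0
#'
#' Recordings start whenever an animal enters the cage; everything before
#' the first occurrence of lights-on (ZT 0) is discarded so every retained
#' day covers a full light/dark cycle from ZT 0. A mouse whose first record
#' falls exactly at ZT 0 is unchanged.
#'
#' @param records trace records.
#' @param cutoff optional named numeric vector (per mouse, epoch seconds)
#'   of previously determined first-ZT 0 instants to reuse; the instant is
#'   a property of the recording, so re-applying the rule to already
#'   filtered data must not re-derive it from a post-QC first record.
#' @return records at or after each mouse's first ZT 0 instant, with the
#'   per-mouse cutoff instants attached as attribute `zt0_cutoff`.
#' @export
drop_pre_zt0 <- function(records, cutoff = NULL) {
  if (!nrow(records)) return(records)
  if (is.null(cutoff)) {
    t0 <- preceding_lights_on(records)
    sp <- split(records, records$mouse_id)
    first_zt <- vapply(sp, function(d) d$zt[which.min(d$timestamp)], numeric(1))
    # first ZT 0 at/after the first record: same instant if the series
    # starts at ZT 0, otherwise the next lights-on
    cutoff <- t0 + ifelse(first_zt > 1e-9, 24 * 3600, 0)
  }
  known <- records$mouse_id %in% names(cutoff)
  keep <- !known |
    as.numeric(records$timestamp) >= cutoff[records$mouse_id] - 1e-6
  out <- records[keep, ]
  attr(out, "zt0_cutoff") <- cutoff
  out
}

#' Apply the datapoint-discard rules
#'
#' Removes, in order: (1) food values equal to the balance-noise sentinel;
#' (2) negative food, water, dO2 or dCO2 values; (3) per mouse, food or
#' water above Q75 + k IQR; (4) per mouse, dO2 or dCO2 below Q25 - k IQR.
#' Quartile thresholds (type-7 quantiles) are computed once, per mouse
#' pooled over days, on the records surviving steps 1-2; a record failing
#' several rules is attributed to the first in this order so removal counts
#' are conserved. Mice with fewer than 4 records surviving steps 1-2 skip
#' the quartile rules and are flagged in the report.
#'
#' @param records trace records (time-ordered per mouse).
#' @param cfg a [qc_config()].
#' @param thresholds optional per-mouse threshold table (as returned in the
#'   report's `thresholds` element) to reuse instead of recomputing; with
#'   reused thresholds the pass is idempotent — rerunning it on its own
#'   output removes nothing.
#' @return list with `records` (survivors) and `report` (a `qc_report`
#'   whose `thresholds` element holds the per-mouse quartile cutoffs).
#' @export
apply_point_rules <- function(records, cfg = qc_config(), thresholds = NULL) {
  stopifnot(inherits(cfg, "qc_config"))
  n_in <- nrow(records)
  rule <- rep(NA_character_, n_in)

  is_sentinel <- !is.na(records$food_g) &
    abs(records$food_g - cfg$food_noise_g) <= cfg$food_noise_tol_g
  rule[is.na(rule) & is_sentinel] <- "food_noise"

  is_neg <- records$food_g < 0 | records$water_g < 0 |
    records$d_o2 < 0 | records$d_co2 < 0
  rule[is.na(rule) & is_neg] <- "negative_value"

  skipped <- character(0)
  k <- cfg$iqr_multiplier
  hi <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] + k * (q[2] - q[1])
  }
  lo <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    q[1] - k * (q[2] - q[1])
  }
  thr_rows <- list()
  for (m in unique(records$mouse_id)) {
    idx <- which(records$mouse_id == m & is.na(rule))
    if (!is.null(thresholds)) {
      th <- thresholds[thresholds$mouse_id == m, ]
      if (!nrow(th)) {
        skipped <- c(skipped, m)
        next
      }
    } else {
      if (length(idx) < 4L) {
        skipped <- c(skipped, m)
        next
      }
      # thresholds fixed once on the post-step-2 survivors, then applied
      th <- tibble::tibble(mouse_id = m,
                           food_hi = hi(records$food_g[idx]),
                           water_hi = hi(records$water_g[idx]),
                           o2_lo = lo(records$d_o2[idx]),
                           co2_lo = lo(records$d_co2[idx]))
    }
    thr_rows[[m]] <- th
    bad_hi <- idx[records$food_g[idx] > th$food_hi |
                  records$water_g[idx] > th$water_hi]
    rule[bad_hi] <- "intake_high_outlier"
    idx2 <- setdiff(idx, bad_hi)
    bad_lo <- idx2[records$d_o2[idx2] < th$o2_lo |
                   records$d_co2[idx2] < th$co2_lo]
    rule[bad_lo] <- "gas_low_outlier"
  }

  keep <- is.na(rule)
  counts <- vapply(qc_rules[1:4], function(r) sum(rule == r, na.rm = TRUE),
                   integer(1))
  out <- records[keep, ]
  if (nrow(out)) {
    out$qc_flags <- ""
  }
  report <- new_qc_report(n_in, nrow(out),
                          c(as.list(counts), incomplete_day = 0L),
                          skipped_quartile_mice = unique(skipped))
  report$thresholds <- dplyr::bind_rows(thr_rows)
  list(records = out, report = report)
}

#' Drop incomplete mouse-days
#'
#' A mouse-day from which strictly more than `day_removal_fraction` of the
#' expected datapoints (24 h / cadence) are missing is discarded entirely,
#' so the circadian grid underlying daily aggregates is comparable between
#' days and animals. The denominator is the expected daily record count
#' (e.g. 60 at 24-min cadence), not the observed count.
#'
#' @param records trace records after [apply_point_rules()].
#' @param cfg a [qc_config()].
#' @return list with `records` (survivors) and `report` (a `qc_report`
#'   whose `dropped_days` table lists the discarded mouse-days).
#' @export
day_completeness_filter <- function(records, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  n_in <- nrow(records)
  expected <- 24 * 60 / cfg$cadence_min
  if (!n_in) {
    return(list(records = records,
                report = new_qc_report(0L, 0L,
                  c(as.list(stats::setNames(rep(0L, 4), qc_rules[1:4])),
                    incomplete_day = 0L))))
  }
  d <- records
  d$.day <- day_index(d)
  tab <- dplyr::count(tibble::as_tibble(d), .data$mouse_id, .data$.day)
  tab$removed_fraction <- (expected - tab$n) / expected
  drop <- tab[tab$removed_fraction > cfg$day_removal_fraction, ]
  bad <- paste(d$mouse_id, d$.day) %in% paste(drop$mouse_id, drop$.day)
  out <- records[!bad, ]
  counts <- c(as.list(stats::setNames(rep(0L, 4), qc_rules[1:4])),
              incomplete_day = sum(bad))
  dropped <- tibble::tibble(mouse_id = drop$mouse_id,
                            day = as.integer(drop$.day),
                            removed_fraction = drop$removed_fraction)
  list(records = out, report = new_qc_report(n_in, nrow(out), counts, dropped))
}

#' Run the full quality-control pass
#'
#' [drop_pre_zt0()], then [apply_point_rules()], then
#' [day_completeness_filter()], with a combined conservation-checked report.
#'
#' @inheritParams apply_point_rules
#' @param reuse optional `qc_report` from a previous [run_qc()] whose
#'   quartile thresholds and first-ZT 0 cutoffs are reused instead of
#'   re-derived; with reuse the pass is idempotent (a second application
#'   removes nothing).
#' @return list with `records` and `report`.
#' @export
run_qc <- function(records, cfg = qc_config(), reuse = NULL) {
  thresholds <- NULL
  cutoff <- NULL
  if (!is.null(reuse)) {
    stopifnot(inherits(reuse, "qc_report"))
    thresholds <- reuse$thresholds
    cutoff <- reuse$zt0_cutoff
  }
  n_in <- nrow(records)
  r0 <- drop_pre_zt0(records, cutoff = cutoff)
  cutoff <- attr(r0, "zt0_cutoff")
  pre_zt0_removed <- n_in - nrow(r0)
  p <- apply_point_rules(r0, cfg, thresholds = thresholds)
  dcf <- day_completeness_filter(p$records, cfg)
  counts <- p$report$rule_counts
  counts$incomplete_day <- dcf$report$rule_counts$incomplete_day
  counts <- c(list(pre_zt0 = pre_zt0_removed), counts)
  rep <- new_qc_report(n_in, nrow(dcf$records), counts,
                       dropped_days = dcf$report$dropped_days,
                       skipped_quartile_mice = p$report$skipped_quartile_mice)
  rep$thresholds <- p$report$thresholds
  rep$zt0_cutoff <- cutoff
  stopifnot(rep$input_n == rep$surviving_n + sum(unlist(rep$rule_counts)))
  list(records = dcf$records, report = rep)
}
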