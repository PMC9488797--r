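#' Trapezoid area under the curve over a time window
#'
#' Integrates instantaneous values by the trapezoid rule over `window`.
#' When the series straddles a window edge, the value at the edge is
#' obtained by linear interpolation between the neighbouring points, so
#' phase windows that share an edge (light/dark at ZT 12) tile exactly and
#' light + dark AUC equals the full-day AUC. Gaps left by quality control
#' are bridged by a single trapezoid.
#'
#' @param time numeric, strictly increasing sampling times (hours).
#' @param value numeric values at `time`.
#' @param window numeric length-2, `c(t0, t1)`.
#' @return the AUC in value x time units, or `NA` (with attribute
#'   `reason = "insufficient points"`) when fewer than 2 points fall inside
#'   the window.
#' @export
#' @examples
#' auc_trapezoid(0:2, c(0, 1, 0), c(0, 2))  # 1
auc_trapezoid <- function(time, value, window) {
  stopifnot(length(time) == length(value), length(window) == 2L,
            window[1] < window[2])
  ok <- !is.na(time) & !is.na(value)
  time <- time[ok]; value <- value[ok]
  if (is.unsorted(time, strictly = TRUE)) {
    o <- order(time)
    time <- time[o]; value <- value[o]
    if (anyDuplicated(time)) stop("duplicated time points", call. = FALSE)
  }
  inside <- time >= window[1] & time <= window[2]
  if (sum(inside) < 2L) {
    return(structure(NA_real_, reason = "insufficient points"))
  }
  t_in <- time[inside]; v_in <- value[inside]
  # interpolate a value onto an edge the series straddles
  if (min(t_in) > window[1] && any(time < window[1])) {
    e <- stats::approx(time, value, xout = window[1])$y
    t_in <- c(window[1], t_in); v_in <- c(e, v_in)
  }
  if (max(t_in) < window[2] && any(time > window[2])) {
    e <- stats::approx(time, value, xout = window[2])$y
    t_in <- c(t_in, window[2]); v_in <- c(v_in, e)
  }
  sum(diff(t_in) * (utils::head(v_in, -1) + utils::tail(v_in, -1)) / 2)
}

#' Cumulative intake over a time window
#'
#' Interval consumptions (food or water) are already per-interval amounts,
#' so intake over a window is their sum; windows are half-open `[t0, t1)`
#' so windows partitioning a day sum exactly to the daily total.
#'
#' @param time numeric sampling times (hours).
#' @param amount_g per-interval consumption (g).
#' @param window numeric length-2, `c(t0, t1)`.
#' @return grams consumed in the window.
#' @export
cumulative_intake <- function(time, amount_g, window) {
  stopifnot(length(time) == length(amount_g), length(window) == 2L)
  inside <- time >= window[1] & time < window[2]
  sum(amount_g[inside], na.rm = TRUE)
}

#' Per-mouse, per-day, per-phase circadian summaries
#'
#' For every mouse-day present after quality control, computes the
#' energy-expenditure AUC (kcal), mean pointwise RER, hydrogen-production
#' AUC (ppm L) and cumulative food intake (g) for the light phase (ZT
#' 0-12), the dark phase (ZT 12-24) and the full day. Rate AUCs are
#' integrated on the hour axis and converted to per-minute rate units
#' (x 60). Days removed wholesale by QC simply yield no row.
#'
#' @param records trace records carrying the exchange columns from
#'   [add_exchange()].
#' @return tibble with one row per mouse x day x phase: `mouse_id`, `day`,
#'   `phase` (`light`/`dark`/`full_day`), `ee_kcal`, `rer_mean`, `h2_auc`,
#'   `food_g`, `n_points`.
#' @export
summarize_phases <- function(records) {
  stopifnot(all(c("ee_kcal_min", "rer", "h2_rate", "food_g") %in% names(records)))
  if (!nrow(records)) {
    return(tibble::tibble(mouse_id = character(0), day = integer(0),
                          phase = character(0), ee_kcal = numeric(0),
                          rer_mean = numeric(0), h2_auc = numeric(0),
                          food_g = numeric(0), n_points = integer(0)))
  }
  records$.day <- day_index(records)
  records$.t <- records$.day * 24 + records$zt %% 24
  out <- lapply(split(records, records$mouse_id), function(d) {
    d <- d[order(d$.t), ]
    rows <- lapply(sort(unique(d$.day)), function(day) {
      base <- day * 24
      win <- list(light = c(base, base + 12),
                  dark = c(base + 12, base + 24),
                  full_day = c(base, base + 24))
      per_phase <- lapply(names(win), function(ph) {
        w <- win[[ph]]
        inside <- d$.t >= w[1] & d$.t < w[2]
        tibble::tibble(
          mouse_id = d$mouse_id[1], day = as.integer(day), phase = ph,
          ee_kcal = 60 * as.numeric(auc_trapezoid(d$.t, d$ee_kcal_min, w)),
          rer_mean = if (any(inside)) mean(d$rer[inside], na.rm = TRUE) else NA_real_,
          h2_auc = 60 * as.numeric(auc_trapezoid(d$.t, d$h2_rate, w)),
          food_g = cumulative_intake(d$.t, d$food_g, w),
          n_points = sum(inside)
        )
      })
      dplyr::bind_rows(per_phase)
    })
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  res$phase <- factor(res$phase, levels = c("light", "dark", "full_day"))
  res[order(res$mouse_id, res$day, res$phase), ]
}

#' Per-timepoint averages for an individual-level circadian variable
#'
#' Continuous circadian variables (RER, hydrogen production) are first
#' averaged at each Zeitgeber timepoint within each mouse across its
#' recording days; smoothing is then applied to these averages, never to
#' the raw pooled points, so mice with more recording days do not dominate
#' the curve.
#'
#' @param records trace records with the variable of interest.
#' @param var name of the column to average.
#' @param digits ZT values are rounded to this many decimals to identify
#'   the shared sampling grid across days.
#' @return tibble with `mouse_id`, `zt`, `mean`.
#' @export
per_timepoint_means <- function(records, var, digits = 3) {
  stopifnot(var %in% names(records))
  d <- tibble::tibble(mouse_id = records$mouse_id,
                      zt = round(records$zt %% 24, digits),
                      value = records[[var]])
  d <- dplyr::group_by(d, .data$mouse_id, .data$zt)
  d <- dplyr::summarise(d, mean = mean(.data$value, na.rm = TRUE),
                        .groups = "drop")
  d
}

#' Smooth a circadian profile with a penalized cubic regression spline
#'
#' Fits a generalized additive model `y ~ s(zt, bs = basis, k = k)` with
#' the smoothing parameter chosen by generalized cross-validation, and
#' evaluates the fit on a uniform ZT grid. The default basis is the
#' shrinkage cubic regression spline (`"cs"`); a cyclic cubic basis
#' (`"cc"`) is available for strictly periodic profiles.
#'
#' @param zt Zeitgeber hours of the (typically per-timepoint-averaged)
#'   observations; at least 10 distinct values required.
#' @param y observed values.
#' @param k basis dimension (default 10); reduced with a warning when the
#'   data contain fewer distinct timepoints than basis functions.
#' @param basis mgcv smooth basis code, `"cs"` or `"cc"`.
#' @param grid_n number of evaluation points on `[0, 24)`.
#' @return an object of class `smoothed_curve`: list with `grid`, `fitted`,
#'   `k`, `sp` (selected smoothing parameter), `gcv`, and the `gam` fit.
#' @export
smooth_circadian <- function(zt, y, k = 10, basis = "cs", grid_n = 200) {
  ok <- !is.na(zt) & !is.na(y)
  zt <- zt[ok]; y <- y[ok]
  n_unique <- length(unique(zt))
  if (n_unique < 10L) {
    stop("smooth_circadian needs at least 10 distinct ZT values, got ",
         n_unique, call. = FALSE)
  }
  if (n_unique < k) {
    warning("basis dimension reduced from ", k, " to ", n_unique - 1,
            " (only ", n_unique, " distinct timepoints)", call. = FALSE)
    k <- n_unique - 1
  }
  dat <- data.frame(zt = zt, y = y)
  fit <- mgcv::gam(y ~ s(zt, bs = basis, k = k), data = dat,
                   method = "GCV.Cp")
  grid <- seq(0, 24, length.out = grid_n + 1)[seq_len(grid_n)]
  fitted <- as.numeric(predict(fit, newdata = data.frame(zt = grid)))
  structure(list(grid = grid, fitted = fitted, k = k, basis = basis,
                 sp = unname(fit$sp), gcv = fit$gcv.ubre, model = fit),
            class = "smoothed_curve")
}

#' @export
predict.smoothed_curve <- function(object, zt = NULL, ...) {
  if (is.null(zt)) return(object$fitted)
  as.numeric(predict(object$model, newdata = data.frame(zt = zt)))
}

#' @export
print.smoothed_curve <- function(x, ...) {
  cat("<smoothed_curve> penalized cubic spline (bs = ", x$basis,
      ", k = ", x$k, ")\n", sep = "")
  cat("  smoothing parameter (GCV): ", format(x$sp), "\n", sep = "")
  cat("  grid: ", length(x$grid), " points on [0, 24)\n", sep = "")
  invisible(x)
}
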