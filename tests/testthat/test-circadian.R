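test_that("trapezoid AUC is exact for constant, triangular and linear series", {
  # constant c over span T gives c * T
  expect_equal(auc_trapezoid(seq(0, 12, 0.4), rep(2, 31), c(0, 12)), 24)
  # triangle (0,0),(1,1),(2,0) has area 1
  expect_equal(auc_trapezoid(0:2, c(0, 1, 0), c(0, 2)), 1.0)
  # trapezoid rule is exact for a linear ramp
  t <- seq(0, 10, 0.7)
  expect_equal(auc_trapezoid(t, 3 + 2 * t, c(0, max(t))),
               3 * max(t) + max(t)^2)
})

test_that("AUC interpolates window edges and flags insufficient points", {
  # window [0.5, 3.5] of the line y = t: exact integral 6 needs both edges
  # interpolated from the neighbouring points
  expect_equal(auc_trapezoid(0:4, 0:4, c(0.5, 3.5)), 6)
  out <- auc_trapezoid(c(0, 5), c(1, 1), c(1, 2))
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "insufficient points")
})

test_that("cumulative intake sums half-open windows that tile the day", {
  t <- seq(0, 23.6, 0.4)
  food <- rep(0.05, length(t))
  expect_equal(cumulative_intake(t, food, c(5, 5)), 0)       # empty window
  expect_equal(cumulative_intake(c(1, 2, 3), rep(0.2, 3), c(0, 24)), 0.6)
  # windows partitioning the day sum to the daily total
  total <- cumulative_intake(t, food, c(0, 24))
  parts <- cumulative_intake(t, food, c(0, 12)) +
    cumulative_intake(t, food, c(12, 24))
  expect_equal(parts, total)
})

test_that("light + dark AUC equals the full-day AUC (phase additivity)", {
  cohort <- generate_cohort(
    cohort_config(n_per_group = c(GF = 2, OLIGO = 2, SPF = 2), days = 2),
    seed = 3)
  ps <- summarize_phases(add_exchange(cohort$traces))
  wide <- tidyr::pivot_wider(ps[, c("mouse_id", "day", "phase", "ee_kcal")],
                             names_from = "phase", values_from = "ee_kcal")
  expect_equal(wide$light + wide$dark, wide$full_day, tolerance = 1e-10)
})

test_that("phase summaries recover the generator's analytic integrals", {
  cfg <- cohort_config(n_per_group = c(GF = 2, OLIGO = 2, SPF = 2), days = 3,
                       rer_noise_sd = 0, gas_noise = 0, h2_noise_ppm = 0,
                       intake_cv = 0)
  cohort <- generate_cohort(cfg, seed = 21)
  ps <- summarize_phases(add_exchange(cohort$traces))
  full <- merge(ps[ps$phase == "full_day" & ps$day < 2, ], cohort$truth)
  # interior days cover [0, 24] exactly; the circadian cosine integrates to
  # zero over a full period, so the full-day EE AUC is the latent daily EE
  expect_equal(full$ee_kcal, full$daily_ee_kcal, tolerance = 0.01)
  # constant-RER phases are recovered exactly as phase means
  light <- merge(ps[ps$phase == "light", ], cohort$truth)
  expect_equal(light$rer_mean, unname(light$rer_light), tolerance = 1e-9)
  # germ-free hydrogen stays at blank level (zero here, noise disabled)
  gf_h2 <- ps$h2_auc[ps$phase == "full_day" &
                     grepl("^GF", ps$mouse_id) & ps$day < 2]
  expect_equal(gf_h2, rep(0, length(gf_h2)), tolerance = 1e-9)
})

test_that("days dropped by QC produce no summary row", {
  tr <- dplyr::bind_rows(make_traces(120, mouse_id = "A"),
                         make_traces(120, mouse_id = "B")[-(61:100), ])
  q <- day_completeness_filter(tr, qc_config())
  ps <- summarize_phases(add_exchange(q$records))
  expect_setequal(unique(ps$day[ps$mouse_id == "A"]), c(0, 1))
  expect_equal(unique(ps$day[ps$mouse_id == "B"]), 0)
})

test_that("per-timepoint averaging precedes smoothing", {
  # two days with different values at the same ZT average to their mean
  tr <- make_traces(120)
  tr$rer <- rep(c(0.7, 0.9), each = 60)
  m <- per_timepoint_means(tr, "rer")
  expect_equal(nrow(m), 60)
  expect_equal(m$mean, rep(0.8, 60))
})

test_that("the penalized spline recovers a noiseless cubic to 1e-6", {
  zt <- seq(0, 23.6, by = 0.4)
  y <- 1 + 0.1 * zt - 0.02 * zt^2 + 0.001 * zt^3
  # in the penalty -> 0 limit the fit interpolates the data within the
  # spline space, so the basis must be rich enough to contain the signal
  sc <- smooth_circadian(zt, y, k = length(zt) - 1)
  expect_lt(max(abs(predict(sc, zt) - y)), 1e-6)
})

test_that("the spline tracks a noisy sinusoid to max error < 0.05", {
  set.seed(7)
  zt <- seq(0, 23.6, length.out = 60)
  truth <- sin(2 * pi * zt / 24)
  sc <- smooth_circadian(zt, truth + rnorm(60, 0, 0.01))
  expect_lt(max(abs(predict(sc, zt) - truth)), 0.05)
})

test_that("constant data give a constant fit and the response shift carries over", {
  zt <- seq(0, 23, 1)
  sc <- smooth_circadian(zt, rep(2, length(zt)))
  expect_equal(sc$fitted, rep(2, length(sc$fitted)))
  # equivariance: adding a constant shifts the fit by that constant
  set.seed(11)
  y <- sin(2 * pi * zt / 24) + rnorm(length(zt), 0, 0.05)
  f1 <- smooth_circadian(zt, y)
  f2 <- smooth_circadian(zt, y + 5)
  expect_equal(f2$fitted, f1$fitted + 5, tolerance = 1e-6)
})

test_that("too few distinct timepoints is an error, excess basis is reduced", {
  expect_error(smooth_circadian(1:5, 1:5), "at least 10 distinct")
  zt <- seq(0, 22, 2)  # 12 distinct points
  expect_warning(smooth_circadian(zt, sin(zt), k = 20), "reduced")
})
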