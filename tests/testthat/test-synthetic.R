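small_cfg <- function(...) {
  cohort_config(n_per_group = c(GF = 3, OLIGO = 3, SPF = 3), days = 2, ...)
}

test_that("the same seed reproduces the cohort bitwise", {
  a <- generate_cohort(small_cfg(), seed = 17)
  b <- generate_cohort(small_cfg(), seed = 17)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$traces, b$traces)
  expect_identical(a$fecal, b$fecal)
  expect_identical(a$assays, b$assays)
  c <- generate_cohort(small_cfg(), seed = 18)
  expect_false(identical(a$traces$d_o2, c$traces$d_o2))
})

test_that("profiles satisfy the body-composition invariants", {
  p <- generate_cohort(cohort_config(), seed = 2)$profiles
  expect_true(all(p$total_mass_nocecum_g == p$total_mass_g - p$cecal_mass_g))
  fat <- p$fat_ibat_g + p$fat_iwat_g + p$fat_vwat_g
  expect_true(all(fat <= p$total_mass_g))
  expect_true(all(p[sapply(p, is.numeric)] >= 0))
  # cecal-mass ordering mirrors the colonization gradient
  m <- tapply(p$cecal_mass_g, p$group, mean)
  expect_true(m[["GF"]] > m[["OLIGO"]] && m[["OLIGO"]] > m[["SPF"]])
})

test_that("the fault rate realises the configured binomial expectation", {
  rates <- c(food_sentinel = 0.02, negative_gas = 0.01,
             intake_outlier = 0.01, gas_dropout = 0.01)
  n_tot <- 0; n_fault <- 0
  for (s in 1:5) {
    ch <- generate_cohort(small_cfg(fault_rates = rates), seed = s)
    n_tot <- n_tot + nrow(ch$traces)
    n_fault <- n_fault + nrow(ch$fault_log)
  }
  rate <- n_fault / n_tot
  # 5 % nominal; binomial SE over ~5,400 records is ~0.3 %
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
  # at most one fault per record
  expect_false(anyDuplicated(ch$fault_log$row) > 0)
})

test_that("a fault-free cohort loses only the outlier-rule false positives", {
  ch <- generate_cohort(cohort_config(), seed = 11)
  q <- run_qc(ch$traces)
  counts <- q$report$rule_counts
  # no sentinel, negative or gas-dropout removals occur without faults
  expect_equal(counts$food_noise, 0)
  expect_equal(counts$negative_value, 0)
  expect_equal(counts$gas_low_outlier, 0)
  # heavy-tailed feeding bouts put a small mass above Q75 + 1.5 IQR; the
  # overall loss stays well under the 20 % day threshold
  expect_lt(1 - q$report$surviving_n / q$report$input_n, 0.08)
  expect_equal(nrow(q$report$dropped_days), 0)
})

test_that("the pipeline recovers latent daily EE within 0.5 % without noise", {
  cfg <- small_cfg(rer_noise_sd = 0, gas_noise = 0, h2_noise_ppm = 0,
                   intake_cv = 0)
  ch <- generate_cohort(cfg, seed = 23)
  ps <- summarize_phases(add_exchange(ch$traces))
  full <- merge(ps[ps$phase == "full_day" & ps$day == 0, ], ch$truth)
  expect_equal(full$ee_kcal, full$daily_ee_kcal, tolerance = 0.005)
})

test_that("germ-free hydrogen traces stay inside the blank noise band", {
  ch <- generate_cohort(small_cfg(), seed = 31)
  gf <- ch$traces[grepl("^GF", ch$traces$mouse_id), ]
  noise <- ch$config$h2_noise_ppm
  expect_lt(max(abs(gf$d_h2)), 5 * noise)
  expect_equal(mean(gf$d_h2), 0, tolerance = 3 * noise / sqrt(nrow(gf)) + 0.05)
})

test_that("generated energy books close near 9 kcal extracted per day", {
  ch <- generate_cohort(cohort_config(), seed = 41)
  daily <- merge(ch$intake, ch$fecal)
  for (g in c("GF", "OLIGO", "SPF")) {
    rows <- daily[grepl(paste0("^", g, "_"), daily$mouse_id), ]
    input <- daily_energy_input(group_uval(rows$intake_g))
    excretion <- daily_energy_excretion(group_uval(rows$fecal_dry_g),
                                        group_uval(rows$energy_kcal_per_g))
    b <- balance(input, excretion)
    # configured absorbed energy ~ 9 kcal/day, within the 95 % interval
    expect_lt(abs(b$extraction$mean - 9), 1.96 * b$extraction$u + 1)
  }
  # germ-free mice eat 10-20 % more than colonized
  tot <- tapply(daily$intake_g, sub("_\\d+$", "", daily$mouse_id), mean)
  ratio <- tot[["GF"]] / mean(c(tot[["OLIGO"]], tot[["SPF"]]))
  expect_gt(ratio, 1.05)
  expect_lt(ratio, 1.25)
})

test_that("traces follow the configured cadence and the written dialect", {
  ch <- generate_cohort(small_cfg(), seed = 51)
  one <- ch$traces[ch$traces$mouse_id == ch$traces$mouse_id[1], ]
  gaps <- diff(as.numeric(one$timestamp)) / 60
  expect_equal(gaps, rep(24, length(gaps)))
  # round-trip through the trace dialect preserves the records
  path <- withr::local_tempfile(fileext = ".tsv")
  write_traces(ch$traces, path, ch$dialect)
  back <- read_traces(path, ch$dialect)
  expect_equal(nrow(back), nrow(ch$traces))
  expect_equal(back$d_o2, ch$traces$d_o2[order(ch$traces$mouse_id,
                                               ch$traces$timestamp)])
})
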