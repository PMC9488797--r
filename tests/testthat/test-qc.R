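test_that("records before the first ZT 0 are discarded, later ones kept", {
  # series starting at lights-on is untouched
  tr0 <- make_traces(10, start_zt = 0)
  expect_identical(drop_pre_zt0(tr0)$timestamp, tr0$timestamp)
  # series starting at ZT 20: the ZT 20-24 leading records go, the rest stay
  tr <- make_traces(20, start_zt = 20)
  out <- drop_pre_zt0(tr)
  expect_equal(nrow(out), 10)
  expect_equal(min(out$zt), 0)
  expect_true(all(tr$zt[seq_len(10)] >= 20))  # exactly the leading block went
  # empty input passes through
  expect_equal(nrow(drop_pre_zt0(make_traces(0))), 0)
})

test_that("point rules remove exactly the constructed violations, in order", {
  # 20 rows: 17 clean, one food sentinel, one negative water, one huge food
  tr <- make_traces(20,
                    food_g = rep(c(0.18, 0.20, 0.22, 0.19), 5),
                    water_g = rep(0.3, 20))
  tr$food_g[3] <- 0.01    # balance-noise sentinel
  tr$water_g[7] <- -0.1   # leaky measurement
  tr$food_g[12] <- 2.0    # 10x the median: dropped pellet

  # independent brute-force application of the rules on this fixture
  keep <- rep(TRUE, 20)
  keep[3] <- FALSE                       # rule 1
  keep[7] <- FALSE                       # rule 2
  surv12 <- which(keep)                  # survivors of steps 1-2
  q <- quantile(tr$food_g[surv12], c(0.25, 0.75), type = 7)
  cut_hi <- q[2] + 1.5 * (q[2] - q[1])
  expect_true(tr$food_g[12] > cut_hi)    # fixture really violates rule 3
  keep[12] <- FALSE

  res <- apply_point_rules(tr, qc_config())
  expect_equal(nrow(res$records), 17)
  expect_equal(res$records$timestamp, tr$timestamp[keep])
  counts <- res$report$rule_counts
  expect_equal(counts$food_noise, 1)
  expect_equal(counts$negative_value, 1)
  expect_equal(counts$intake_high_outlier, 1)
  expect_equal(counts$gas_low_outlier, 0)
  # conservation: input = surviving + attributed removals
  expect_equal(res$report$input_n,
               res$report$surviving_n + sum(unlist(counts)))
})

test_that("a clean fixture passes untouched and zero IQR removes nothing", {
  tr <- make_traces(20)  # all values identical within each column
  res <- apply_point_rules(tr, qc_config())
  expect_equal(nrow(res$records), 20)
  expect_true(all(unlist(res$report$rule_counts) == 0))
})

test_that("mice with fewer than 4 records skip quartile rules, flagged", {
  tr <- make_traces(3)
  tr$food_g[1] <- 5  # would be an outlier if quartiles were computed
  res <- apply_point_rules(tr, qc_config())
  expect_equal(nrow(res$records), 3)
  expect_equal(res$report$skipped_quartile_mice, "m1")
})

test_that("the 20 % day rule keeps a 12/60 day and drops a 13/60 day", {
  cfg <- qc_config()
  # mouse A: 48 of 60 expected records (12 removed, exactly 20 %)
  a <- make_traces(60, mouse_id = "A")[-(1:12), ]
  # mouse B: 47 of 60 (13 removed, strictly over 20 %)
  b <- make_traces(60, mouse_id = "B")[-(1:13), ]
  res <- day_completeness_filter(dplyr::bind_rows(a, b), cfg)
  expect_true(all(res$records$mouse_id == "A"))
  expect_equal(nrow(res$records), 48)
  expect_equal(res$report$dropped_days$mouse_id, "B")
  expect_equal(res$report$dropped_days$removed_fraction, 13 / 60)
  # a day with zero removals is retained
  full <- make_traces(60, mouse_id = "C")
  expect_equal(nrow(day_completeness_filter(full, cfg)$records), 60)
})

test_that("full QC is conservative, idempotent under reuse, and monotone in k", {
  cfg <- cohort_config(
    n_per_group = c(GF = 4, OLIGO = 4, SPF = 4), days = 3,
    fault_rates = c(food_sentinel = 0.02, negative_gas = 0.02,
                    intake_outlier = 0.01, gas_dropout = 0.01))
  cohort <- generate_cohort(cfg, seed = 12)
  q1 <- run_qc(cohort$traces)
  expect_equal(q1$report$input_n,
               q1$report$surviving_n + sum(unlist(q1$report$rule_counts)))
  # second application with the first pass's thresholds removes nothing
  q2 <- run_qc(q1$records, reuse = q1$report)
  expect_equal(q2$report$surviving_n, q2$report$input_n)
  # a laxer outlier multiplier never removes more records
  q_lax <- run_qc(cohort$traces, qc_config(iqr_multiplier = 3))
  expect_gte(q_lax$report$surviving_n, q1$report$surviving_n)
})

test_that("every injected fault is caught by QC (recall 1)", {
  cfg <- cohort_config(
    n_per_group = c(GF = 4, OLIGO = 4, SPF = 4), days = 3,
    fault_rates = c(food_sentinel = 0.02, negative_gas = 0.02,
                    intake_outlier = 0.01, gas_dropout = 0.01))
  cohort <- generate_cohort(cfg, seed = 5)
  expect_gt(nrow(cohort$fault_log), 0)
  q <- run_qc(cohort$traces)
  faulted <- paste(cohort$traces$mouse_id,
                   cohort$traces$timestamp)[cohort$fault_log$row]
  surviving <- paste(q$records$mouse_id, q$records$timestamp)
  expect_equal(mean(faulted %in% surviving), 0)
})
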