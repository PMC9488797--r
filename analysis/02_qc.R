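#!/usr/bin/env Rscript
# Datapoint quality control: drop records before the first ZT 0, apply the
# discard rules (0.01 g food sentinel; negative food/water/dO2/dCO2;
# intake above Q75 + 1.5 IQR; gas differentials below Q25 - 1.5 IQR), then
# drop any mouse-day missing more than 20 % of its expected records.

suppressPackageStartupMessages(library(gnotocal))

out_dir <- "results"
dialect <- study_dialect(lights_on = "07:00")
traces <- read_traces("results/study/traces.tsv", dialect)

qc <- run_qc(traces, qc_config())
print(qc$report)

utils::write.csv(qc$records, file.path(out_dir, "traces_clean.csv"),
                 row.names = FALSE)
counts <- tibble::tibble(rule = names(qc$report$rule_counts),
                         removed = unlist(qc$report$rule_counts))
utils::write.csv(counts, file.path(out_dir, "qc_rule_counts.csv"),
                 row.names = FALSE)
if (nrow(qc$report$dropped_days)) {
  utils::write.csv(qc$report$dropped_days,
                   file.path(out_dir, "qc_dropped_days.csv"),
                   row.names = FALSE)
}

message("QC kept ", qc$report$surviving_n, " of ", qc$report$input_n,
        " records (", nrow(qc$report$dropped_days),
        " mouse-days dropped wholesale).")
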