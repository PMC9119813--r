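#!/usr/bin/env Rscript
# Fit the mixed-indicator latent-class model on age, sex, HbA1c and BMI at
# diagnosis; compare K = 2..5 by BIC with the 70% mean-posterior and 1%
# class-share rules; assign and label subgroups (MARD / MOD / SHD), overall
# and within each of the three modelled ethnic groups.

library(t2dsubgroups)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

baseline <- read.csv("results/baseline_table.csv")
fits <- stratified_lca(baseline, K_range = 2:5, seed = seed, restarts = 10)

diags <- do.call(rbind, lapply(names(fits), function(st) {
  cbind(stratum = st, fits[[st]]$selection$diagnostics)
}))
write.csv(diags, "results/lca_diagnostics.csv", row.names = FALSE)
# strata may select different K, so pad posterior columns before binding
asg_list <- lapply(fits, function(f) f$assignments)
all_cols <- unique(unlist(lapply(asg_list, names)))
asg <- do.call(rbind, lapply(asg_list, function(a) {
  a[setdiff(all_cols, names(a))] <- NA
  a[all_cols]
}))
write.csv(asg, "results/assignments.csv", row.names = FALSE)

overall <- fits$overall$assignments
radar <- radar_summary(baseline[match(overall$id, baseline$id), ], overall$label)
write.csv(radar, "results/radar.csv", row.names = FALSE)

for (st in names(fits)) {
  sel <- fits[[st]]$selection
  cat(sprintf("stratum %-12s selected K = %d (rules %s)\n", st, sel$selected_K,
              if (sel$selection_passed) "passed" else "FAILED"))
}
s <- cohort_summary(overall, baseline)
print(s$subgroups)
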