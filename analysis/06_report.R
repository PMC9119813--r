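#!/usr/bin/env Rscript
# Headline summary: subgroup shares (1 d.p.) and ethnic-group shares
# (integer percent) with the published rounding conventions, plus crude
# incident proportions from the survival analysis sets.

library(t2dsubgroups)

baseline <- read.csv("results/baseline_table.csv")
asg <- read.csv("results/assignments.csv")
asg <- asg[asg$stratum == "overall", ]
vasc <- read.csv("results/vascular_hr.csv")

s <- cohort_summary(asg, baseline)
write.csv(s$subgroups, "results/headline_subgroups.csv", row.names = FALSE)
write.csv(s$ethnicities, "results/headline_ethnicities.csv", row.names = FALSE)

cat("subgroup shares:\n"); print(s$subgroups, row.names = FALSE)
cat("\nethnic-group shares:\n"); print(s$ethnicities, row.names = FALSE)
ov <- vasc[vasc$stratum == "overall" & vasc$subgroup == "all", ]
crude <- aggregate(cbind(n_events, n) ~ outcome,
                   vasc[vasc$stratum == "overall", ], sum)
crude$crude_pct <- percent_of(crude$n_events, crude$n, 1)
cat("\ncrude incident proportions:\n"); print(crude, row.names = FALSE)
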