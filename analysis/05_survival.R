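#!/usr/bin/env Rscript
# Time-to-event analyses by subgroup: age- and sex-adjusted Cox
# proportional-hazards models (Breslow ties) for treatment initiation
# (non-insulin and insulin, with the 30-day baseline-initiator rule) and for
# incident macro/microvascular disease among those free of the composite at
# baseline; overall and per ethnic group.

library(t2dsubgroups)

cohort <- read_cohort("results/cohort")
baseline <- read.csv("results/baseline_table.csv")
baseline$diagnosis_date <- as.Date(baseline$diagnosis_date)
baseline$end_date <- as.Date(baseline$end_date)
asg <- read.csv("results/assignments.csv")
asg <- asg[asg$stratum == "overall", ]

init <- initiation_summary(baseline, cohort$prescriptions, asg)
write.csv(init, "results/initiation_summary.csv", row.names = FALSE)
vasc <- vascular_report(baseline, cohort$clinical_events, asg)
write.csv(vasc, "results/vascular_hr.csv", row.names = FALSE)

ni <- init[init$drug_class == "noninsulin_antidiabetic" &
             init$stratum == "overall", ]
cat("non-insulin initiation, overall:\n")
print(ni[c("subgroup", "n_eligible", "n_initiating", "pct_initiating", "hr")],
      row.names = FALSE)
cat("\nvascular hazard ratios vs MARD, overall:\n")
print(vasc[vasc$stratum == "overall",
           c("outcome", "subgroup", "n_events", "crude_pct", "hr", "ci_lo", "ci_hi")],
      row.names = FALSE)
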