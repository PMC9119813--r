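#!/usr/bin/env Rscript
# Yearly-mean HbA1c over the five years after diagnosis, per subgroup and
# ethnic group (the trajectory-figure tables, on both unit scales).

library(t2dsubgroups)

cohort <- read_cohort("results/cohort")
asg <- read.csv("results/assignments.csv")
asg <- asg[asg$stratum == "overall", ]

traj <- trajectory_table(cohort, asg)
write.csv(traj, "results/trajectories.csv", row.names = FALSE)

y1 <- traj[traj$ethnicity == "overall" & traj$year == 1, ]
cat("year-1 mean HbA1c (%) by subgroup:\n")
print(y1[c("label", "mean_hba1c_pct", "n_patients")], row.names = FALSE)
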