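#!/usr/bin/env Rscript
# Stage 2: covariate recodes, the filter cascade, the MDD outcome, and
# Table-1-style weighted descriptives.

library(mddineq)

out_dir <- "results/analysis"
tab <- read_survey_csv(file.path(out_dir, "survey.csv"))

tab <- recode_covariates(tab)
cascade <- apply_filter_cascade(tab)
print(cascade$report)

cohort <- cascade$table
outcome <- compute_mdd(cohort)
cohort$mdd <- outcome$mdd
cohort$n_food_groups <- outcome$n_groups
write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
write.csv(as.data.frame(cascade$report), file.path(out_dir, "cascade_report.csv"),
          row.names = FALSE)

desc <- weighted_descriptives(cohort, cohort$mdd)
write.csv(desc, file.path(out_dir, "descriptives.csv"), row.names = FALSE)

cat(sprintf("\ncohort: %d children (weighted n = %.0f)\n",
            nrow(cohort), sum(cohort$weight)))
cat(sprintf("weighted MDD prevalence: %.2f%%\n",
            desc$mdd_pct[desc$variable == "overall"]))
cat("prevalence by wealth quintile:\n")
print(desc[desc$variable == "wealth_quintile", c("category", "pct", "mdd_pct")],
      row.names = FALSE, digits = 4)
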