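#!/usr/bin/env Rscript
# Step 5 — the cohort statistics layer on a simulated cohort (77 NC / 79 VCI,
# group ALPS means 1.95 / 1.80): group comparison table, recomputation of
# the published summary statistics, correlations, logistic regression of
# VCI status on the percentage-scaled ALPS index, and a standardized
# multiple regression of MoCA with VIF diagnostics.

library(glymphnet)
out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# The published comparison statistics, recomputed from printed summaries.
pub <- recompute_published_stats()
write.csv(pub, file.path(out, "published_statistics_recomputed.csv"), row.names = FALSE)
cat("published-summary statistics (recomputed):\n")
print(pub, digits = 4)

co <- simulate_cohort(cohort_params(seed = 1))
write.csv(co, file.path(out, "cohort.csv"), row.names = FALSE)

tab <- group_compare_table(co)
write.csv(tab, file.path(out, "group_comparison.csv"), row.names = FALSE)
cat("\nsimulated-cohort comparison (NC vs VCI):\n")
print(tab, digits = 3)

cors <- do.call(rbind, lapply(c("Eg", "MoCA", "FSRP", "age"), function(v) {
  r <- correlate(co$mean_alps, co[[v]])
  data.frame(variable = v, r = r$r, p = r$p)
}))
cat("\ncorrelations with the ALPS index:\n")
print(cors, digits = 3)
write.csv(cors, file.path(out, "alps_correlations.csv"), row.names = FALSE)

lg <- logistic_fit(co[c("mean_alps", "age", "sex", "education")],
                   as.integer(co$group == "VCI"), percent = "mean_alps")
cat("\nlogistic regression, VCI ~ ALPS(%) + age + sex + education:\n")
print(lg, digits = 3)
write.csv(lg, file.path(out, "logistic_vci.csv"), row.names = FALSE)

lf <- linear_fit_standardized(co[c("mean_alps", "FSRP", "age", "lacune")], co$MoCA)
cat("\nstandardized regression of MoCA (with VIF):\n")
print(lf, digits = 3)
write.csv(lf, file.path(out, "linear_moca.csv"), row.names = FALSE)
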