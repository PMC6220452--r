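#!/usr/bin/env Rscript
# Step 2: methylome profiling and differential cytosines.
#
# Per-condition context summaries (mean ML, mC/C), treatment-vs-LS
# increment rates, and Fisher-exact DmC calls (p < 0.05, |delta ML| >=
# 0.2) for every treatment against the LS control.

library(epiregseek)

dir.create("results", showWarnings = FALSE)
sim <- simulate_study(sim_config(seed = 1))

summaries <- lapply(sim$methylomes, context_summary)
cs <- do.call(rbind, Map(function(s, cond) cbind(condition = cond, s),
                         summaries, names(summaries)))
write.table(cs, "results/02_context_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# increment rates of ML and mC/C relative to the LS control, as the
# treatments are summarised in the study design
inc <- do.call(rbind, lapply(c("LL", "HS", "HL"), function(cond) {
  a <- summaries$LS; b <- summaries[[cond]]
  data.frame(condition = cond, context = a$context,
             ml_increment = increment_rate(b$mean_ml, a$mean_ml),
             mc_over_c_increment = increment_rate(b$mc_over_c, a$mc_over_c))
}))
write.table(inc, "results/02_increment_rates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("ML increment rates vs LS:\n")
print(inc, row.names = FALSE, digits = 3)

# DmCs per condition change
dmc_counts <- list()
for (cond in c("LL", "HS", "HL")) {
  d <- call_dmcs(sim$methylomes$LS, sim$methylomes[[cond]])
  write.table(d, sprintf("results/02_dmcs_LS-%s.tsv", cond), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dmc_counts[[cond]] <- cbind(condition = cond,
                              as.data.frame(table(context = d$context,
                                                  direction = d$direction)))
}
dmc_counts <- do.call(rbind, dmc_counts)
write.table(dmc_counts, "results/02_dmc_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nDmC counts by context and direction:\n")
print(dmc_counts, row.names = FALSE)
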