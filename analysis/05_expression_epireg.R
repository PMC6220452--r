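#!/usr/bin/env Rscript
# Step 5: differential expression and the epiregulation screen.
#
# DEGs per condition change (divergence probability >= 0.8, fold-change
# >= 2), their overlaps, the per-gene temperature x photoperiod ANOVA,
# DETs (gene-overlapping TEs discarded, BH-adjusted p < 0.05), and the
# join of CG/CHG DMRs in CDS / 2 kb of TSS-TES to DEGs with the
# positive associations discarded.

library(epiregseek)

dir.create("results", showWarnings = FALSE)
sim <- simulate_study(sim_config(seed = 1))
ex <- sim$expression

deg_sets <- list()
for (cond in c("LL", "HS", "HL")) {
  degs <- call_degs(ex, "LS", cond)
  write.table(degs, sprintf("results/05_degs_LS-%s.tsv", cond), sep = "\t",
              quote = FALSE, row.names = FALSE)
  deg_sets[[paste0("LS-", cond)]] <- degs
}
cat("DEGs per condition change:",
    paste(names(deg_sets), vapply(deg_sets, nrow, 1L), collapse = ", "), "\n")
venn <- deg_overlap(deg_sets)
write.table(venn, "results/05_deg_venn.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ga <- gene_anova(ex$fpkm, ex$samples)
write.table(ga$per_gene, "results/05_gene_anova.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nGenes significant (p < 0.05) per two-factor ANOVA term:\n")
print(ga$n_significant)

dets <- call_dets(ex$te_counts, ex$samples, "LS", "HL", sim$annotation,
                  ex$library_sizes)
write.table(dets, "results/05_dets_LS-HL.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
td <- sim$truth$planted_dets[sim$truth$planted_dets$condition == "HL", ]
cat("\nDETs (LS-HL):", nrow(dets), "| planted recovered:",
    sum(td$te_id %in% dets$te_id), "of", nrow(td), "\n")

dmrs <- call_dmrs(sim$methylomes$LS, sim$methylomes$HL,
                  contexts = c("CG", "CHG"))
scr <- epireg_screen(dmrs, deg_sets[["LS-HL"]], sim$annotation)
write.table(scr$events, "results/05_epireg_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(scr$putative_genes, "results/05_putative_epiregulated_genes.txt")
cat("\nEpiregulation screen (LS-HL):\n")
print(scr$summary)
epi <- evaluate_epireg_recovery(scr, sim$truth$planted_epiregs)
cat("planted negative couplings recovered:", round(100 * epi$recall, 1),
    "% | planted concordant couplings emitted:", epi$n_concordant_emitted,
    "\n")
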