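#!/usr/bin/env Rscript
# Stage 5 -- association statistics between conservation and the property
# tables: rank correlations with BH adjustment, quartile (Fisher)
# enrichment of pathway membership, ROC enrichment, and the planted-truth
# validation studies at reduced size.

suppressMessages(library(strucons))

props <- read.delim("results/corpus/properties.tsv")
summary_tab <- read.delim("results/og_summary.tsv")
m <- merge(summary_tab, props, by = "og_id")

assoc <- rbind(
  cbind(variable = "abundance_log2",
        correlate(m$abundance_log2, m$og_cr, "spearman")),
  cbind(variable = "flux_cv", correlate(m$flux_cv, m$og_cr, "spearman")),
  cbind(variable = "kcat_log_sd",
        correlate(m$kcat_log_sd, m$og_cr, "spearman")),
  cbind(variable = "flux_n_species",
        correlate(m$flux_n_species, m$og_cr, "kendall")),
  cbind(variable = "n_inhibitors",
        correlate(m$n_inhibitors, m$og_cr, "kendall")))
assoc$p_adjusted <- bh_adjust(assoc$p_value)
write.table(assoc, "results/associations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("associations with orthogroup CR (estimate / adjusted p):\n")
for (r in seq_len(nrow(assoc))) {
  cat(sprintf("  %-16s %6.2f  %.3f\n", assoc$variable[r], assoc$estimate[r],
              assoc$p_adjusted[r]))
}

## quartile pathway enrichment and ROC enrichment on the corpus
values <- setNames(m$og_cr, m$og_id)
membership <- split(m$og_id, m$pathway)
enr <- quartile_enrichment(values, membership, tail = "top25")
if (!is.null(enr)) {
  write.table(enr, "results/pathway_enrichment.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("pathway enrichment: %d sets tested, min adjusted p = %.3f\n",
              nrow(enr), min(enr$p_adjusted)))
}
lab <- as.integer(m$pathway == names(which.max(table(m$pathway))))
if (length(unique(lab)) == 2) {
  roc <- roc_enrichment(values, lab)
  cat(sprintf("ROC enrichment of the largest pathway: AUC = %.2f\n", roc$auc))
}

## reduced-size planted-truth validation (full sizes run in the test suite
## and scripts/acceptance.R)
h <- study_planted_hierarchy(n_seeds = 20, seed = 1)
cat(sprintf("planted hierarchy recovered in %.0f%% of 20 seeds ",
            100 * h$hierarchy_rate))
cat(sprintf("(class CR: binding %.3f, core %.3f, surface %.3f)\n",
            h$cr_pooled[["bind"]], h$cr_pooled[["core"]],
            h$cr_pooled[["surface"]]))
cp <- study_couplings(n_runs = 10, seed = 1)
cat(sprintf("coupling signs recovered: abundance %.0f%%, flux cv %.0f%%\n",
            100 * cp$sign_rate_abundance, 100 * cp$sign_rate_flux_cv))
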