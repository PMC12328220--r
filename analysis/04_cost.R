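#!/usr/bin/env Rscript
# Stage 4 -- amino-acid cost and composition by structural element.
#
# Joins per-element mean cost (median-normalised Akashi-Gojobori and
# molecular-weight metrics) and amino-acid composition with the
# element-restricted conservation ratios.

suppressMessages(library(strucons))

corpus_dir <- "results/corpus"
stage2 <- readRDS("scratch/stage2.rds")
manifest <- read.delim(file.path(corpus_dir, "manifest.tsv"))
features <- read.delim("results/features.tsv")

rows <- list()
for (og_id in names(stage2$profiles)) {
  prof <- stage2$profiles[[og_id]]
  ids <- manifest$structure_id[manifest$og_id == og_id]
  structures <- setNames(lapply(ids, function(id)
    read_structure(file.path(corpus_dir, "structures", paste0(id, ".pdb")),
                   plddt_from_bfactor = TRUE, structure_id = id)), ids)
  og <- new_orthogroup(og_id, prof$reference_id, structures)
  f <- features[features$og_id == og_id, ]
  rows[[og_id]] <- element_cost_report(og, stage2$mappings[[og_id]], f,
                                       profile = prof)
}
report <- do.call(rbind, rows)
write.table(report, "results/element_cost.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

wide <- report[report$element %in% c("core", "surface"), ]
core <- wide[wide$element == "core", ]
surf <- wide[wide$element == "surface", ]
cat(sprintf("mean cost per residue: core %.3f vs surface %.3f (relative)\n",
            mean(core$cost_akashi_gojobori, na.rm = TRUE),
            mean(surf$cost_akashi_gojobori, na.rm = TRUE)))
all_cr <- report$cr[report$element == "all_mapped"]
surf_cost <- surf$cost_akashi_gojobori
ct <- correlate(surf_cost, all_cr, "spearman")
cat(sprintf("Spearman rho(surface cost, CR) = %.2f (p = %.3f, n = %d)\n",
            ct$estimate, ct$p_value, ct$n))
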