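#!/usr/bin/env Rscript
# Stage 3 -- residue features and conserved-residue clusters.
#
# Annotates each reference structure with rSASA (surface/core at rSASA
# 0.25), secondary structure, and binding-site flags (planted pocket as
# UPb; a planted ligand drives CSb), then builds the 10 A contact network
# of fully conserved residues, extracts clusters (connected components,
# minimum size 3), and measures their overlap with the annotated sites.

suppressMessages(library(strucons))

corpus_dir <- "results/corpus"
stage2 <- readRDS("scratch/stage2.rds")
manifest <- read.delim(file.path(corpus_dir, "manifest.tsv"))
truth <- read.delim(file.path(corpus_dir, "truth.tsv"))

feature_rows <- cluster_rows <- overlap_rows <- list()
for (og_id in names(stage2$profiles)) {
  prof <- stage2$profiles[[og_id]]
  ref <- read_structure(
    file.path(corpus_dir, "structures", paste0(prof$reference_id, ".pdb")),
    plddt_from_bfactor = TRUE, structure_id = prof$reference_id)
  pocket <- as.integer(strsplit(truth$pocket[truth$og_id == og_id], ",")[[1]])
  attr(ref, "pocket") <- pocket
  ref <- plant_ligand(ref)
  f <- residue_features(ref)
  f$upb <- f$ref_idx %in% pocket
  feature_rows[[og_id]] <- cbind(og_id = og_id, f)

  cl <- find_clusters(conserved_network(prof, ref))
  if (length(cl$clusters) > 0) {
    cluster_rows[[og_id]] <- data.frame(
      og_id = og_id, cluster_id = rep(seq_along(cl$clusters), cl$sizes),
      ref_idx = unlist(cl$clusters))
  }
  for (flag in c("upb", "csb")) {
    ov <- suppressWarnings(cluster_site_overlap(cl, f[[flag]], ref, prof))
    overlap_rows[[paste(og_id, flag)]] <- data.frame(
      og_id = og_id, site_type = flag, n_clusters = length(cl$clusters),
      median_size = if (length(cl$sizes)) median(as.numeric(cl$sizes)) else NA,
      pct_sites_covered = ov$pct_sites_covered,
      enrichment_ratio = ov$enrichment_ratio)
  }
}
features <- do.call(rbind, feature_rows)
overlap <- do.call(rbind, overlap_rows)
write.table(features, "results/features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(do.call(rbind, cluster_rows), "results/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(overlap, "results/overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("features: %d residues annotated; surface fraction %.2f\n",
            nrow(features), mean(features$exposure == "surface")))
cat(sprintf("clusters per orthogroup: median %.1f, median size %.1f\n",
            median(overlap$n_clusters[overlap$site_type == "upb"]),
            median(overlap$median_size, na.rm = TRUE)))
cat(sprintf("UPb sites covered by a cluster: %.0f%% of orthogroups at 100%%\n",
            100 * mean(overlap$pct_sites_covered[overlap$site_type == "upb"]
                       == 100, na.rm = TRUE)))
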