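#!/usr/bin/env Rscript
# Stage 4 — sphere-ROI extraction, trait correlations, commonality analysis.
#
# A 10-mm sphere around each detected cluster peak yields one neural-trait
# value per subject (mean log current density across ROI voxels). The ROI
# columns are merged into the trait table; the pairwise correlation table is
# reported uncorrected (exploratory), and a two-predictor commonality
# analysis partitions each ROI's regression variance into parts unique to RT
# and COV and their shared part.

library(neurotrait)

map <- read_voxel_map("results/data/maps")
traits <- read_traits("results/data/traits.csv")
scores <- utils::read.delim("results/bart_scores.tsv")
clusters <- utils::read.delim("results/clusters.tsv")
traits$rt <- scores$rt[match(traits$subject_id, scores$subject_id)]
traits$cov <- scores$cov[match(traits$subject_id, scores$subject_id)]

if (nrow(clusters) == 0) {
  stop("no clusters detected upstream; nothing to extract")
}

roi_cols <- character(0)
for (sc in unique(clusters$score_name)) {
  top <- clusters[clusters$score_name == sc, ][1, ]
  roi <- sphere_roi(map, c(top$peak_x_mm, top$peak_y_mm, top$peak_z_mm),
                    radius_mm = 10, band = "delta")
  col <- paste0("roi_", sc, "_delta")
  traits[[col]] <- unname(roi$values[traits$subject_id])
  roi_cols <- c(roi_cols, col)
  cat(sprintf("%s ROI: %d voxels around (%g, %g, %g) mm\n", toupper(sc),
              length(roi$voxel_ids), top$peak_x_mm, top$peak_y_mm,
              top$peak_z_mm))
}
write_tsv_report(traits, "results/trait_table.tsv")

ct <- correlation_table(traits)
utils::write.table(round(ct$r, 3), "results/correlations_r.tsv", sep = "\t",
                   quote = FALSE, col.names = NA)
utils::write.table(signif(ct$p, 3), "results/correlations_p.tsv", sep = "\t",
                   quote = FALSE, col.names = NA)

commonality <- do.call(rbind, lapply(roi_cols, function(col) {
  res <- commonality_two_predictors(traits[[col]], traits$rt, traits$cov)
  cbind(data.frame(y = col, x1 = "rt", x2 = "cov"), commonality_tidy(res))
}))
write_tsv_report(commonality, "results/commonality.tsv")
cat("\nCommonality partition (percent of explained variance):\n")
print(commonality[, c("y", "r2_full", "percent_unique_x1",
                      "percent_unique_x2", "percent_common")])
cat("Outputs: results/trait_table.tsv, correlations_[rp].tsv, commonality.tsv\n")
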