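#!/usr/bin/env Rscript
# Biomarker statistics on the packaged reference serum cohort (36 controls,
# 2 Tay-Sachs, 1 Sandhoff): group comparisons with Grubbs filtering and BH
# adjustment, GM2/GM3 ratios, PCA on the GM species, and heatmap z-scores.
suppressPackageStartupMessages(library(gslquant))
dir.create("results", showWarnings = FALSE)

tab <- gsl_cohort()
ctl <- tab[tab$group == "control", ]
cat("control class means (fmol):\n")
print(round(colMeans(ctl[, setdiff(names(ctl), c("sample_id", "sex", "age",
                                                 "group"))]), 1))

stats_tab <- group_compare(tab)
write.csv(stats_tab, "results/cohort_group_stats.csv", row.names = FALSE)
cat("\nper-species patient-vs-control comparison:\n")
print(stats_tab[, c("species", "fc_mean", "fc_median", "p", "p_adj",
                    "removed")], digits = 3)

ratio <- gm2_gm3_ratio(tab)
write.csv(ratio$samples, "results/gm2_gm3_ratios.csv", row.names = FALSE)
cat(sprintf("\nGM2/GM3 ratio fold-change: mean-based %.1f, median-based %.1f\n",
            ratio$fold_change[["mean"]], ratio$fold_change[["median"]]))

pca <- cohort_pca(tab, species = c("GM1", "GM2", "GM3"))
write.csv(data.frame(sample_id = rownames(pca$scores), group = pca$groups,
                     pca$scores),
          "results/pca_scores.csv", row.names = FALSE)
write.csv(data.frame(species = rownames(pca$loadings), pca$loadings),
          "results/pca_loadings.csv", row.names = FALSE)
pc1 <- pca$scores[, 1]
pat <- pca$groups != "control"
cat(sprintf("PCA: PC1 explains %.1f%%; patients separate from controls on PC1: %s\n",
            100 * pca$explained_variance[1],
            min(pc1[pat]) > max(pc1[!pat]) || max(pc1[pat]) < min(pc1[!pat])))

z <- heatmap_zscores(tab, species = c("GM3", "GM2", "GM1"))
write.csv(data.frame(sample_id = rownames(z), group = tab$group, z),
          "results/heatmap_zscores.csv", row.names = FALSE)
cat("largest GM2 z-score:", rownames(z)[which.max(z[, "GM2"])], "\n")
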