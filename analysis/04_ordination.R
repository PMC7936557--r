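#!/usr/bin/env Rscript
# Classical MDS and covariance PCA of the 14-population scenario.
#
# Reads the synthetic reference tables written by 03_population_structure.R
# (run that first), projects the populations into 2-D by classical MDS of
# the Nei DA matrix and into 3 components by covariance PCA of the
# concatenated allele-frequency vectors, and reports how well the 2-D
# embedding preserves the distances.

suppressPackageStartupMessages(library(strpopgen))

ref_files <- Sys.glob("results/structure/SynthRef*.csv")
if (length(ref_files) == 0L)
  stop("no reference tables found; run analysis/03_population_structure.R first")

ft <- load_guanzhong_freqs()
panel <- guanzhong_shared_panel()
focal <- freq_table(ft$population, ft$loci[panel], ft$gene_copies)
pops <- c(list(focal), lapply(ref_files, read_freq_table))

dir.create("results/ordination", recursive = TRUE, showWarnings = FALSE)

da <- nei_da_matrix(pops, panel)
mds <- classical_mds(da, dims = 2)
mdf <- data.frame(population = mds$labels, round(mds$coords, 6))
names(mdf)[-1] <- c("dim1", "dim2")
write.csv(mdf, "results/ordination/mds_coordinates.csv", row.names = FALSE)

dc <- as.matrix(dist(mds$coords))
rho <- cor(da[lower.tri(da)], dc[lower.tri(dc)])
cat("MDS over", nrow(da), "populations\n")
cat("  leading eigenvalues:",
    paste(signif(mds$explained[1:3], 4), collapse = ", "), "\n")
cat("  negative inertia truncated:", signif(mds$negative_inertia, 3), "\n")
cat("  distance preservation (Pearson r, input vs 2-D):",
    sprintf("%.3f", rho), "\n\n")

pca <- pca_frequencies(pops, dims = 3, loci = panel)
pdf_ <- data.frame(population = pca$labels, round(pca$coords, 6))
write.csv(pdf_, "results/ordination/pca_coordinates.csv", row.names = FALSE)
cat("PCA of the (locus, allele) frequency matrix:",
    length(pca$center), "columns\n")
cat("  explained by first three components:",
    paste(sprintf("%.1f%%", 100 * pca$explained[1:3]), collapse = ", "),
    sprintf("(total %.1f%%)\n", 100 * sum(pca$explained[1:3])))
nb <- names(sort(da[1, -1]))[1]
cat("  nearest population to the focal sample in PC1/PC2:",
    pca$labels[which.min(rowSums(sweep(pca$coords[, 1:2], 2,
      pca$coords[1, 1:2])[-1, , drop = FALSE]^2)) + 1L],
    "(DA nearest:", nb, ")\n")
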