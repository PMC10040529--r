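#!/usr/bin/env Rscript
# Group predicted proteins into gene families: BLOSUM62 Smith-Waterman with
# affine gaps (11/1), score-normalized distance, single linkage at 0.75.
# Writes results/clusters.tsv.

library(pancooc)

faas <- list.files("results/orfs", pattern = "\\.faa$", full.names = TRUE)
stopifnot(length(faas) > 0)
aa <- do.call(c, lapply(faas, Biostrings::readAAStringSet))
proteins <- setNames(as.character(aa), names(aa))
cat(sprintf("clustering %d proteins (median length %d aa)\n",
            length(proteins), as.integer(median(nchar(proteins)))))

D <- build_distance_matrix(proteins, prefilter_k = 4L)
assignment <- single_linkage_cluster(D, threshold = 0.75)
write_clusters(assignment, "results/clusters.tsv")

sizes <- table(assignment$cluster_id)
cat(sprintf("%d gene families; sizes: min %d, median %g, max %d\n",
            length(sizes), min(sizes), median(sizes), max(sizes)))
off <- D[upper.tri(D)]
cat(sprintf("distance separation: %d pairs below the 0.75 threshold, %d at/above\n",
            sum(off < 0.75), sum(off >= 0.75)))
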