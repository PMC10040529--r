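#!/usr/bin/env Rscript
# Build the family x genome copy-count pan-matrix, screen Pearson
# co-occurrence against the maximum-NaCl phenotype at > 0.8, and compare the
# passing set with the planted truth. Writes results/panmatrix.tsv,
# results/screen_results.tsv and results/undefined.tsv.

library(pancooc)

assignment <- read_clusters("results/clusters.tsv")
phenotype <- read_phenotype("results/data/phenotype.tsv")
pan <- build_pan_matrix(assignment, phenotype = phenotype)
write_pan_matrix(pan, "results/panmatrix.tsv")

scr <- screen_cooccurrence(pan, phenotype, threshold = 0.8, mode = "counts")
results <- join_annotations(scr$pass)
write.table(data.frame(cluster_id = results$cluster_id,
                       cooccurrence = sprintf("%.2f", results$value_2dp),
                       n_members = results$n_members,
                       annotation = results$annotation),
            "results/screen_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(scr$undefined[, c("cluster_id", "n_members")],
            "results/undefined.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

print(scr)

# trace passing clusters back to planted families via exact coordinates
genes <- read.delim("results/data/genes.tsv", stringsAsFactors = FALSE)
truth <- read.delim("results/data/truth.tsv", stringsAsFactors = FALSE)
orf <- do.call(rbind, strsplit(assignment$orf_id, "|", fixed = TRUE))
orf_key <- paste(orf[, 1], orf[, 2], orf[, 3], orf[, 4], sep = "|")
gene_key <- paste(genes$genome_id, genes$contig_id, genes$start, genes$end, sep = "|")
fam <- genes$family_id[match(orf_key, gene_key)]
fam_of_cluster <- vapply(split(fam, assignment$cluster_id),
                         function(v) unique(v)[1], "")
pass_fams <- sort(unname(fam_of_cluster[results$cluster_id]))
want <- sort(truth$family_id[!is.na(truth$expected_cooccurrence) &
                               truth$expected_cooccurrence > 0.8])
cat(sprintf("passing families: %s\nplanted > 0.8:    %s\nexact match: %s\n",
            paste(pass_fams, collapse = ", "), paste(want, collapse = ", "),
            identical(pass_fams, want)))
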