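# Independent oracles, written before the implementations they check.

# Brute-force affine-gap local alignment DP: H/E/F recurrences over the full
# matrix, gap of length L costs open + L * ext, clamped at 0.
sw_oracle <- function(a, b, M, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + M[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Union-find over all sub-threshold pairs: the brute-force counterpart of
# single-linkage components.
uf_components <- function(D, threshold) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(len) paste(sample(AA, len, replace = TRUE), collapse = "")

# Small, fast simulation used by module-level tests (the full study-scale
# configuration is exercised in the acceptance tests).
small_sim <- function(seed = 11L, n_background = 6L) {
  sim_config(n_background = n_background, protein_length = 60L, seed = seed)
}

small_orf_params <- function() orf_params(min_protein_length = 50L)

# Map every recovered cluster to the planted family of its member genes via
# exact contig coordinates (cluster -> member ORFs -> coordinates -> truth).
map_clusters_to_families <- function(run, dataset) {
  genes <- dataset$genes
  gene_key <- paste(genes$genome_id, genes$contig_id, genes$start, genes$end,
                    sep = "|")
  orf_key <- paste(run$orfs$genome_id, run$orfs$contig_id, run$orfs$start,
                   run$orfs$end, sep = "|")
  fam_of_orf <- setNames(genes$family_id[match(orf_key, gene_key)],
                         run$orfs$orf_id)
  cl <- run$assignment$cluster_id[match(names(fam_of_orf), run$assignment$orf_id)]
  split(unname(fam_of_orf), cl)
}

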