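#' Alignment scoring scheme
#'
#' BLOSUM62 with affine gap penalties at the BLASTP defaults (open 11,
#' extend 1). A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param substitution_matrix symmetric named substitution matrix.
#' @param gap_open,gap_extend positive gap penalties, `gap_extend <= gap_open`.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution_matrix = blosum62(),
                           gap_open = 11L, gap_extend = 1L) {
  if (!isSymmetric(unname(substitution_matrix))) {
    stop("substitution matrix must be symmetric")
  }
  if (gap_open <= 0 || gap_extend <= 0 || gap_extend > gap_open) {
    stop("need 0 < gap_extend <= gap_open")
  }
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

check_protein <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L) {
    stop(what, " must be a single non-empty string")
  }
  if (grepl(sprintf("[^%s]", paste(AA20, collapse = "")), x)) {
    stop(what, " contains characters outside the 20-letter amino-acid alphabet")
  }
  invisible(x)
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under the scheme's substitution matrix and
#' affine gap penalties, clamped at 0 (two sequences with no positive-scoring
#' local alignment, e.g. "WWW" vs "PPP" under BLOSUM62, score 0).
#'
#' @param a,b protein sequences (non-empty, 20-letter alphabet).
#' @param scheme a [scoring_scheme()].
#' @return single non-negative alignment score.
#' @export
local_align_score <- function(a, b, scheme = scoring_scheme()) {
  check_protein(a, "'a'"); check_protein(b, "'b'")
  s <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = scheme$substitution_matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE)
  max(0, s)
}

self_score <- function(x, scheme) {
  m <- scheme$substitution_matrix
  sum(diag(m)[strsplit(x, "")[[1L]]])
}

#' Normalized alignment distance between two proteins
#'
#' `d = 1 - 2 S(a,b) / (S(a,a) + S(b,b))`, clamped into \[0, 1\]: 0 for
#' identical sequences, 1 for sequences with no positive-scoring local
#' alignment. Self-scores are gap-free diagonal sums (each diagonal entry is
#' its row maximum in BLOSUM62, so the identity alignment is optimal).
#'
#' @inheritParams local_align_score
#' @return distance in \[0, 1\].
#' @export
pairwise_distance <- function(a, b, scheme = scoring_scheme()) {
  s <- local_align_score(a, b, scheme)
  d <- 1 - 2 * s / (self_score(a, scheme) + self_score(b, scheme))
  min(1, max(0, d))
}

kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

#' All-vs-all normalized alignment distances
#'
#' Computes the full symmetric distance matrix over a named set of proteins.
#' With the k-mer prefilter on (default k = 4), pairs sharing no k-mer are
#' assigned distance 1 without alignment — a large saving for unrelated
#' random-background families, and exact for clustering purposes because
#' such pairs sit far above any sensible threshold.
#'
#' @param proteins named character vector (names are ORF ids, must be unique).
#' @param scheme a [scoring_scheme()].
#' @param prefilter_k k-mer length for the shared-k-mer prefilter, or `NULL`
#'   to align every pair.
#' @return symmetric numeric matrix in \[0, 1\] with zero diagonal and the
#'   protein names as dimnames.
#' @export
build_distance_matrix <- function(proteins, scheme = scoring_scheme(),
                                  prefilter_k = 4L) {
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    stop("'proteins' must be uniquely named")
  }
  for (p in proteins) check_protein(p)
  n <- length(proteins)
  ids <- names(proteins)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n == 1L) return(D)
  selfs <- vapply(proteins, self_score, 0, scheme = scheme)
  km <- if (!is.null(prefilter_k)) kmer_sets(proteins, as.integer(prefilter_k))
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    if (!is.null(prefilter_k)) {
      share <- vapply(js, function(j) any(km[[i]] %in% km[[j]]), NA)
      D[i, js[!share]] <- 1
      js <- js[share]
    }
    if (length(js)) {
      sc <- Biostrings::pairwiseAlignment(
        unname(proteins[js]), proteins[[i]], type = "local",
        substitutionMatrix = scheme$substitution_matrix,
        gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
        scoreOnly = TRUE)
      sc <- pmax(0, sc)
      D[i, js] <- pmin(1, pmax(0, 1 - 2 * sc / (selfs[i] + selfs[js])))
    }
  }
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

#' Single-linkage gene-family clustering
#'
#' Gene families are the connected components of the graph whose edges join
#' sequence pairs with distance strictly below the threshold — equivalently,
#' the single-linkage dendrogram cut at the threshold. Cluster ids
#' `Cluster_1`, `Cluster_2`, ... are assigned by ascending order of each
#' cluster's lexicographically smallest member id, so the partition and its
#' labels are invariant under permutation of the input.
#'
#' @param D symmetric distance matrix with unique dimnames
#'   (from [build_distance_matrix()]).
#' @param threshold merge distance in (0, 1]; pairs with `d < threshold`
#'   (strict) are connected. Default 0.75.
#' @return data frame with columns `orf_id`, `cluster_id`, ordered by
#'   cluster rank then member id.
#' @export
single_linkage_cluster <- function(D, threshold = 0.75) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("'threshold' must be in (0, 1]")
  }
  ids <- rownames(D)
  if (is.null(ids) || anyDuplicated(ids)) stop("'D' must have unique rownames")
  adj <- (D < threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  rep_id <- vapply(split(ids, comp), min, "")
  new_rank <- rank(rep_id)  # representatives are distinct, so no ties
  cluster_id <- paste0("Cluster_", new_rank[as.character(comp)])
  out <- data.frame(orf_id = ids, cluster_id = cluster_id,
                    stringsAsFactors = FALSE)
  out <- out[order(cluster_rank(out$cluster_id), out$orf_id), ]
  rownames(out) <- NULL
  out
}

#' Write / read a cluster assignment TSV (`orf_id<TAB>cluster_id`)
#' @param assignment data frame with columns `orf_id`, `cluster_id`.
#' @param path TSV path.
#' @return `write_clusters` returns `path` invisibly; `read_clusters` the
#'   assignment data frame.
#' @export
write_clusters <- function(assignment, path) {
  utils::write.table(assignment[, c("orf_id", "cluster_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character"))
}

#' Write a distance matrix as TSV (ids as header row and first column,
#' values at 4 decimals)
#' @param D distance matrix.
#' @param path TSV path.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(id = rownames(D), format(round(D, 4L), nsmall = 4L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
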