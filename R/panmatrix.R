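#' Read a phenotype table
#'
#' Reads the tab-separated strain phenotype table (columns `strain_id`,
#' `max_nacl_percent`). The strain order in the file fixes the genome order
#' of every downstream matrix, so the file should list strains in the order
#' results are to be reported (here: decreasing maximum NaCl).
#'
#' @param path TSV file with header `strain_id<TAB>max_nacl_percent`.
#' @return data frame with columns `strain_id` (character) and
#'   `max_nacl_percent` (numeric).
#' @export
read_phenotype <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric"))
  validate_phenotype(df)
}

validate_phenotype <- function(df) {
  if (!all(c("strain_id", "max_nacl_percent") %in% names(df))) {
    stop("phenotype table needs columns 'strain_id' and 'max_nacl_percent'")
  }
  df <- df[, c("strain_id", "max_nacl_percent")]
  if (nrow(df) < 3L) stop("phenotype table needs at least 3 strains")
  if (anyDuplicated(df$strain_id)) stop("duplicate strain ids in phenotype table")
  if (anyNA(df$max_nacl_percent) || any(df$max_nacl_percent <= 0)) {
    stop("phenotype values must be positive numbers")
  }
  if (stats::var(df$max_nacl_percent) == 0) {
    stop("phenotype is constant across strains; co-occurrence would be undefined everywhere")
  }
  df
}

#' Build the gene-family x genome copy-count pan-matrix
#'
#' Counts, for every cluster, how many member ORFs each genome contributes.
#' Columns follow the phenotype table's strain order so abundance rows line
#' up with the phenotype vector. Total counts equal the number of clustered
#' ORFs (nothing is dropped).
#'
#' @param assignment data frame with columns `orf_id`, `cluster_id`
#'   (a cluster assignment from [single_linkage_cluster()] or read from TSV).
#' @param orf_to_genome named character vector mapping `orf_id` to strain id.
#'   Defaults to parsing the genome field of ids shaped
#'   `genome|contig|start|end|strand`.
#' @param phenotype phenotype data frame; its `strain_id` order fixes the
#'   column order.
#' @return Object of class `pan_matrix`: list with `counts` (integer matrix,
#'   clusters x genomes) and `members` (cluster id -> character vector of
#'   member ORF ids).
#' @export
build_pan_matrix <- function(assignment, orf_to_genome = NULL, phenotype) {
  phenotype <- validate_phenotype(phenotype)
  strains <- phenotype$strain_id
  if (is.null(orf_to_genome)) {
    orf_to_genome <- stats::setNames(
      vapply(strsplit(assignment$orf_id, "|", fixed = TRUE), `[`, "", 1L),
      assignment$orf_id)
  }
  genome <- unname(orf_to_genome[assignment$orf_id])
  if (anyNA(genome)) {
    stop("no genome mapping for ORFs: ",
         paste(utils::head(assignment$orf_id[is.na(genome)], 3L), collapse = ", "))
  }
  bad <- setdiff(unique(genome), strains)
  if (length(bad)) {
    stop("ORFs mapped to strains absent from the phenotype table: ",
         paste(bad, collapse = ", "))
  }
  ids <- unique(assignment$cluster_id)
  ids <- ids[order(cluster_rank(ids))]
  counts <- matrix(0L, nrow = length(ids), ncol = length(strains),
                   dimnames = list(ids, strains))
  if (nrow(assignment)) {
    tab <- table(factor(assignment$cluster_id, levels = ids),
                 factor(genome, levels = strains))
    counts[] <- as.integer(tab)
  }
  members <- split(assignment$orf_id, factor(assignment$cluster_id, levels = ids))
  structure(list(counts = counts, members = members), class = "pan_matrix")
}

#' @export
print.pan_matrix <- function(x, ...) {
  cat(sprintf("pan-matrix: %d gene families x %d genomes (%d ORFs)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Write / read a pan-matrix as TSV
#'
#' Plain clusters-by-genomes table: first column `cluster_id`, remaining
#' columns one per strain in phenotype order.
#'
#' @param pan a `pan_matrix` object.
#' @param path output TSV path.
#' @return `write_pan_matrix` returns `path` invisibly; `read_pan_matrix`
#'   returns an integer matrix with cluster-id rownames.
#' @export
write_pan_matrix <- function(pan, path) {
  df <- data.frame(cluster_id = rownames(pan$counts), pan$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pan_matrix
#' @export
read_pan_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$cluster_id
  m
}
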