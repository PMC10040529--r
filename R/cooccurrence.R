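#' Pearson co-occurrence between a gene family's abundance and a phenotype
#'
#' The screening statistic of the pipeline: the sample Pearson correlation
#' between a family's per-genome copy counts `x` and the quantitative
#' phenotype `y` (maximum NaCl, \% w/v). Normalization factors cancel between
#' numerator and denominator, so sample and population variants are
#' identical by construction.
#'
#' Families present in every genome at equal copy number (zero variance in
#' `x`) have no defined correlation; these "core" rows return `NA` and are
#' reported separately by [screen_cooccurrence()], never silently dropped.
#'
#' @param x numeric vector of non-negative per-genome abundances.
#' @param y numeric phenotype vector, same genome order as `x`.
#' @return A single value in \[-1, 1\], or `NA_real_` when `x` is constant.
#' @examples
#' y <- c(10, 9, 9, 5, 4, 3)
#' pearson_cooccurrence(c(1, 1, 1, 0, 0, 0), y)  # 0.970...
#' pearson_cooccurrence(c(1, 1, 1, 1, 1, 1), y)  # NA: core family
#' @export
pearson_cooccurrence <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("'x' and 'y' must be numeric vectors")
  }
  if (length(x) != length(y)) {
    stop("length mismatch: length(x) = ", length(x),
         ", length(y) = ", length(y))
  }
  if (length(x) < 3L) stop("need at least 3 genomes")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (syy == 0) stop("phenotype vector is constant; co-occurrence undefined for every family")
  if (sxx == 0) return(NA_real_)
  sum(dx * dy) / sqrt(sxx * syy)
}

#' Round half away from zero
#'
#' Two-decimal reporting uses half-away-from-zero rounding (so 0.975 -> 0.98
#' and -0.975 -> -0.98) rather than banker's rounding, keeping printed values
#' stable across platforms.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Screen a pan-matrix for families co-occurring with the phenotype
#'
#' Computes the co-occurrence of every pan-matrix row against the phenotype
#' and retains families whose (unrounded) value strictly exceeds the
#' threshold. Rows with zero abundance variance ("core" families) are
#' undefined and reported in the `undefined` component. Passing rows are
#' ordered by the 2-decimal value descending, ties broken by cluster id
#' ascending (numeric suffix order for ids like `Cluster_12`).
#'
#' @param pan a `pan_matrix` from [build_pan_matrix()], or a plain numeric
#'   matrix with cluster-id rownames and genome columns in phenotype order.
#' @param phenotype a phenotype table (see [read_phenotype()]) or a numeric
#'   vector in the pan-matrix's column order.
#' @param threshold screening cutoff; families with value strictly greater
#'   than this pass. Default 0.8.
#' @param mode `"counts"` screens integer copy counts; `"binary"` binarizes
#'   each row to presence/absence first.
#' @param absolute if `TRUE`, screen on `|value|` so strong negative
#'   associations also pass; the reported value keeps its sign.
#' @return A list of class `cooc_screen` with data frames `pass`, `undefined`
#'   and `all`. Each row carries `cluster_id`, `value` (full precision),
#'   `value_2dp`, `n_members` and `member_orf_ids` (comma-joined).
#' @export
screen_cooccurrence <- function(pan, phenotype, threshold = 0.8,
                                mode = c("counts", "binary"),
                                absolute = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1) {
    stop("'threshold' must be a single value in [0, 1)")
  }
  counts <- if (inherits(pan, "pan_matrix")) pan$counts else as.matrix(pan)
  members <- if (inherits(pan, "pan_matrix")) pan$members else NULL
  y <- if (is.data.frame(phenotype)) phenotype$max_nacl_percent else phenotype
  if (is.data.frame(phenotype) && ncol(counts) > 0 &&
      !identical(colnames(counts), phenotype$strain_id)) {
    stop("pan-matrix genome order does not match the phenotype table")
  }
  if (ncol(counts) > 0 && length(y) != ncol(counts)) {
    stop("phenotype length does not match the number of genomes")
  }

  n <- nrow(counts)
  ids <- rownames(counts)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    x <- counts[i, ]
    if (mode == "binary") x <- as.numeric(x > 0)
    vals[i] <- pearson_cooccurrence(x, y)
  }
  member_str <- if (is.null(members)) {
    rep(NA_character_, n)
  } else {
    vapply(ids, function(id) paste(sort(members[[id]]), collapse = ","), "")
  }
  all_df <- data.frame(
    cluster_id = if (is.null(ids)) character(0) else ids,
    value = vals,
    value_2dp = round_half_away(vals, 2L),
    n_members = as.integer(rowSums(counts)),
    member_orf_ids = member_str,
    stringsAsFactors = FALSE
  )
  undef <- all_df[is.na(all_df$value), , drop = FALSE]
  defined <- all_df[!is.na(all_df$value), , drop = FALSE]
  crit <- if (absolute) abs(defined$value) else defined$value
  pass <- defined[crit > threshold, , drop = FALSE]
  ord <- order(-pass$value_2dp, cluster_rank(pass$cluster_id))
  pass <- pass[ord, , drop = FALSE]
  rownames(pass) <- NULL
  rownames(undef) <- NULL
  structure(list(pass = pass, undefined = undef, all = all_df,
                 threshold = threshold, mode = mode, absolute = absolute),
            class = "cooc_screen")
}

#' @export
print.cooc_screen <- function(x, ...) {
  cat(sprintf(
    "co-occurrence screen: %d/%d families pass (> %g, mode = %s)%s\n",
    nrow(x$pass), nrow(x$all), x$threshold, x$mode,
    if (nrow(x$undefined)) sprintf("; %d core rows undefined", nrow(x$undefined)) else ""
  ))
  if (nrow(x$pass)) {
    print(x$pass[, c("cluster_id", "value_2dp", "n_members")], row.names = FALSE)
  }
  invisible(x)
}

# Sort key for cluster ids: numeric suffix where the id looks like
# "Cluster_<n>", lexicographic rank otherwise.
cluster_rank <- function(ids) {
  suf <- suppressWarnings(as.numeric(sub("^.*_", "", ids)))
  if (anyNA(suf)) xtfrm(ids) else suf
}

#' Enumerate all abundance patterns and their co-occurrence values
#'
#' Exhaustive oracle for the screening statistic: every vector in
#' `{0..max_count}^n` except all-zero, with its Pearson co-occurrence
#' against `y`. Used to verify which patterns can produce a printed value
#' (e.g. which copy-count vectors round to 0.84) and to check uniqueness of
#' binary explanations.
#'
#' @param y phenotype vector (length at most 8; combinatorial guard).
#' @param max_count largest copy count to enumerate (at most 4).
#' @return data frame with `pattern` (comma-joined counts), `value`, and
#'   `value_2dp`; `NA` value marks constant (undefined) patterns.
#' @export
enumerate_patterns <- function(y, max_count = 1L) {
  if (length(y) > 8L) stop("pattern enumeration is guarded to length(y) <= 8")
  if (!is.numeric(max_count) || length(max_count) != 1L ||
      max_count < 1L || max_count > 4L) {
    stop("'max_count' must be an integer in 1..4")
  }
  grid <- as.matrix(expand.grid(rep(list(0:max_count), length(y)),
                                KEEP.OUT.ATTRS = FALSE))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  vals <- apply(grid, 1L, pearson_cooccurrence, y = y)
  data.frame(
    pattern = apply(grid, 1L, paste, collapse = ","),
    value = vals,
    value_2dp = round_half_away(vals, 2L),
    stringsAsFactors = FALSE
  )
}

#' Attach functional annotations to screen results
#'
#' Replaces an external protein-database search with a join against a
#' user-supplied `cluster_id -> annotation` map. Families without an entry
#' get the conventional "hypothetical protein" label. Row order is preserved.
#'
#' @param results a data frame with a `cluster_id` column (e.g. the `pass`
#'   component of a [screen_cooccurrence()] result).
#' @param annotations named character vector or two-column data frame
#'   (`cluster_id`, `annotation`). May be empty.
#' @return `results` with an `annotation` column appended.
#' @export
join_annotations <- function(results, annotations = character(0)) {
  if (is.data.frame(annotations)) {
    annotations <- stats::setNames(as.character(annotations[[2L]]),
                                   as.character(annotations[[1L]]))
  }
  unknown <- setdiff(names(annotations), results$cluster_id)
  if (length(unknown)) {
    warning("annotations for unknown clusters ignored: ",
            paste(unknown, collapse = ", "))
  }
  ann <- unname(annotations[results$cluster_id])
  ann[is.na(ann)] <- "hypothetical protein"
  if (nrow(results) == 0L) ann <- character(0)
  results$annotation <- ann
  results
}
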