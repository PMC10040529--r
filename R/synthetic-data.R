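# Deterministic seed derivation: every random stream in the generator is a
# fixed integer recurrence on the single config seed, kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 97651L) * 7919 + 13 * i) %% 2147483646L + 1L
}

# Spacer tile: TTAA is its own reverse complement, contains no G (so no ATG
# on either strand), and three tiles in a row place a stop codon in all six
# frames within 12 nt.
TTAA_BLOCK <- "TTAATTAATTAA"

#' Deterministic residue -> codon table for gene synthesis
#'
#' One fixed codon per amino acid — the lexicographically smallest codon
#' (so Lys -> AAA, Met -> ATG) — giving byte-stable reverse translation.
#' Note that any one-codon-per-residue table skews off-frame codon
#' statistics (this one places no T in third codon positions, leaving one
#' shifted frame stop-free), which is why [generate_dataset()] samples
#' synonymous codons with a seed instead of using a fixed table.
#'
#' @return named character vector, amino acid -> codon.
#' @export
default_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  vapply(AA20, function(aa) sort(names(gc)[gc == aa])[1L], "")
}

synonymous_codons <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))[AA20]
    }
    cache
  }
})

#' Substitute residues of a protein at a fixed per-site rate
#'
#' Each position is independently substituted with probability `rate` by a
#' uniformly chosen *different* residue, so `rate = 1` changes every
#' position. Deterministic given `seed`.
#'
#' @param protein residue string over the 20-letter alphabet.
#' @param rate per-residue substitution probability in \[0, 1).
#' @param seed integer seed.
#' @return mutated residue string, same length.
#' @export
mutate_protein <- function(protein, rate, seed) {
  check_protein(protein, "'protein'")
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1) {
    stop("'rate' must be a probability in [0, 1]")
  }
  res <- strsplit(protein, "")[[1L]]
  with_seed(seed, {
    hit <- stats::runif(length(res)) < rate
    if (any(hit)) {
      res[hit] <- vapply(res[hit], function(r) sample(setdiff(AA20, r), 1L), "")
    }
  })
  paste(res, collapse = "")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Reverse-translate a protein into a coding sequence
#'
#' Emits one codon per residue followed by a single `TAA` stop, so a protein
#' of length n starting with M becomes an `ATG`-led CDS of length 3(n+1)
#' with no internal stop, and `translate_cds(reverse_translate(p)) == p`.
#' By default codons come from the fixed [default_codon_table()]
#' (byte-stable output); with `seed` set, each codon is drawn uniformly from
#' the residue's synonymous codons instead, which restores natural stop
#' density in the five non-coding frames.
#'
#' @param protein residue string.
#' @param codon_table residue -> codon map with no stop-codon values
#'   (ignored when `seed` is given).
#' @param seed integer seed for uniform synonymous-codon sampling, or
#'   `NULL` (default) for the fixed table.
#' @return nucleotide string.
#' @export
reverse_translate <- function(protein, codon_table = default_codon_table(),
                              seed = NULL) {
  check_protein(protein, "'protein'")
  res <- strsplit(protein, "")[[1L]]
  if (!is.null(seed)) {
    syn <- synonymous_codons()
    codons <- with_seed(seed, vapply(res, function(r) {
      cands <- syn[[r]]
      cands[sample.int(length(cands), 1L)]
    }, ""))
    return(paste0(paste(codons, collapse = ""), "TAA"))
  }
  if (any(codon_table %in% STOP_CODONS)) {
    stop("codon table must not map residues to stop codons")
  }
  missing <- setdiff(res, names(codon_table))
  if (length(missing)) {
    stop("no codon for residue(s): ", paste(missing, collapse = ", "))
  }
  paste0(paste(codon_table[res], collapse = ""), "TAA")
}

#' Specify a planted or background gene family
#'
#' @param family_id label carried into the truth ledger.
#' @param copy_counts non-negative integer vector, one entry per strain:
#'   copies of this family per genome. At least one must be positive.
#' @param protein_length prototype length in residues.
#' @param role `"planted"` (pattern chosen to hit a known co-occurrence) or
#'   `"background"` (phenotype-unassociated filler).
#' @return list of class `family_spec`.
#' @export
family_spec <- function(family_id, copy_counts, protein_length = 120L,
                        role = c("planted", "background")) {
  role <- match.arg(role)
  if (any(copy_counts < 0) || any(copy_counts != round(copy_counts))) {
    stop("copy counts must be non-negative integers")
  }
  if (all(copy_counts == 0)) stop("family '", family_id, "' has all-zero counts")
  if (protein_length < 2L) stop("'protein_length' must be at least 2")
  structure(list(family_id = as.character(family_id),
                 copy_counts = as.integer(copy_counts),
                 protein_length = as.integer(protein_length),
                 role = role),
            class = "family_spec")
}

#' Simulation configuration
#'
#' Defaults mirror the six-strain study design: strains ordered by
#' decreasing maximum NaCl with phenotype vector (10, 9, 9, 5, 4, 3) % w/v,
#' five planted families whose copy-count patterns hit known co-occurrence
#' values (0.97, 0.81, 0.84, a -0.97 negative control and an undefined core
#' family), 30 phenotype-unassociated background families, 120-residue
#' proteins, 5% within-family divergence.
#'
#' @param strains character vector of distinct strain ids.
#' @param phenotype_values positive phenotype vector, same order.
#' @param families list of [family_spec()] objects, or `NULL` to build the
#'   default planted + background set deterministically from `seed`.
#' @param n_background number of background families when `families` is NULL.
#' @param substitution_rate per-residue substitution probability applied to
#'   each gene copy (position 1 is kept as Met so every copy remains an
#'   ATG-started gene). Must stay well below the clustering threshold's
#'   divergence equivalent; at the 0.05 default, within-family distances sit
#'   far below 0.5 while unrelated families sit near 1.
#' @param protein_length prototype length for default families.
#' @param spacer_length minimum intergenic spacer, nt. Spacers are built
#'   from A/T-only `TTAA` tiles (stop codons in all six frames every 12 nt,
#'   no ATG on either strand) alternating with 30-nt random stretches, and
#'   always abut genes with a tile, so the ORF finder recovers exactly the
#'   planted genes.
#' @param seed integer master seed; all randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(strains = c("KCTC_42006", "JCM_17802", "KCTC_12311",
                                   "KCTC_52763", "KCTC_42453", "KCTC_52259"),
                       phenotype_values = c(10, 9, 9, 5, 4, 3),
                       families = NULL,
                       n_background = 30L,
                       substitution_rate = 0.05,
                       protein_length = 120L,
                       spacer_length = 60L,
                       seed = 1L) {
  if (anyDuplicated(strains)) stop("duplicate strain ids")
  if (length(phenotype_values) != length(strains)) {
    stop("'phenotype_values' must match 'strains' in length")
  }
  if (any(phenotype_values <= 0)) stop("phenotype values must be positive")
  if (!is.numeric(substitution_rate) || substitution_rate < 0 ||
      substitution_rate >= 1) {
    stop("'substitution_rate' must be in [0, 1)")
  }
  if (is.null(families)) {
    families <- default_families(length(strains), phenotype_values,
                                 n_background, protein_length, seed)
  }
  for (f in families) {
    if (!inherits(f, "family_spec")) stop("'families' must be family_spec objects")
    if (length(f$copy_counts) != length(strains)) {
      stop("family '", f$family_id, "' has ", length(f$copy_counts),
           " counts for ", length(strains), " strains")
    }
  }
  if (anyDuplicated(vapply(families, `[[`, "", "family_id"))) {
    stop("duplicate family ids")
  }
  structure(list(strains = as.character(strains),
                 phenotype_values = as.numeric(phenotype_values),
                 families = families,
                 substitution_rate = substitution_rate,
                 spacer_length = as.integer(spacer_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Default family set: planted patterns with known co-occurrence against the
# phenotype, plus background families with iid counts in {0,1,2} resampled
# until phenotype-unassociated (|r| <= 0.8; constant rows allowed — real pan
# genomes have a core).
default_families <- function(n_strains, y, n_background, protein_length, seed) {
  stopifnot(n_strains == 6L)
  planted <- list(
    family_spec("planted_pres3", c(1, 1, 1, 0, 0, 0), protein_length, "planted"),
    family_spec("planted_pres4", c(1, 1, 1, 1, 0, 0), protein_length, "planted"),
    family_spec("planted_dup3",  c(1, 1, 2, 0, 0, 0), protein_length, "planted"),
    family_spec("planted_anti",  c(0, 0, 0, 1, 1, 1), protein_length, "planted"),
    family_spec("planted_core",  c(1, 1, 1, 1, 1, 1), protein_length, "planted")
  )
  bg <- vector("list", n_background)
  for (i in seq_len(n_background)) {
    counts <- with_seed(derive_seed(seed, 1000L + i), {
      repeat {
        cand <- sample(0:2, n_strains, replace = TRUE,
                       prob = c(0.35, 0.5, 0.15))
        if (all(cand == 0)) next
        r <- pearson_cooccurrence(cand, y)
        if (is.na(r) || abs(r) <= 0.8) break
      }
      cand
    })
    bg[[i]] <- family_spec(sprintf("bg_%02d", i), counts, protein_length,
                           "background")
  }
  c(planted, bg)
}

random_protein <- function(len, seed) {
  with_seed(seed, paste(c("M", sample(AA20, len - 1L, replace = TRUE)),
                        collapse = ""))
}

random_dna <- function(len, seed) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""))
}

# Shortest spurious-ORF length the generator guards against: ORF callers
# run at min_protein_length >= this recover exactly the planted genes.
clean_len <- function(config) {
  min(50L, vapply(config$families, `[[`, 0L, "protein_length"))
}

# Synthesize a CDS whose only recoverable ORF (>= min_len residues, any of
# the six frames) is the gene itself. Codons are drawn seeded-uniform from
# the synonymous sets; draws that leave a long stop-free stretch in an
# off-frame are rejected and resampled with the next derived seed. The CDS
# is checked flanked by one TTAA tile per side because in assembled contigs
# every frame entering the flanking spacer hits a stop within 12 nt.
clean_cds <- function(protein, seed, min_len) {
  for (attempt in seq_len(100L)) {
    cds <- reverse_translate(protein, seed = derive_seed(seed, 7000L + attempt))
    flanked <- paste0(TTAA_BLOCK, cds, TTAA_BLOCK)
    hits <- find_orfs(flanked, params = orf_params(
      min_protein_length = min_len, require_stop = FALSE))
    if (nrow(hits) == 1L) return(cds)
  }
  stop("could not synthesize a clean CDS in 100 attempts (protein length ",
       nchar(protein), ", guard ", min_len, ")")
}

# Spacer: TTAA tiles flanking 30-nt random stretches; grows until at least
# `min_len`, always starting and ending on a tile.
make_spacer <- function(min_len, seed) {
  s <- TTAA_BLOCK
  i <- 0L
  while (nchar(s) < min_len) {
    i <- i + 1L
    s <- paste0(s, random_dna(30L, derive_seed(seed, i)), TTAA_BLOCK)
  }
  s
}

#' Generate a synthetic multi-genome dataset with planted gene families
#'
#' Builds one contig per strain: for each family with copy count k in that
#' strain, k independently mutated copies of the family's random prototype
#' protein are reverse-translated and embedded between stop-rich spacers,
#' in a per-strain deterministic shuffle. The truth ledger records each
#' family's copy-count vector and its expected co-occurrence, computed with
#' the same statistic the screen applies ([pearson_cooccurrence()]), plus
#' the exact contig coordinates of every embedded gene.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset`:
#'   `genomes` (named character vector, strain -> contig sequence),
#'   `phenotype` (data frame `strain_id`, `max_nacl_percent`),
#'   `truth` (data frame `family_id`, `role`, `copy_counts` comma-joined,
#'   `expected_cooccurrence`),
#'   `genes` (data frame `family_id`, `genome_id`, `contig_id`, `start`,
#'   `end`, `strand`, `protein`), and `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  fams <- config$families
  protos <- lapply(seq_along(fams), function(i) {
    random_protein(fams[[i]]$protein_length, derive_seed(config$seed, 2000L + i))
  })
  genomes <- character(0)
  genes <- list()
  for (g in seq_along(config$strains)) {
    strain <- config$strains[g]
    contig_id <- paste0(strain, "_c1")
    # collect this strain's gene copies (family index, copy index)
    copies <- do.call(rbind, lapply(seq_along(fams), function(i) {
      k <- fams[[i]]$copy_counts[g]
      if (k > 0) data.frame(fam = i, copy = seq_len(k)) else NULL
    }))
    seq_parts <- make_spacer(config$spacer_length,
                             derive_seed(config$seed, 3000L + 100L * g))
    if (!is.null(copies)) {
      ord <- with_seed(derive_seed(config$seed, 4000L + g),
                       sample(nrow(copies)))
      copies <- copies[ord, , drop = FALSE]
      for (r in seq_len(nrow(copies))) {
        i <- copies$fam[r]; ci <- copies$copy[r]
        mseed <- derive_seed(config$seed, 5000L + 211L * i + 17L * g + ci)
        body <- mutate_protein(substring(protos[[i]], 2L),
                               config$substitution_rate, mseed)
        prot <- paste0("M", body)
        cds <- clean_cds(prot, mseed, clean_len(config))
        start <- nchar(seq_parts) + 1L
        end <- start + nchar(cds) - 1L
        genes[[length(genes) + 1L]] <- data.frame(
          family_id = fams[[i]]$family_id, genome_id = strain,
          contig_id = contig_id, start = start, end = end, strand = "+",
          protein = prot, stringsAsFactors = FALSE)
        seq_parts <- paste0(
          seq_parts, cds,
          make_spacer(config$spacer_length,
                      derive_seed(config$seed, 3000L + 100L * g + r)))
      }
    }
    genomes[[strain]] <- seq_parts
  }
  genes <- do.call(rbind, genes)
  truth <- data.frame(
    family_id = vapply(fams, `[[`, "", "family_id"),
    role = vapply(fams, `[[`, "", "role"),
    copy_counts = vapply(fams, function(f) paste(f$copy_counts, collapse = ","), ""),
    expected_cooccurrence = vapply(fams, function(f)
      pearson_cooccurrence(f$copy_counts, config$phenotype_values), 0),
    stringsAsFactors = FALSE)
  phenotype <- data.frame(strain_id = config$strains,
                          max_nacl_percent = config$phenotype_values,
                          stringsAsFactors = FALSE)
  structure(list(genomes = genomes, phenotype = phenotype, truth = truth,
                 genes = genes, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d strains, %d families, %d embedded genes\n",
              length(x$genomes), nrow(x$truth), nrow(x$genes)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' One nucleotide FASTA per strain (`<strain>.fna`, 70-character wrap), a
#' phenotype TSV, the truth ledger TSV and the embedded-gene coordinate TSV.
#'
#' @param dataset a `sim_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (strain in names(dataset$genomes)) {
    p <- file.path(dir, paste0(strain, ".fna"))
    dna <- Biostrings::DNAStringSet(stats::setNames(dataset$genomes[strain],
                                                    paste0(strain, "_c1")))
    Biostrings::writeXStringSet(dna, p, width = 70L)
    paths <- c(paths, p)
  }
  p_phen <- file.path(dir, "phenotype.tsv")
  utils::write.table(dataset$phenotype, p_phen, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_truth <- file.path(dir, "truth.tsv")
  utils::write.table(dataset$truth, p_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_genes <- file.path(dir, "genes.tsv")
  utils::write.table(dataset$genes, p_genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, p_phen, p_truth, p_genes))
}
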