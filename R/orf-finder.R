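STOP_CODONS <- c("TAA", "TAG", "TGA")

#' ORF-calling parameters
#'
#' @param min_protein_length minimum translated length, in residues,
#'   for an ORF to be reported. Default 100.
#' @param start_codons candidate start codons. Default `"ATG"`; add
#'   `"GTG"`/`"TTG"` for bacterial alternative starts.
#' @param require_stop if `TRUE` (default) an ORF must end in a stop codon;
#'   if `FALSE`, a start-to-contig-end stretch with no stop is also reported.
#' @return list of class `orf_params`.
#' @export
orf_params <- function(min_protein_length = 100L,
                       start_codons = "ATG",
                       require_stop = TRUE) {
  if (!is.numeric(min_protein_length) || min_protein_length < 1L) {
    stop("'min_protein_length' must be a positive integer")
  }
  if (!all(grepl("^[ACGT]{3}$", start_codons))) {
    stop("start codons must be 3-letter A/C/G/T strings")
  }
  structure(list(min_protein_length = as.integer(min_protein_length),
                 start_codons = toupper(start_codons),
                 require_stop = isTRUE(require_stop)),
            class = "orf_params")
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds uppercase A/C/G/T string, length divisible by 3, with at most
#'   a single trailing stop codon (which is dropped). An internal stop codon
#'   is an error, as is any ambiguity code: inputs here are assembled
#'   contigs/CDS where an unexpected base signals an upstream bug.
#' @return the translated residue string, without a stop symbol.
#' @export
translate_cds <- function(cds) {
  if (!is.character(cds) || length(cds) != 1L || nchar(cds) == 0L) {
    stop("'cds' must be a single non-empty string")
  }
  if (grepl("[^ACGT]", cds)) stop("non-ACGT character in CDS (no IUPAC ambiguity support)")
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  if (codons[length(codons)] %in% STOP_CODONS) codons <- codons[-length(codons)]
  if (any(codons %in% STOP_CODONS)) stop("internal stop codon in CDS")
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Reverse-complement a nucleotide string
#' @param x uppercase A/C/G/T string.
#' @return the reverse complement, as a plain string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Predict ORFs on both strands of a contig
#'
#' Six-frame scan: in each frame, every maximal stop-to-stop interval
#' contributes at most one ORF, running from the first start codon after the
#' previous stop to the next stop. Minus-strand frames are scanned on the
#' reverse complement and reported in forward-strand coordinates (1-based,
#' inclusive, stop codon included), so `end - start + 1` is always divisible
#' by 3 and the protein has `(end - start + 1)/3 - 1` residues.
#'
#' @param contig nucleotide string (uppercase A/C/G/T).
#' @param contig_id,genome_id identifiers used to form
#'   `orf_id = genome|contig|start|end|strand`.
#' @param params an [orf_params()] list.
#' @return data frame with columns `orf_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`, `frame`, `protein`, sorted by
#'   (contig, start, end, strand).
#' @export
find_orfs <- function(contig, contig_id = "contig", genome_id = "genome",
                      params = orf_params()) {
  if (!is.character(contig) || length(contig) != 1L || nchar(contig) == 0L) {
    stop("'contig' must be a single non-empty string")
  }
  contig <- toupper(contig)
  if (grepl("[^ACGT]", contig)) {
    stop("ambiguity codes in contig are rejected (clean A/C/G/T input expected)")
  }
  L <- nchar(contig)
  res <- rbind(scan_strand(contig, "+", L, params),
               scan_strand(reverse_complement(contig), "-", L, params))
  if (nrow(res)) {
    res$genome_id <- genome_id
    res$contig_id <- contig_id
    res$orf_id <- paste(genome_id, contig_id, res$start, res$end, res$strand,
                        sep = "|")
    res <- res[order(res$start, res$end, res$strand), ]
    rownames(res) <- NULL
  } else {
    res <- empty_orf_frame()
  }
  res[, c("orf_id", "genome_id", "contig_id", "start", "end", "strand",
          "frame", "protein")]
}

empty_orf_frame <- function() {
  data.frame(orf_id = character(0), genome_id = character(0),
             contig_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), frame = integer(0), protein = character(0),
             stringsAsFactors = FALSE)
}

# One strand of the six-frame scan. `seq` is the scanned strand (already
# reverse-complemented for "-"); coordinates are converted back to the
# forward strand before returning.
scan_strand <- function(seq, strand, L, params) {
  out <- list()
  for (f in 0:2) {
    n_codon <- (L - f) %/% 3L
    if (n_codon < 2L) next
    cod_start <- seq.int(1L + f, by = 3L, length.out = n_codon)
    codons <- substring(seq, cod_start, cod_start + 2L)
    stop_idx <- which(codons %in% STOP_CODONS)
    is_start <- codons %in% params$start_codons
    bounds <- c(0L, stop_idx)
    ends <- c(stop_idx, if (!params$require_stop) n_codon + 1L)
    for (k in seq_along(ends)) {
      lo <- bounds[k] + 1L
      hi <- ends[k] - 1L           # last codon of the protein
      if (hi < lo) next
      cand <- which(is_start[lo:hi])
      if (!length(cand)) next
      i0 <- lo + cand[1L] - 1L
      prot_len <- hi - i0 + 1L
      if (prot_len < params$min_protein_length) next
      has_stop <- ends[k] <= n_codon
      last_cod <- if (has_stop) ends[k] else hi
      s <- 1L + f + 3L * (i0 - 1L)
      e <- 1L + f + 3L * (last_cod - 1L) + 2L
      protein <- paste(unname(Biostrings::GENETIC_CODE[codons[i0:hi]]),
                       collapse = "")
      if (strand == "-") { tmp <- s; s <- L - e + 1L; e <- L - tmp + 1L }
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = e, strand = strand, frame = f, protein = protein,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               frame = integer(0), protein = character(0),
               stringsAsFactors = FALSE)
}

#' Predict ORFs for every contig of a genome FASTA
#'
#' @param path nucleotide FASTA file; sequence names become contig ids.
#' @param genome_id strain identifier; defaults to the file name without
#'   extension.
#' @param params an [orf_params()] list.
#' @return data frame as [find_orfs()], concatenated over contigs.
#' @export
find_orfs_fasta <- function(path, genome_id = NULL, params = orf_params()) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fna|fasta)$", "", basename(path))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) return(empty_orf_frame())
  per_contig <- lapply(seq_along(seqs), function(i) {
    find_orfs(as.character(seqs[[i]]), contig_id = names(seqs)[i],
              genome_id = genome_id, params = params)
  })
  out <- do.call(rbind, per_contig)
  rownames(out) <- NULL
  out
}

#' Write predicted ORFs as protein FASTA and GFF3
#'
#' Protein FASTA records are named by `orf_id`; the GFF3 uses source
#' `pancooc`, type `ORF`, phase 0 and an `ID=` attribute.
#'
#' @param orfs ORF data frame from [find_orfs()] / [find_orfs_fasta()].
#' @param faa_path,gff_path output paths (either may be `NULL` to skip).
#' @return invisibly, a character vector of the files written.
#' @export
write_orfs <- function(orfs, faa_path = NULL, gff_path = NULL) {
  written <- character(0)
  if (!is.null(faa_path)) {
    aa <- Biostrings::AAStringSet(stats::setNames(orfs$protein, orfs$orf_id))
    Biostrings::writeXStringSet(aa, faa_path, width = 70L)
    written <- c(written, faa_path)
  }
  if (!is.null(gff_path)) {
    lines <- c("##gff-version 3",
               sprintf("%s\tpancooc\tORF\t%d\t%d\t.\t%s\t0\tID=%s",
                       orfs$contig_id, orfs$start, orfs$end, orfs$strand,
                       orfs$orf_id))
    writeLines(lines, gff_path)
    written <- c(written, gff_path)
  }
  invisible(written)
}
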