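#' Pipeline configuration
#'
#' Collects every stage parameter in one validated object. Three input
#' modes: `"simulate"` (generate the synthetic dataset internally),
#' `"genomes"` (nucleotide FASTA per strain; ORFs are predicted), and
#' `"proteins"` (pre-predicted protein FASTA per strain; the ORF stage is
#' skipped).
#'
#' @param mode input mode.
#' @param genome_paths,protein_paths named character vector (strain id ->
#'   FASTA path) for the non-simulate modes.
#' @param phenotype_path phenotype TSV (required unless simulating).
#' @param annotation_path optional TSV `cluster_id<TAB>annotation`.
#' @param sim a [sim_config()] for simulate mode.
#' @param orf an [orf_params()].
#' @param scheme a [scoring_scheme()].
#' @param cluster_threshold single-linkage merge distance, default 0.75.
#' @param screen_threshold co-occurrence cutoff, default 0.8.
#' @param screen_mode `"counts"` or `"binary"`.
#' @param absolute screen on absolute value.
#' @param prefilter_k k-mer prefilter length or NULL.
#' @param out_dir output directory.
#' @param seed master seed (simulate mode only source of randomness).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "genomes", "proteins"),
                            genome_paths = NULL, protein_paths = NULL,
                            phenotype_path = NULL, annotation_path = NULL,
                            sim = NULL, orf = orf_params(),
                            scheme = scoring_scheme(),
                            cluster_threshold = 0.75,
                            screen_threshold = 0.8,
                            screen_mode = "counts", absolute = FALSE,
                            prefilter_k = 4L,
                            out_dir = "pancooc_out", seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(sim)) sim <- sim_config(seed = seed)
  if (mode == "genomes") check_paths(genome_paths, "genome_paths")
  if (mode == "proteins") check_paths(protein_paths, "protein_paths")
  if (mode != "simulate" && is.null(phenotype_path)) {
    stop("'phenotype_path' is required unless mode = \"simulate\"")
  }
  structure(list(mode = mode, genome_paths = genome_paths,
                 protein_paths = protein_paths,
                 phenotype_path = phenotype_path,
                 annotation_path = annotation_path,
                 sim = sim, orf = orf, scheme = scheme,
                 cluster_threshold = cluster_threshold,
                 screen_threshold = screen_threshold,
                 screen_mode = screen_mode, absolute = absolute,
                 prefilter_k = prefilter_k,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

check_paths <- function(paths, what) {
  if (is.null(paths) || is.null(names(paths)) || any(names(paths) == "")) {
    stop("'", what, "' must be a named (strain id -> path) vector")
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input files: ", paste(missing, collapse = ", "))
  }
  invisible(paths)
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML mirroring the [pipeline_config()] arguments; nested blocks
#' `sim` (fields of [sim_config()], with `families` as a list of
#' `{family_id, copy_counts, protein_length, role}`), `orf` (fields of
#' [orf_params()]) and `genome_paths`/`protein_paths` as strain -> path maps.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$sim)) {
    s <- raw$sim
    fams <- NULL
    if (!is.null(s$families)) {
      fams <- lapply(s$families, function(f) {
        family_spec(f$family_id, unlist(f$copy_counts),
                    f$protein_length %||% 120L, f$role %||% "planted")
      })
    }
    sim <- sim_config(
      strains = unlist(s$strains) %||% eval(formals(sim_config)$strains),
      phenotype_values = unlist(s$phenotype_values %||% c(10, 9, 9, 5, 4, 3)),
      families = fams,
      n_background = s$n_background %||% 30L,
      substitution_rate = s$substitution_rate %||% 0.05,
      protein_length = s$protein_length %||% 120L,
      spacer_length = s$spacer_length %||% 60L,
      seed = s$seed %||% raw$seed %||% 1L)
  }
  orf <- orf_params(
    min_protein_length = raw$orf$min_protein_length %||% 100L,
    start_codons = unlist(raw$orf$start_codons %||% "ATG"),
    require_stop = raw$orf$require_stop %||% TRUE)
  pipeline_config(
    mode = raw$mode %||% "simulate",
    genome_paths = if (!is.null(raw$genome_paths)) unlist(raw$genome_paths),
    protein_paths = if (!is.null(raw$protein_paths)) unlist(raw$protein_paths),
    phenotype_path = raw$phenotype_path,
    annotation_path = raw$annotation_path,
    sim = sim, orf = orf,
    cluster_threshold = raw$cluster_threshold %||% 0.75,
    screen_threshold = raw$screen_threshold %||% 0.8,
    screen_mode = raw$screen_mode %||% "counts",
    absolute = raw$absolute %||% FALSE,
    prefilter_k = raw$prefilter_k %||% 4L,
    out_dir = raw$out_dir %||% "pancooc_out",
    seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full co-occurrence screen end-to-end
#'
#' simulate? -> find ORFs -> cluster -> pan-matrix -> screen -> annotate.
#' Every intermediate artifact is written under `config$out_dir` with the
#' documented file contracts, plus a `manifest.json` recording parameters,
#' seed, input checksums and per-stage record counts. Re-running with an
#' identical config reproduces identical result files byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (which go to standard error).
#' @return invisibly, a list with the in-memory stage results
#'   (`dataset`, `orfs`, `assignment`, `pan`, `screen`, `results`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must come from pipeline_config() or read_pipeline_config()")
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pancooc] ", sprintf(...))
  stage_counts <- list()

  dataset <- NULL
  if (config$mode == "simulate") {
    say("simulate: %d strains, %d families, seed %d",
        length(config$sim$strains), length(config$sim$families), config$sim$seed)
    dataset <- generate_dataset(config$sim)
    sim_dir <- file.path(out, "simulated")
    write_dataset(dataset, sim_dir)
    phenotype <- dataset$phenotype
    genome_paths <- stats::setNames(
      file.path(sim_dir, paste0(names(dataset$genomes), ".fna")),
      names(dataset$genomes))
    stage_counts$embedded_genes <- nrow(dataset$genes)
  } else {
    phenotype <- read_phenotype(config$phenotype_path)
    genome_paths <- config$genome_paths
  }

  if (config$mode == "proteins") {
    orfs <- do.call(rbind, lapply(names(config$protein_paths), function(strain) {
      aa <- Biostrings::readAAStringSet(config$protein_paths[[strain]])
      data.frame(orf_id = names(aa), genome_id = strain, contig_id = NA,
                 start = NA, end = NA, strand = NA, frame = NA,
                 protein = as.character(aa), stringsAsFactors = FALSE)
    }))
  } else {
    orf_dir <- file.path(out, "orfs")
    dir.create(orf_dir, showWarnings = FALSE)
    orfs <- do.call(rbind, lapply(names(genome_paths), function(strain) {
      o <- find_orfs_fasta(genome_paths[[strain]], genome_id = strain,
                           params = config$orf)
      write_orfs(o, file.path(orf_dir, paste0(strain, ".faa")),
                 file.path(orf_dir, paste0(strain, ".gff3")))
      o
    }))
    say("findorfs: %d ORFs across %d genomes", nrow(orfs), length(genome_paths))
  }
  if (!nrow(orfs)) stop("stage findorfs: no ORFs predicted from the input genomes")
  stage_counts$orfs <- nrow(orfs)
  if (anyDuplicated(orfs$orf_id)) stop("stage findorfs: duplicate ORF ids")

  proteins <- stats::setNames(orfs$protein, orfs$orf_id)
  D <- build_distance_matrix(proteins, config$scheme,
                             prefilter_k = config$prefilter_k)
  assignment <- single_linkage_cluster(D, config$cluster_threshold)
  write_clusters(assignment, file.path(out, "clusters.tsv"))
  stage_counts$clusters <- length(unique(assignment$cluster_id))
  say("cluster: %d gene families from %d proteins at threshold %g",
      stage_counts$clusters, nrow(orfs), config$cluster_threshold)

  orf_to_genome <- stats::setNames(orfs$genome_id, orfs$orf_id)
  pan <- build_pan_matrix(assignment, orf_to_genome, phenotype)
  write_pan_matrix(pan, file.path(out, "panmatrix.tsv"))

  scr <- screen_cooccurrence(pan, phenotype,
                             threshold = config$screen_threshold,
                             mode = config$screen_mode,
                             absolute = config$absolute)
  annotations <- if (!is.null(config$annotation_path)) {
    utils::read.delim(config$annotation_path, header = TRUE,
                      stringsAsFactors = FALSE)
  } else character(0)
  results <- join_annotations(scr$pass, annotations)
  say("screen: %d/%d families with co-occurrence > %g",
      nrow(results), nrow(scr$all), config$screen_threshold)
  stage_counts$passing <- nrow(results)
  stage_counts$undefined <- nrow(scr$undefined)

  res_out <- data.frame(cluster_id = results$cluster_id,
                        cooccurrence = format_2dp(results$value_2dp),
                        n_members = results$n_members,
                        annotation = results$annotation,
                        stringsAsFactors = FALSE)
  utils::write.table(res_out, file.path(out, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scr$undefined[, c("cluster_id", "n_members")],
                     file.path(out, "undefined.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "pancooc",
    version = as.character(utils::packageVersion("pancooc")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = config$mode,
    seed = config$seed,
    parameters = list(
      min_protein_length = config$orf$min_protein_length,
      start_codons = config$orf$start_codons,
      require_stop = config$orf$require_stop,
      gap_open = config$scheme$gap_open,
      gap_extend = config$scheme$gap_extend,
      cluster_threshold = config$cluster_threshold,
      screen_threshold = config$screen_threshold,
      screen_mode = config$screen_mode,
      absolute = config$absolute,
      prefilter_k = config$prefilter_k),
    inputs = as.list(tools::md5sum(unname(
      if (config$mode == "proteins") config$protein_paths else genome_paths))),
    stage_counts = stage_counts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dataset = dataset, orfs = orfs, assignment = assignment,
                 pan = pan, screen = scr, results = results,
                 manifest = manifest))
}

format_2dp <- function(x) formatC(x, format = "f", digits = 2L)
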