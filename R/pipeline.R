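#' Pipeline configuration
#'
#' Assembles and validates the full analysis configuration. Inputs are
#' either a simulation (a [simulation_config()] to generate reads from) or a
#' read file (FASTA/FASTQ/aligned-FASTA with `round=`/`passes=` header
#' metadata) plus a host reference.
#'
#' @param output_dir Directory for all outputs.
#' @param simulation Optional [simulation_config()]; when given, reads and
#'   references are simulated.
#' @param reads_path,reads_format Optional input read file and its format.
#' @param reference_path Host reference FASTA (required with `reads_path`).
#' @param deletion_windows Parasite deletion windows (used to derive class
#'   references when reading external data).
#' @param length_bins Length bins ([default_length_bins()]).
#' @param min_passes_by_class Pass-count thresholds (see
#'   [filter_by_passes()]).
#' @param dominance_threshold Dominant-mutation threshold (strictly between
#'   0 and 1).
#' @param top_n Genotypes kept per (round, class).
#' @param scoring Aligner scoring ([alignment_scoring()]).
#' @param coord_scaling PCoA coordinate scaling (see [pcoa_embed()]).
#' @param seed Integer seed for all stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            simulation = NULL,
                            reads_path = NULL,
                            reads_format = "fasta",
                            reference_path = NULL,
                            deletion_windows = NULL,
                            length_bins = default_length_bins(),
                            min_passes_by_class = c(
                              "host" = 5L, "parasite-alpha" = 10L,
                              "parasite-beta" = 10L, "parasite-gamma" = 10L),
                            dominance_threshold = 0.10,
                            top_n = 90L,
                            scoring = alignment_scoring(),
                            coord_scaling = "sqrt",
                            seed = 1L) {
  cfg <- list(output_dir = output_dir, simulation = simulation,
              reads_path = reads_path, reads_format = reads_format,
              reference_path = reference_path,
              deletion_windows = deletion_windows,
              length_bins = length_bins,
              min_passes_by_class = min_passes_by_class,
              dominance_threshold = dominance_threshold,
              top_n = as.integer(top_n), scoring = scoring,
              coord_scaling = coord_scaling, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.numeric(cfg$dominance_threshold) ||
      cfg$dominance_threshold <= 0 || cfg$dominance_threshold >= 1)
    stop("dominance_threshold must lie strictly between 0 and 1")
  if (!is_count(cfg$top_n)) stop("top_n must be a positive integer")
  validate_length_bins(cfg$length_bins)
  if (any(cfg$min_passes_by_class < 0)) stop("pass thresholds must be >= 0")
  if (!cfg$coord_scaling %in% c("sqrt", "eigenvalue"))
    stop("coord_scaling must be 'sqrt' or 'eigenvalue'")
  if (is.null(cfg$simulation)) {
    if (is.null(cfg$reads_path) || is.null(cfg$reference_path))
      stop("either a simulation config or reads_path + reference_path is required")
  } else {
    validate_simulation_config(cfg$simulation)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly to [pipeline_config()] arguments; the
#' `simulation` block maps to [simulation_config()], `scoring` to
#' [alignment_scoring()], and `deletion_windows` to a named list of
#' `[start, end]` pairs.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    if (!is.null(raw$simulation$deletion_windows))
      raw$simulation$deletion_windows <-
        lapply(raw$simulation$deletion_windows, function(w) as.integer(unlist(w)))
    raw$simulation <- do.call(simulation_config, raw$simulation)
  }
  if (!is.null(raw$scoring)) raw$scoring <- do.call(alignment_scoring, raw$scoring)
  if (!is.null(raw$deletion_windows))
    raw$deletion_windows <- lapply(raw$deletion_windows, function(w) as.integer(unlist(w)))
  if (!is.null(raw$length_bins)) raw$length_bins <- as.data.frame(raw$length_bins)
  if (!is.null(raw$min_passes_by_class))
    raw$min_passes_by_class <- unlist(raw$min_passes_by_class)
  do.call(pipeline_config, raw)
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[coevotrace:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation (or read loading), length classification,
#' pass-count filtering, alignment and mutation calling, dominant-mutation
#' identification, genotype projection, distance matrix / PCoA embedding /
#' edge construction, and lineage reports. Every stage's output is written
#' as TSV into `config$output_dir`, and a JSON manifest records the seed,
#' config hash, package version, and row counts of every output. The
#' manifest is written even when a stage fails (with the failing stage
#' recorded), and identical configs and seeds yield byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list. Side effects: TSV/JSON files in
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "coevotrace",
    version = as.character(utils::packageVersion("coevotrace")),
    seed = config$seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = list(), status = "running", failed_stage = NULL)
  manifest_path <- file.path(config$output_dir, "manifest.json")
  cfg_path <- file.path(config$output_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))

  emit <- function(name, df) {
    path <- file.path(config$output_dir, paste0(name, ".tsv"))
    write_tsv(as.data.frame(df), path)
    manifest$outputs[[name]] <<- list(file = basename(path), rows = nrow(df))
    df
  }
  finish <- function(status, stage = NULL) {
    manifest$status <<- status
    manifest$failed_stage <<- stage
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  }
  stage <- "setup"
  res <- tryCatch({
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(config$seed)

    if (!is.null(config$simulation)) {
      stage <- "simulate"
      sim_cfg <- config$simulation
      if (is.null(sim_cfg$reads_per_round)) sim_cfg$reads_per_round <- 500L
      sim <- simulate_serial_transfer(sim_cfg)
      refs <- sim$refs
      reads <- sim$reads
      pipeline_log(stage, "%d rounds, %d reads", sim_cfg$n_rounds, nrow(reads))
      write_simulation_truth(sim$truth, config$output_dir)
      emit("reads_raw", reads[c("id", "round", "class_label", "mol", "passes")])
      aligned_ref <- NULL
    } else {
      stage <- "load"
      reads <- read_sequences(config$reads_path, config$reads_format)
      host <- read_sequences(config$reference_path, "fasta")
      windows <- config$deletion_windows %||% default_deletion_windows(nchar(gsub("-", "", host$sequence[1])))
      aligned_ref <- if (grepl("-", host$sequence[1], fixed = TRUE)) host$sequence[1] else NULL
      refs <- reference_set(gsub("-", "", host$sequence[1]), windows)
      pipeline_log(stage, "%d reads from %s", nrow(reads), config$reads_path)
    }

    stage <- "classify"
    reads <- classify_by_length(reads, config$length_bins)
    pipeline_log(stage, "%d reads classified (%d unclassified)",
                 nrow(reads), sum(reads$class_label == "unclassified"))

    stage <- "filter"
    reads <- filter_by_passes(reads, config$min_passes_by_class)
    pipeline_log(stage, "%d reads retained after pass filtering", nrow(reads))

    stage <- "call"
    freq <- build_frequency_table(reads, refs, config$scoring, aligned_ref)
    emit("mutation_frequencies", freq)
    pipeline_log(stage, "%d frequency rows", nrow(freq))

    stage <- "dominant"
    dom <- identify_dominant(freq, config$dominance_threshold)
    emit("dominant_mutations", dom$mutations)
    pipeline_log(stage, "%d dominant mutations in %d sites",
                 nrow(dom$mutations), length(dom$sites))

    stage <- "genotypes"
    geno <- project_genotypes(reads, refs, dom, config$top_n,
                              config$scoring, aligned_ref)
    emit("genotypes", geno)
    pipeline_log(stage, "%d genotypes", nrow(geno))

    stage <- "map"
    if (nrow(geno) > 0L) {
      dm <- build_distance_matrix(geno)
      emb <- pcoa_embed(dm, config$coord_scaling)
      coords <- data.frame(genotype_id = geno$genotype_id,
                           class_label = geno$class_label,
                           round = geno$round, rank = geno$rank,
                           frequency = geno$frequency,
                           x = emb$coordinates[, 1], y = emb$coordinates[, 2],
                           stringsAsFactors = FALSE)
      emit("coordinates", coords)
      edges <- build_edges(dm)
      emit("edges", edges)
      pipeline_log(stage, "%d within-class + %d cross-class edges",
                   sum(edges$type == "within"), sum(edges$type == "cross"))
    } else {
      edges <- emit("edges", build_edges(
        build_distance_matrix(data.frame(vector = "", class_label = "host",
                                         stringsAsFactors = FALSE))))
      emit("coordinates", data.frame())
    }

    stage <- "lineage"
    parasite_classes <- intersect(names(refs$windows), unique(reads$class_label))
    uniq <- lapply(stats::setNames(parasite_classes, parasite_classes),
                   function(cls) find_unique_mutations(freq, dom, refs, cls))
    for (cls in parasite_classes)
      emit(paste0("unique_mutations_", gsub("[^a-z]+", "_", cls)), uniq[[cls]])
    origins <- if (nrow(geno)) match_parasite_origin(geno) else
      match_parasite_origin(data.frame(vector = character(),
                                       class_label = character(),
                                       round = integer(),
                                       genotype_id = character()))
    emit("origin_candidates", origins)
    writeLines(lineage_summary(uniq, origins),
               file.path(config$output_dir, "lineage_summary.txt"))
    pipeline_log(stage, "%d origin candidate pairs", nrow(origins))

    finish("ok")
    manifest
  }, error = function(e) {
    finish("failed", stage)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# a YAML-serializable view of the config (drives the config hash)
serialize_config <- function(cfg) {
  s <- cfg
  class(s) <- NULL
  if (!is.null(s$simulation)) s$simulation <- unclass(s$simulation)
  s$scoring <- unclass(s$scoring)
  s$length_bins <- as.list(s$length_bins)
  s$min_passes_by_class <- as.list(s$min_passes_by_class)
  s
}
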