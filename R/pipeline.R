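#' Assemble a full pipeline configuration
#'
#' Nested configuration for one end-to-end run: cohort generation,
#' featurization, training, decimation, composite construction, and transfer
#' evaluation. A single global seed deterministically derives every stage's
#' seed. The object is plain-list-backed and round-trips through YAML via
#' [read_pipeline_config()].
#'
#' @param cohort A [cohort_spec()] for the training cohort.
#' @param transfer_cohort A [cohort_spec()] for the transfer cohort
#'   (typically 5 + 5 participants).
#' @param connectivity A [connectivity_config()].
#' @param training A [training_config()].
#' @param composite A [composite_config()].
#' @param transfer A [transfer_config()].
#' @param n_families Number of model families.
#' @param stop_fraction Decimation stopping threshold (fraction of the full
#'   feature set).
#' @param seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            transfer_cohort = cohort_spec(n_per_group = 5),
                            connectivity = connectivity_config(),
                            training = training_config(),
                            composite = composite_config(),
                            transfer = transfer_config(),
                            n_families = 20L,
                            stop_fraction = 0.05,
                            seed = 1L) {
  stopifnot(n_families >= 1, stop_fraction > 0, stop_fraction < 1)
  cohort$seed <- derive_seed(seed, "simulate")
  transfer_cohort$seed <- derive_seed(seed, "simulate-transfer")
  training$seed <- derive_seed(seed, "train")
  structure(list(cohort = cohort, transfer_cohort = transfer_cohort,
                 connectivity = connectivity, training = training,
                 composite = composite, transfer = transfer,
                 n_families = as.integer(n_families),
                 stop_fraction = stop_fraction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' A small configuration for smoke-testing the full pipeline
#'
#' 20 ROIs, 4 + 4 training participants, 2 families with an early stopping
#' threshold, and a light training budget, so an end-to-end run completes in
#' well under two minutes.
#'
#' @param seed Global seed.
#' @return A `pipeline_config`.
#' @export
smoke_pipeline_config <- function(seed = 1L) {
  pipeline_config(
    cohort = cohort_spec(n_per_group = 4, n_roi = 20, runs_per_condition = 2,
                         volumes_per_run = 120, n_group_edges = 8,
                         n_condition_edges = 8),
    transfer_cohort = cohort_spec(n_per_group = 3, n_roi = 20,
                                  runs_per_condition = 2,
                                  volumes_per_run = 120, n_group_edges = 8,
                                  n_condition_edges = 8),
    training = training_config(max_epochs = 24, patience = 8, k_folds = 3),
    composite = composite_config(min_family_count = 1L,
                                 composite_k_folds = 3L),
    transfer = transfer_config(n_sets = 1L, partitions_per_set = 1L),
    n_families = 2L,
    stop_fraction = 0.5,
    seed = seed)
}

#' Read a pipeline configuration from a YAML file
#'
#' Any subset of the sections (`cohort`, `transfer_cohort`, `connectivity`,
#' `training`, `composite`, `transfer`, `n_families`, `stop_fraction`,
#' `seed`) may be given; missing fields take the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, section) do.call(ctor, y[[section]] %||% list())
  pipeline_config(
    cohort = build(cohort_spec, "cohort"),
    transfer_cohort = if (is.null(y$transfer_cohort))
      cohort_spec(n_per_group = 5) else build(cohort_spec, "transfer_cohort"),
    connectivity = build(connectivity_config, "connectivity"),
    training = build(training_config, "training"),
    composite = build(composite_config, "composite"),
    transfer = build(transfer_config, "transfer"),
    n_families = y$n_families %||% 20L,
    stop_fraction = y$stop_fraction %||% 0.05,
    seed = y$seed %||% 1L)
}

#' Run the full fingerprinting pipeline end to end
#'
#' Simulate -> featurize -> model families (decimation) -> composite model
#' and class networks -> transfer evaluation, with one JSON report
#' aggregating every stage's metrics, seeds and artifact paths.
#'
#' @param config A [pipeline_config()].
#' @param out Output directory (artifacts and `report.json`); NULL keeps
#'   everything in memory.
#' @param force Overwrite a non-empty output directory.
#' @param verbose Log stage progress to stderr.
#' @return A list of class `pipeline_report` with `cohort`, `patterns`,
#'   `families`, `composite`, `relevant_edges`, `adjacency`, `transfer`, and
#'   `report` (the serializable summary).
#' @export
run_end_to_end <- function(config, out = NULL, force = FALSE,
                           verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[fcfingerprint] ", ...)
  t0 <- proc.time()[["elapsed"]]
  stage_time <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stage_time[[name]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  if (!is.null(out)) {
    if (dir.exists(out) && length(list.files(out)) > 0 && !force)
      stop_input("output directory is not empty; use force = TRUE")
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
  }

  say("simulating cohorts")
  cohort <- generate_cohort(config$cohort)
  transfer_cohort <- generate_transfer_cohort(config$transfer_cohort,
                                              cohort$truth)
  tick("simulate")

  say("featurizing runs")
  patterns <- build_pattern_set(cohort, config$connectivity)
  transfer_patterns <- build_pattern_set(
    transfer_cohort, config$connectivity,
    map = feature_index_map(config$cohort$n_roi,
                            config$cohort$cluster_assignment))
  tick("featurize")

  say("running ", config$n_families, " model families")
  families <- run_families(patterns, config$n_families, config$training,
                           stop_fraction = config$stop_fraction)
  tick("families")

  say("building composite model")
  counts <- feature_frequencies(families, patterns$map)
  composite_set <- select_composite(counts, patterns$map, config$composite)
  composite <- train_composite(patterns, composite_set, config$training,
                               config$composite)
  edges <- flag_highly_relevant(composite, config$composite)
  adjacency <- build_class_adjacency(edges, patterns)
  tick("composite")

  say("transfer evaluation")
  transfer <- run_transfer(patterns, transfer_patterns, config$transfer,
                           config$training)
  tick("transfer")

  fam_first <- family_metric_table(families, "first")
  fam_final <- family_metric_table(families, "final")
  report <- list(
    schema = "fcfingerprint/report/1",
    seed = config$seed,
    stage_seconds = stage_time,
    n_patterns = nrow(patterns$features),
    n_features = ncol(patterns$features),
    generations_per_family =
      vapply(families, `[[`, 0L, "n_generations"),
    first_generation = if (nrow(fam_first) >= 2)
      summarize_families(fam_first)$summary else fam_first,
    final_generation = if (nrow(fam_final) >= 2)
      summarize_families(fam_final)$summary else fam_final,
    composite_metrics = composite$metrics,
    n_composite_features = length(composite_set),
    n_relevant_edges = if (is.null(edges)) 0L else nrow(edges),
    transfer_group_metrics = transfer$group_metrics,
    transfer_profile = transfer$profile[c("pooled", "unanimous")])

  artifacts <- list()
  if (!is.null(out)) {
    write_cohort(cohort, file.path(out, "cohort"), force = force)
    write_cohort(transfer_cohort, file.path(out, "transfer_cohort"),
                 force = force)
    write_pattern_set(patterns, file.path(out, "patterns"), force = force)
    utils::write.table(
      data.frame(feature = patterns$map$feature, i = patterns$map$i,
                 j = patterns$map$j, count = counts),
      file.path(out, "feature_frequencies.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
    if (!is.null(edges))
      utils::write.table(adjacency$edges, file.path(out, "relevant_edges.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    for (cl in c("poor", "skilled", "pseudoword", "word"))
      utils::write.table(adjacency[[cl]],
                         file.path(out, paste0("adjacency_", cl, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    artifacts <- list(
      cohort = file.path(out, "cohort"),
      transfer_cohort = file.path(out, "transfer_cohort"),
      patterns = file.path(out, "patterns"),
      feature_frequencies = file.path(out, "feature_frequencies.tsv"),
      report = file.path(out, "report.json"))
    report$artifacts <- artifacts
  }
  structure(list(cohort = cohort, transfer_cohort = transfer_cohort,
                 patterns = patterns, transfer_patterns = transfer_patterns,
                 families = families, composite = composite,
                 relevant_edges = edges, adjacency = adjacency,
                 transfer = transfer, report = report),
            class = "pipeline_report")
}
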