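#' Write a cohort to disk as run TSVs plus a JSON sidecar
#'
#' One tab-separated file per run (header = ROI names, rows = volumes),
#' nuisance regressors in a parallel `*_nuisance.tsv`, and one
#' `cohort.json` sidecar holding labels, the spec echo, the seed and the
#' ground-truth edge lists.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if missing).
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop_input("output directory is not empty; use force = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roi_names <- sprintf("roi_%03d", seq_len(cohort$spec$n_roi))
  meta <- list()
  for (k in seq_along(cohort$runs)) {
    run <- cohort$runs[[k]]
    stem <- sprintf("%s_cond-%s_run-%02d", run$participant_id,
                    run$condition_label, run$run_index)
    values <- as.data.frame(run$values)
    names(values) <- roi_names
    utils::write.table(values, file.path(dir, paste0(stem, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    nuis <- as.data.frame(run$nuisance)
    names(nuis) <- paste0("nuisance_", seq_len(ncol(nuis)))
    utils::write.table(nuis, file.path(dir, paste0(stem, "_nuisance.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    meta[[k]] <- list(file = paste0(stem, ".tsv"),
                      nuisance_file = paste0(stem, "_nuisance.tsv"),
                      participant_id = run$participant_id,
                      group_label = run$group_label,
                      condition_label = as.character(run$condition_label),
                      run_index = run$run_index,
                      timepoint = run$timepoint)
  }
  truth <- cohort$truth
  sidecar <- list(
    schema = "fcfingerprint/cohort/1",
    spec = unclass(cohort$spec),
    runs = meta,
    truth = list(group_edges = unname(truth$group_edges),
                 condition_edges = unname(truth$condition_edges),
                 transfer_edges = unname(truth$transfer_edges),
                 delta_group = truth$delta_group,
                 delta_condition = truth$delta_condition,
                 delta_transfer = truth$delta_transfer,
                 group_feature_idx = truth$group_feature_idx,
                 condition_feature_idx = truth$condition_feature_idx))
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' The base correlation matrix is not serialized; the returned truth carries
#' the edge lists and deltas needed for recovery scoring.
#'
#' @param dir Directory containing `cohort.json`.
#' @return A `cohort` (its `truth$base` is NULL).
#' @export
read_cohort <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                 simplifyVector = TRUE)
  if (!identical(sidecar$schema, "fcfingerprint/cohort/1"))
    stop_input("unsupported cohort schema: ", sidecar$schema %||% "<missing>")
  spec <- sidecar$spec
  spec$cluster_assignment <- as.integer(spec$cluster_assignment)
  class(spec) <- "cohort_spec"
  runs_meta <- sidecar$runs
  runs <- lapply(seq_len(nrow(runs_meta)), function(k) {
    rm_ <- runs_meta[k, ]
    values <- as.matrix(utils::read.table(file.path(dir, rm_$file),
                                          header = TRUE, sep = "\t"))
    nuis <- as.matrix(utils::read.table(file.path(dir, rm_$nuisance_file),
                                        header = TRUE, sep = "\t"))
    cond <- rm_$condition_label
    if (cond %in% c("0", "1")) cond <- as.integer(cond)
    structure(list(values = unname(values),
                   participant_id = rm_$participant_id,
                   group_label = rm_$group_label,
                   condition_label = cond,
                   run_index = rm_$run_index,
                   timepoint = rm_$timepoint,
                   nuisance = unname(nuis)), class = "roi_run")
  })
  tr <- sidecar$truth
  as_edges <- function(x) if (is.null(x) || length(x) == 0) {
    matrix(integer(0), 0, 2)
  } else matrix(as.integer(unlist(x)), ncol = 2,
                dimnames = list(NULL, c("i", "j")))
  truth <- structure(list(group_edges = as_edges(tr$group_edges),
                          condition_edges = as_edges(tr$condition_edges),
                          transfer_edges = if (is.null(tr$transfer_edges))
                            NULL else as_edges(tr$transfer_edges),
                          delta_group = tr$delta_group,
                          delta_condition = tr$delta_condition,
                          delta_transfer = tr$delta_transfer,
                          base = NULL,
                          group_feature_idx = as.integer(tr$group_feature_idx),
                          condition_feature_idx =
                            as.integer(tr$condition_feature_idx)),
                     class = "ground_truth")
  structure(list(runs = runs, truth = truth, spec = spec), class = "cohort")
}

#' Save a pattern set as TSV + JSON manifest
#'
#' @param set A `pattern_set`.
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_pattern_set <- function(set, dir, force = FALSE) {
  stopifnot(inherits(set, "pattern_set"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop_input("output directory is not empty; use force = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(set$features, file.path(dir, "features.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(set$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(set$map), file.path(dir, "map.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(schema = "fcfingerprint/patterns/1",
                            config = unclass(set$config),
                            n_patterns = nrow(set$features),
                            n_features = ncol(set$features)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a pattern set written by [write_pattern_set()]
#' @param dir Directory containing `manifest.json`.
#' @return A `pattern_set`.
#' @export
read_pattern_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$schema, "fcfingerprint/patterns/1"))
    stop_input("unsupported pattern-set schema: ", man$schema %||% "<missing>")
  features <- as.matrix(utils::read.table(file.path(dir, "features.tsv"),
                                          sep = "\t"))
  dimnames(features) <- NULL
  meta <- utils::read.table(file.path(dir, "meta.tsv"), header = TRUE,
                            sep = "\t", colClasses = c(
                              lexicality_label = "character"))
  map <- utils::read.table(file.path(dir, "map.tsv"), header = TRUE,
                           sep = "\t")
  class(map) <- c("feature_index_map", "data.frame")
  config <- man$config
  class(config) <- "connectivity_config"
  structure(list(features = features, meta = meta, map = map,
                 config = config), class = "pattern_set")
}

#' Save a trained model as a JSON container
#'
#' All dense weights, biases and batch-normalization state are written in
#' full double precision, with the architecture echo and seed.
#'
#' @param model A `trained_model`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  payload <- list(schema = "fcfingerprint/model/1",
                  spec = unclass(model$spec),
                  seed = model$seed,
                  trained = isTRUE(model$trained),
                  bn_eps = model$bn_eps %||% 1e-3,
                  layers = model$layers,
                  head_group = model$head_group,
                  head_lex = model$head_lex)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model written by [write_model()]
#' @param path Path to the `.json` container.
#' @return A `trained_model`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$schema, "fcfingerprint/model/1"))
    stop_input("unsupported model schema: ", payload$schema %||% "<missing>")
  spec <- payload$spec
  spec$hidden_sizes <- as.integer(spec$hidden_sizes)
  class(spec) <- "architecture_spec"
  layers <- lapply(payload$layers, function(s) {
    w <- s$W
    storage.mode(w) <- "double"
    list(W = w, b = as.numeric(s$b), gamma = as.numeric(s$gamma),
         beta = as.numeric(s$beta), rmean = as.numeric(s$rmean),
         rvar = as.numeric(s$rvar))
  })
  structure(list(layers = layers,
                 head_group = list(w = as.numeric(payload$head_group$w),
                                   b = as.numeric(payload$head_group$b)),
                 head_lex = list(w = as.numeric(payload$head_lex$w),
                                 b = as.numeric(payload$head_lex$b)),
                 spec = spec, seed = payload$seed,
                 trained = payload$trained, bn_eps = payload$bn_eps),
            class = "trained_model")
}
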