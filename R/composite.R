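#' Composite-model configuration
#'
#' @param min_family_count Minimum number of family final sets a feature must
#'   appear in to enter the composite model (default 4 of 20).
#' @param composite_k_folds Cross-validation folds for the composite model
#'   (default 10).
#' @param z_threshold Normalized attribution magnitude above which a
#'   composite feature counts as highly relevant (default 1).
#' @return An object of class `composite_config`.
#' @export
composite_config <- function(min_family_count = 4L, composite_k_folds = 10L,
                             z_threshold = 1.0) {
  stopifnot(min_family_count >= 1, composite_k_folds >= 2, z_threshold > 0)
  structure(list(min_family_count = as.integer(min_family_count),
                 composite_k_folds = as.integer(composite_k_folds),
                 z_threshold = z_threshold),
            class = "composite_config")
}

#' Count how often each feature survived to a family's final generation
#'
#' @param families List of `family_result`s.
#' @param map The full [feature_index_map()] the families were run against
#'   (the masked map of the pattern set is accepted).
#' @return Integer vector over `map$feature`: in how many families' final
#'   sets each feature appears (0 .. number of families).
#' @export
feature_frequencies <- function(families, map) {
  stopifnot(length(families) >= 1)
  counts <- integer(nrow(map))
  names(counts) <- map$feature
  for (fam in families) {
    if (!all(fam$final_features %in% map$feature))
      stop_input("family final features not present in the supplied map")
    pos <- match(fam$final_features, map$feature)
    counts[pos] <- counts[pos] + 1L
  }
  counts
}

#' Select the composite feature set
#'
#' Features retained by at least `min_family_count` independent families'
#' final generations, in ascending feature-index order.
#'
#' @param counts Output of [feature_frequencies()].
#' @param map The matching feature map.
#' @param config A [composite_config()].
#' @return Integer vector of selected feature indices.
#' @export
select_composite <- function(counts, map, config = composite_config()) {
  sel <- map$feature[counts >= config$min_family_count]
  if (length(sel) == 0)
    stop_input("no feature reached ", config$min_family_count,
               " families; lower min_family_count")
  sort(sel)
}

#' Choose the family-count threshold that yields a target composite size
#'
#' The reliability threshold is meaningful because it pins the composite set
#' to roughly the top 5% of the full feature set; this helper returns the
#' smallest count whose selection is no larger than `target_fraction` of the
#' full set (falling back to the largest attainable count).
#'
#' @param counts Output of [feature_frequencies()].
#' @param n_full Full pre-mask feature count.
#' @param target_fraction Target composite size as a fraction of `n_full`.
#' @return Integer threshold.
#' @export
tune_min_family_count <- function(counts, n_full, target_fraction = 0.05) {
  for (k in seq_len(max(counts))) {
    if (sum(counts >= k) <= target_fraction * n_full) return(k)
  }
  max(counts)
}

#' Train and evaluate the composite model
#'
#' Cross-validates the dual-head classifier on the composite feature set
#' (architecture re-derived from the composite width) and aggregates the
#' per-fold signed path weights needed for relevance flagging.
#'
#' @param set The masked `pattern_set`.
#' @param composite_features Integer feature indices from
#'   [select_composite()].
#' @param config A [training_config()]; its `k_folds` is overridden by
#'   `composite_config$composite_k_folds`.
#' @param composite_cfg A [composite_config()].
#' @return A `composite_result`: list with `features`, `metrics` (per head),
#'   `fold_results`, `signed_scores` (mean signed path weight across folds),
#'   `models`, `map` (composite rows of the feature map).
#' @export
train_composite <- function(set, composite_features,
                            config = training_config(),
                            composite_cfg = composite_config()) {
  stopifnot(length(composite_features) >= 2)
  cfg <- config
  cfg$k_folds <- composite_cfg$composite_k_folds
  cfg$seed <- derive_seed(config$seed, "composite")
  sub <- subset_patterns(set, feature_idx = composite_features)
  spec <- architecture_spec(length(composite_features))
  cv <- cross_validate(sub, cfg, spec)
  signed <- matrix(0, length(composite_features), 2,
                   dimnames = list(NULL, c("group", "lex")))
  for (m in cv$models) signed <- signed + summed_path_weights(m)
  signed <- signed / length(cv$models)
  structure(list(features = composite_features,
                 metrics = cv$metrics,
                 fold_results = cv$fold_results,
                 signed_scores = signed,
                 models = cv$models,
                 map = sub$map),
            class = "composite_result")
}

#' Flag highly-relevant composite connections
#'
#' Per head, the mean signed path weight across composite folds is z-scored
#' across features; features with `|Z|` above the threshold are flagged. The
#' sign assigns the predicted class: negative scores predict pseudoword /
#' poor reader, positive scores word / highly-skilled reader.
#'
#' @param composite A `composite_result`.
#' @param config A [composite_config()].
#' @return A data.frame of relevant edges: `feature`, `i`, `j`, `head`,
#'   `mean_weight`, `z`, `predicted_class`.
#' @export
flag_highly_relevant <- function(composite, config = composite_config()) {
  stopifnot(inherits(composite, "composite_result"))
  out <- list()
  class_names <- list(group = c("poor", "skilled"),
                      lex = c("pseudoword", "word"))
  for (head in c("group", "lex")) {
    s <- composite$signed_scores[, head]
    if (sd(s) == 0) stop_input("zero variance of ", head, " path weights")
    z <- (s - mean(s)) / sd(s)
    hit <- abs(z) > config$z_threshold
    if (!any(hit)) next
    out[[head]] <- data.frame(
      feature = composite$features[hit],
      i = composite$map$i[hit],
      j = composite$map$j[hit],
      head = head,
      mean_weight = s[hit],
      z = z[hit],
      predicted_class = class_names[[head]][(s[hit] > 0) + 1L],
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  rownames(edges) <- NULL
  edges
}

#' Build per-class adjacency matrices from the highly-relevant edges
#'
#' For every flagged edge, the cell (and its mirror) of the predicted class's
#' adjacency matrix receives the mean normalized connectivity of that edge
#' over all patterns belonging to the predicted class; all other cells are
#' zero. Node strength (row sums) is attached for visualization export.
#'
#' @param edges Data.frame from [flag_highly_relevant()].
#' @param set The `pattern_set` supplying connectivity values and labels.
#' @return A list of class `class_adjacency`: adjacency matrices `poor`,
#'   `skilled`, `pseudoword`, `word`, a `node_strength` matrix (ROI x class),
#'   and the augmented `edges` table with `mean_connectivity`.
#' @export
build_class_adjacency <- function(edges, set) {
  stopifnot(inherits(set, "pattern_set"))
  n_roi <- max(set$map$j)
  classes <- c("poor", "skilled", "pseudoword", "word")
  mats <- lapply(classes, function(cl) matrix(0, n_roi, n_roi))
  names(mats) <- classes
  class_rows <- list(
    poor = set$meta$group_label == 0,
    skilled = set$meta$group_label == 1,
    pseudoword = set$meta$lexicality_label == "0",
    word = set$meta$lexicality_label == "1")
  edges$mean_connectivity <- NA_real_
  for (k in seq_len(nrow(edges))) {
    cl <- edges$predicted_class[k]
    rows <- class_rows[[cl]]
    if (!any(rows)) stop_input("no patterns with class label ", cl)
    col <- match(edges$feature[k], set$map$feature)
    if (is.na(col))
      stop_input("flagged feature ", edges$feature[k], " not in pattern set")
    v <- mean(set$features[rows, col])
    edges$mean_connectivity[k] <- v
    mats[[cl]][edges$i[k], edges$j[k]] <- v
    mats[[cl]][edges$j[k], edges$i[k]] <- v
  }
  strength <- vapply(mats, rowSums, numeric(n_roi))
  structure(c(mats, list(node_strength = strength, edges = edges)),
            class = "class_adjacency")
}
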