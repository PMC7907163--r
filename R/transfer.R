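#' Transfer-evaluation configuration
#'
#' @param n_sets Number of model sets (default 5).
#' @param partitions_per_set Random train partitions per set (default 3).
#' @param train_fraction Fraction of training patterns in each partition
#'   (default 0.66; the remainder serves as the early-stopping validation
#'   split).
#' @return An object of class `transfer_config`.
#' @export
transfer_config <- function(n_sets = 5L, partitions_per_set = 3L,
                            train_fraction = 0.66) {
  stopifnot(n_sets >= 1, partitions_per_set >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(n_sets = as.integer(n_sets),
                 partitions_per_set = as.integer(partitions_per_set),
                 train_fraction = train_fraction),
            class = "transfer_config")
}

# Stratified random subsample of `frac` of the patterns (by group x lex).
stratified_partition <- function(meta, frac, seed) {
  strata <- interaction(meta$group_label, meta$lexicality_label, drop = TRUE)
  take <- logical(nrow(meta))
  with_seed(seed, {
    for (s in levels(strata)) {
      idx <- which(strata == s)
      take[sample(idx, max(1, round(frac * length(idx))))] <- TRUE
    }
  })
  take
}

#' Cross-task transfer evaluation of first-generation models
#'
#' Trains `n_sets x partitions_per_set` first-generation models (no
#' decimation), each on an independent stratified random `train_fraction`
#' subsample of the training-task patterns (the held-out remainder drives
#' early stopping), and scores every transfer-task pattern with every model.
#' Group metrics are computed against the transfer cohort's group labels;
#' the lexicality head — for which transfer patterns have no ground truth —
#' is summarized as class proportions only.
#'
#' @param train_set Training-task `pattern_set` (both label domains).
#' @param transfer_set Transfer-task `pattern_set` sharing the same feature
#'   map (its lexicality labels are ignored).
#' @param config A [transfer_config()].
#' @param train_cfg A [training_config()] (its `seed` is the base seed).
#' @return A `transfer_result`: list with `per_model` (data.frame: set,
#'   partition, group accuracy/d-prime/phi, word/pseudoword proportions),
#'   `group_metrics` (collapsed across models), `summary` (across sets), and
#'   `profile` from [lexicality_profile()].
#' @export
run_transfer <- function(train_set, transfer_set,
                         config = transfer_config(),
                         train_cfg = training_config()) {
  stopifnot(inherits(train_set, "pattern_set"),
            inherits(transfer_set, "pattern_set"))
  if (!identical(train_set$map$feature, transfer_set$map$feature))
    stop_input("training and transfer sets do not share a feature map")
  if (any(transfer_set$meta$participant_id %in% train_set$meta$participant_id))
    stop_input("transfer participants overlap the training cohort")
  spec <- architecture_spec(ncol(train_set$features))
  y_true <- as.numeric(transfer_set$meta$group_label)
  rows <- list()
  tables <- list()
  prob_store <- list()
  for (s in seq_len(config$n_sets)) {
    for (p in seq_len(config$partitions_per_set)) {
      seed <- derive_seed(train_cfg$seed, "transfer", s, p)
      take <- stratified_partition(train_set$meta, config$train_fraction,
                                   seed)
      tr <- subset_patterns(train_set, rows = take)
      va <- subset_patterns(train_set, rows = !take)
      cfg <- train_cfg
      cfg$seed <- seed
      fit <- train_fold(spec, tr, va, cfg, fold = (s - 1) * 10 + p)
      prob <- predict(fit$model, transfer_set)
      pred_g <- hard_labels(prob[, "group"])
      pred_l <- hard_labels(prob[, "lex"])
      tab <- contingency_table(y_true, pred_g)
      tables[[length(tables) + 1L]] <- tab
      m <- classification_metrics(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        set = s, partition = p,
        group_accuracy = m$accuracy, group_d_prime = m$d_prime,
        group_phi = m$phi,
        word_proportion = mean(pred_l == 1),
        pseudoword_proportion = mean(pred_l == 0))
      prob_store[[length(prob_store) + 1L]] <- prob
    }
  }
  per_model <- do.call(rbind, rows)
  collapsed <- structure(list(
    hits = sum(vapply(tables, `[[`, 0, "hits")),
    misses = sum(vapply(tables, `[[`, 0, "misses")),
    false_alarms = sum(vapply(tables, `[[`, 0, "false_alarms")),
    correct_rejections = sum(vapply(tables, `[[`, 0, "correct_rejections"))),
    class = "contingency_table")
  collapsed$n <- with(collapsed, hits + misses + false_alarms +
                        correct_rejections)
  res <- structure(list(per_model = per_model,
                        group_metrics = classification_metrics(collapsed),
                        probabilities = prob_store,
                        n_transfer_patterns = nrow(transfer_set$features),
                        config = config),
                   class = "transfer_result")
  res$profile <- lexicality_profile(res)
  res
}

#' Lexicality-head class profile over transfer patterns
#'
#' Reports, per model and pooled, the fraction of transfer patterns the
#' lexicality head assigns to each class, with a normal-approximation 95%
#' binomial interval on the pooled word proportion, and flags unanimity when
#' a single class receives every pattern.
#'
#' @param result A `transfer_result`.
#' @return A list with `per_model` (data.frame), `pooled` (named
#'   proportions), `pooled_ci` (95% CI on the pooled word proportion), and
#'   `unanimous` (`"word"`, `"pseudoword"` or NA).
#' @export
lexicality_profile <- function(result) {
  stopifnot(inherits(result, "transfer_result"))
  pm <- result$per_model[, c("set", "partition", "word_proportion",
                             "pseudoword_proportion")]
  pooled_word <- mean(pm$word_proportion)
  n_total <- result$n_transfer_patterns * nrow(pm)
  se <- sqrt(pooled_word * (1 - pooled_word) / n_total)
  unanimous <- if (pooled_word == 1) "word"
    else if (pooled_word == 0) "pseudoword" else NA_character_
  list(per_model = pm,
       pooled = c(word = pooled_word, pseudoword = 1 - pooled_word),
       pooled_ci = c(max(0, pooled_word - 1.96 * se),
                     min(1, pooled_word + 1.96 * se)),
       unanimous = unanimous)
}
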