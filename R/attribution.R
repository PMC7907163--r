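#' Summed path weights from every input feature to each classifier head
#'
#' The influence of one input feature on a head is the sum, over all
#' hidden-unit paths from that input to the head, of the product of the dense
#' weights along the path — computed in one shot as the product of the dense
#' weight matrices `W1 W2 W3 w_head`. Biases and batch-normalization
#' parameters are excluded. A negative score drives the head toward class 0
#' (pseudoword / poor reader), a positive score toward class 1 (word /
#' highly-skilled reader).
#'
#' @param model A `trained_model`.
#' @return A feature x 2 matrix with columns `group` and `lex` of signed
#'   scores.
#' @export
summed_path_weights <- function(model) {
  stopifnot(inherits(model, "trained_model"))
  w <- lapply(model$layers, `[[`, "W")
  p <- w[[1]] %*% w[[2]] %*% w[[3]]
  cbind(group = as.numeric(p %*% model$head_group$w),
        lex = as.numeric(p %*% model$head_lex$w))
}

#' Decimate features by the union of the two heads' bottom deciles
#'
#' Per head, the `ceiling(fraction * F)` features with the smallest
#' aggregated absolute scores are marked (ties broken toward the smaller
#' feature index); the union of the two marked sets is removed and the
#' survivors are returned in their original order.
#'
#' @param scores A feature x 2 matrix of aggregated absolute scores (columns
#'   group, lex), rows aligned with `feature_idx`.
#' @param feature_idx Feature indices labelling the rows.
#' @param fraction Per-head elimination fraction (default 0.1).
#' @return Integer vector of surviving feature indices.
#' @export
decimate_features <- function(scores, feature_idx = seq_len(nrow(scores)),
                              fraction = 0.1) {
  f <- nrow(scores)
  stopifnot(length(feature_idx) == f, ncol(scores) == 2)
  if (f * fraction < 1)
    stop_input("too few features (", f, ") to decimate at fraction ", fraction)
  n_cut <- ceiling(fraction * f)
  marked <- logical(f)
  for (h in 1:2) {
    ord <- order(abs(scores[, h]), feature_idx)
    marked[ord[seq_len(n_cut)]] <- TRUE
  }
  feature_idx[!marked]
}

#' Train and decimate one model generation
#'
#' Restricts the pattern set to the currently retained features, re-derives
#' the architecture from the current feature count, trains the k
#' cross-validation folds, aggregates each feature's attribution as the sum
#' over folds of the absolute summed path weights per head, and applies
#' decimation to propose the next generation's feature set.
#'
#' @param set The full (masked) `pattern_set`.
#' @param retained Integer vector of currently retained feature indices
#'   (values of `set$map$feature`).
#' @param config A [training_config()].
#' @param seed Generation seed (controls fold assignment and training).
#' @param generation Generation index recorded in the result.
#' @param decimate Apply decimation (default TRUE; the final evaluation
#'   generation of a family is trained without decimating).
#' @param fraction Per-head elimination fraction.
#' @return A `generation_result`: list with `generation`, `retained_in`,
#'   `retained_out`, `metrics` (per head, collapsed across folds), `scores`
#'   (aggregated absolute score matrix), `signed_scores` (mean signed path
#'   weight across folds), `fold_results`, `hidden_sizes`, `n_weights`.
#' @export
run_generation <- function(set, retained, config, seed, generation = 1L,
                           decimate = TRUE, fraction = 0.1) {
  stopifnot(length(retained) >= 2)
  sub <- subset_patterns(set, feature_idx = retained)
  spec <- architecture_spec(length(retained))
  cfg <- config
  cfg$seed <- seed
  cv <- cross_validate(sub, cfg, spec)
  agg <- matrix(0, length(retained), 2,
                dimnames = list(NULL, c("group", "lex")))
  signed <- agg
  for (m in cv$models) {
    spw <- summed_path_weights(m)
    agg <- agg + abs(spw)
    signed <- signed + spw
  }
  signed <- signed / length(cv$models)
  out <- if (decimate) decimate_features(agg, retained, fraction) else retained
  structure(list(generation = generation,
                 retained_in = retained,
                 retained_out = out,
                 metrics = cv$metrics,
                 scores = agg,
                 signed_scores = signed,
                 fold_results = cv$fold_results,
                 hidden_sizes = spec$hidden_sizes,
                 n_weights = count_dense_weights(spec)),
            class = "generation_result")
}

count_dense_weights <- function(spec) {
  d <- c(spec$input_dim, spec$hidden_sizes)
  sum(d[-4] * d[-1]) + 2 * d[4]
}

#' Run one model family: iterative decimation to the stopping threshold
#'
#' Starting from the post-mask feature set, repeatedly trains a generation
#' and removes the union of the two heads' bottom-decile features, until the
#' retained count is at most `stop_fraction` of the *full* (pre-mask) feature
#' count. The family's last generation is then trained on the surviving set
#' without decimating — the "final generation" whose models use the reduced
#' feature set. `n_generations` counts every trained generation including
#' that final one; `n_decimating_generations` counts only the cycles that
#' removed features.
#'
#' @param set The masked `pattern_set` (its map must carry full-set feature
#'   indices, as produced by [build_pattern_set()]).
#' @param config A [training_config()].
#' @param family_seed Seed for this family; generations derive their seeds
#'   from it.
#' @param stop_fraction Stopping threshold as a fraction of the full feature
#'   set (default 0.05).
#' @param n_full Full pre-mask feature count (default `N(N-1)/2` implied by
#'   the map).
#' @param fraction Per-head elimination fraction per generation.
#' @param max_generations Abort beyond this many generations.
#' @return A `family_result`: list with `generations` (decimating
#'   generations), `final_generation` (the generation trained on the final
#'   set, which does not decimate), `final_features`,
#'   `n_decimating_generations`, `n_generations` (trained generations, i.e.
#'   decimating generations plus the final one), `stop_threshold`,
#'   `family_seed`.
#' @export
run_family <- function(set, config = training_config(), family_seed = 1L,
                       stop_fraction = 0.05, n_full = NULL, fraction = 0.1,
                       max_generations = 40L) {
  stopifnot(inherits(set, "pattern_set"))
  if (is.null(n_full)) {
    n_roi <- max(set$map$j)
    n_full <- n_roi * (n_roi - 1) / 2
  }
  threshold <- floor(stop_fraction * n_full)
  retained <- set$map$feature
  generations <- list()
  g <- 0L
  while (length(retained) > threshold) {
    g <- g + 1L
    if (g > max_generations)
      stop_input("decimation failed to reach ", threshold, " features in ",
                 max_generations, " generations")
    gen <- run_generation(set, retained, config,
                          seed = derive_seed(family_seed, "generation", g),
                          generation = g)
    if (length(gen$retained_out) >= length(retained))
      stop_input("decimation did not shrink the feature set at generation ", g)
    generations[[g]] <- gen
    retained <- gen$retained_out
  }
  final <- run_generation(set, retained, config,
                          seed = derive_seed(family_seed, "final"),
                          generation = g + 1L, decimate = FALSE)
  structure(list(generations = generations,
                 final_generation = final,
                 final_features = retained,
                 n_decimating_generations = g,
                 n_generations = g + 1L,
                 stop_threshold = threshold,
                 family_seed = family_seed),
            class = "family_result")
}

#' Run independent model families
#'
#' Each family runs the full decimation loop under its own derived seed; no
#' state is shared between families.
#'
#' @param set The masked `pattern_set`.
#' @param n_families Number of families (default 20).
#' @param config A [training_config()] whose `seed` is the base seed.
#' @param ... Passed to [run_family()].
#' @return A list of `family_result` objects.
#' @export
run_families <- function(set, n_families = 20L, config = training_config(),
                         ...) {
  lapply(seq_len(n_families), function(k)
    run_family(set, config,
               family_seed = derive_seed(config$seed, "family", k), ...))
}

#' Per-family metric table
#'
#' One row per family with collapsed first- and final-generation metrics,
#' ready for [summarize_families()].
#'
#' @param families List of `family_result`s.
#' @param which `"final"` (default) or `"first"`.
#' @return A data.frame with accuracy, d-prime and phi per head.
#' @export
family_metric_table <- function(families, which = c("final", "first")) {
  which <- match.arg(which)
  rows <- lapply(seq_along(families), function(k) {
    fam <- families[[k]]
    m <- if (which == "final") fam$final_generation$metrics
         else fam$generations[[1]]$metrics
    data.frame(family = k,
               group_accuracy = m$group$accuracy,
               group_d_prime = m$group$d_prime,
               group_phi = m$group$phi,
               lex_accuracy = m$lex$accuracy,
               lex_d_prime = m$lex$d_prime,
               lex_phi = m$lex$phi)
  })
  do.call(rbind, rows)
}
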