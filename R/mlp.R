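#' Hidden layer sizes as a logarithmic function of the input width
#'
#' The first hidden layer has `max(16, 2 * ceiling(log2(i)))` units for `i`
#' input features; the second and third are always half that size. The floor
#' of 16 binds for all `i <= 256`, and the rule makes the hidden stack shrink
#' as decimation removes input features.
#'
#' @param i Number of input features (`i >= 2`).
#' @return Integer vector `c(h1, h2, h3)`.
#' @export
#' @examples
#' hidden_layer_sizes(6302)  # 26 13 13
#' hidden_layer_sizes(327)   # 18  9  9
hidden_layer_sizes <- function(i) {
  if (!is.numeric(i) || length(i) != 1 || i < 2)
    stop_input("need at least 2 input features")
  h1 <- max(16, 2 * ceiling(log2(i)))
  as.integer(c(h1, h1 / 2, h1 / 2))
}

#' Architecture specification for the dual-head classifier
#'
#' @param input_dim Number of input features.
#' @param noise_sd SD of the Gaussian input noise applied during training.
#' @param dropout_rate Input dropout rate during training.
#' @param l1_coefficient L1 penalty on the first dense weight matrix.
#' @return An object of class `architecture_spec` including the derived
#'   `hidden_sizes`.
#' @export
architecture_spec <- function(input_dim, noise_sd = 0.05, dropout_rate = 0.2,
                              l1_coefficient = 5e-4) {
  stopifnot(input_dim >= 2, noise_sd >= 0, dropout_rate >= 0,
            dropout_rate < 1, l1_coefficient >= 0)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_sizes = hidden_layer_sizes(input_dim),
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 l1_coefficient = l1_coefficient),
            class = "architecture_spec")
}

#' Training configuration for the dual-head classifier
#'
#' Plain SGD with momentum and an inverse-time learning-rate schedule
#' `lr / (1 + decay * epoch)`, summed binary cross-entropy over the two heads
#' (equal weighting), and early stopping that monitors the validation
#' lexicality-head loss with best-weight restoration.
#'
#' @param learning_rate Initial learning rate.
#' @param decay Per-epoch inverse-time decay coefficient.
#' @param momentum SGD momentum.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience, in epochs without improvement of
#'   the monitored validation loss.
#' @param k_folds Cross-validation folds.
#' @param bn_momentum Batch-normalization running-statistics momentum.
#' @param bn_eps Batch-normalization variance epsilon.
#' @param seed Training seed.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.01, decay = 0.05,
                            momentum = 0.9, batch_size = 16,
                            max_epochs = 216, patience = 16, k_folds = 5,
                            bn_momentum = 0.9, bn_eps = 1e-3, seed = 1L) {
  stopifnot(learning_rate > 0, learning_rate <= 1, decay >= 0,
            momentum >= 0, momentum < 1, batch_size >= 1,
            max_epochs >= 1, patience < max_epochs, k_folds >= 2)
  structure(list(learning_rate = learning_rate, decay = decay,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 k_folds = as.integer(k_folds),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 seed = as.integer(seed)),
            class = "training_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize an untrained dual-head model
#'
#' Glorot-uniform dense weights, zero biases, and identity batch-norm state,
#' deterministic for a given seed. The forward path is: input (plus Gaussian
#' noise and dropout during training) -> three dense/batch-norm/ReLU hidden
#' layers -> two parallel single-unit sigmoid heads (group, lexicality).
#'
#' @param spec An [architecture_spec()].
#' @param seed Initialization seed.
#' @return An object of class `trained_model` (untrained until passed through
#'   [train_fold()]).
#' @export
initialize_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  with_seed(seed, {
    dims <- c(spec$input_dim, spec$hidden_sizes)
    layers <- lapply(1:3, function(l) {
      h <- dims[l + 1]
      list(W = glorot(dims[l], h), b = rep(0, h), gamma = rep(1, h),
           beta = rep(0, h), rmean = rep(0, h), rvar = rep(1, h))
    })
    h3 <- dims[4]
    model <- list(layers = layers,
                  head_group = list(w = as.numeric(glorot(h3, 1)), b = 0),
                  head_lex = list(w = as.numeric(glorot(h3, 1)), b = 0),
                  spec = spec, seed = as.integer(seed), trained = FALSE)
    class(model) <- "trained_model"
    model
  })
}

#' Stratified k-fold assignment
#'
#' Partitions pattern indices into `k` folds stratified jointly on the group
#' and lexicality labels, so every pattern appears in exactly one validation
#' fold and per-fold strata proportions match the global proportions to
#' within one pattern.
#'
#' @param set A `pattern_set` (or a data.frame of labels with columns
#'   `group_label` and `lexicality_label`).
#' @param k Number of folds.
#' @param seed Shuffling seed.
#' @return Integer vector of fold ids (1..k), one per pattern.
#' @export
stratified_kfold <- function(set, k, seed = 1L) {
  meta <- if (inherits(set, "pattern_set")) set$meta else set
  strata <- interaction(meta$group_label, meta$lexicality_label, drop = TRUE)
  if (min(table(strata)) < k)
    stop_input("a group x lexicality stratum has fewer than k patterns")
  folds <- integer(nrow(meta))
  with_seed(seed, {
    offset <- 0L
    for (s in levels(strata)) {
      idx <- sample(which(strata == s))
      # round-robin deal with a rotating offset so fold sizes stay balanced
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  folds
}

# Forward pass in inference mode (running BN statistics, no perturbation).
mlp_forward <- function(model, x) {
  h <- x
  for (l in model$layers) {
    a <- sweep(h %*% l$W, 2, l$b, `+`)
    a <- sweep(a, 2, l$rmean, `-`)
    a <- sweep(a, 2, sqrt(l$rvar + model$bn_eps %||% 1e-3), `/`)
    a <- sweep(a, 2, l$gamma, `*`)
    a <- sweep(a, 2, l$beta, `+`)
    h <- pmax(a, 0)
  }
  plogis_mat <- function(w, b) 1 / (1 + exp(-(h %*% w + b)))
  cbind(group = as.numeric(plogis_mat(model$head_group$w, model$head_group$b)),
        lex = as.numeric(plogis_mat(model$head_lex$w, model$head_lex$b)))
}

#' Score patterns with a trained model
#'
#' Inference mode: noise and dropout are disabled and batch normalization
#' uses the accumulated running statistics. Hard labels use the rule
#' `probability >= 0.5 -> class 1`.
#'
#' @param object A `trained_model`.
#' @param patterns A `pattern_set` or a pattern x feature matrix.
#' @param ... Unused.
#' @return A matrix with columns `group` and `lex` of probabilities in
#'   `(0, 1)`.
#' @export
predict.trained_model <- function(object, patterns, ...) {
  x <- if (inherits(patterns, "pattern_set")) patterns$features else patterns
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != object$spec$input_dim)
    stop_input("feature dimension ", ncol(x), " does not match model input ",
               object$spec$input_dim)
  mlp_forward(object, x)
}

#' Hard labels from head probabilities
#' @param prob Probability vector or matrix.
#' @return 0/1 labels (`>= 0.5` maps to 1).
#' @export
hard_labels <- function(prob) ifelse(prob >= 0.5, 1L, 0L)

label_matrix <- function(meta) {
  lex <- suppressWarnings(as.numeric(meta$lexicality_label))
  if (anyNA(lex))
    stop_input("patterns without a numeric lexicality label (transfer ",
               "patterns) cannot be used for supervised training")
  cbind(group = as.numeric(meta$group_label), lex = lex)
}

#' Train one cross-validation fold of the dual-head classifier
#'
#' Minimizes the sum of the two heads' binary cross-entropies plus the L1
#' penalty on the first dense layer, by mini-batch SGD with momentum and an
#' inverse-time learning-rate schedule. Early stopping monitors the
#' validation lexicality-head loss and restores the best epoch's weights.
#'
#' @param spec An [architecture_spec()] matching the training feature width.
#' @param train_set,val_set `pattern_set`s sharing one feature map.
#' @param config A [training_config()].
#' @param fold Fold index recorded in the result.
#' @return A list with `model` (a `trained_model`) and `result` (a
#'   `fold_result` holding validation probabilities, labels, per-head
#'   contingency tables, epochs trained, and the loss history).
#' @export
train_fold <- function(spec, train_set, val_set, config, fold = 1L) {
  stopifnot(inherits(spec, "architecture_spec"),
            inherits(config, "training_config"))
  if (!identical(train_set$map$feature, val_set$map$feature))
    stop_input("train and validation sets do not share a feature map")
  y_tr <- label_matrix(train_set$meta)
  if (length(unique(y_tr[, 1])) < 2 || length(unique(y_tr[, 2])) < 2)
    stop_input("training set degenerate in one of the label domains")
  y_val <- label_matrix(val_set$meta)
  init <- initialize_model(spec, seed = derive_seed(config$seed, "init", fold))
  hyper <- list(learning_rate = config$learning_rate, decay = config$decay,
                momentum = config$momentum, batch_size = config$batch_size,
                max_epochs = config$max_epochs, patience = config$patience,
                noise_sd = spec$noise_sd, dropout_rate = spec$dropout_rate,
                l1_coefficient = spec$l1_coefficient,
                bn_momentum = config$bn_momentum, bn_eps = config$bn_eps)
  fit <- mlp_train_cpp(train_set$features, y_tr, val_set$features, y_val,
                       init[c("layers", "head_group", "head_lex")], hyper,
                       derive_seed(config$seed, "sgd", fold))
  model <- init
  model$layers <- lapply(fit$layers, function(l)
    list(W = l$W, b = as.numeric(l$b), gamma = as.numeric(l$gamma),
         beta = as.numeric(l$beta), rmean = as.numeric(l$rmean),
         rvar = as.numeric(l$rvar)))
  model$head_group <- list(w = as.numeric(fit$head_group$w),
                           b = fit$head_group$b)
  model$head_lex <- list(w = as.numeric(fit$head_lex$w), b = fit$head_lex$b)
  model$bn_eps <- config$bn_eps
  model$trained <- TRUE
  prob <- cbind(group = as.numeric(fit$val_prob_group),
                lex = as.numeric(fit$val_prob_lex))
  result <- structure(list(
    fold = fold,
    prob = prob,
    truth = y_val,
    tables = list(
      group = contingency_table(y_val[, 1], hard_labels(prob[, 1])),
      lex = contingency_table(y_val[, 2], hard_labels(prob[, 2]))),
    epochs_trained = fit$epochs_trained,
    best_epoch = fit$best_epoch,
    best_val_lex_loss = fit$best_val_lex_loss,
    history = fit$history), class = "fold_result")
  list(model = model, result = result)
}

#' Run stratified k-fold cross-validation of the dual-head classifier
#'
#' @param set A `pattern_set` with both label domains populated.
#' @param config A [training_config()].
#' @param spec Optional [architecture_spec()]; defaults to the set's width.
#' @return A list with `models`, `fold_results`, `folds` (assignment vector),
#'   and `metrics` (per-head [classification_metrics()] collapsed across
#'   folds).
#' @export
cross_validate <- function(set, config = training_config(), spec = NULL) {
  stopifnot(inherits(set, "pattern_set"))
  if (is.null(spec)) spec <- architecture_spec(ncol(set$features))
  folds <- stratified_kfold(set, config$k_folds,
                            seed = derive_seed(config$seed, "folds"))
  models <- list()
  results <- list()
  for (f in seq_len(config$k_folds)) {
    tr <- subset_patterns(set, rows = folds != f)
    va <- subset_patterns(set, rows = folds == f)
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, "fold", f)
    fit <- train_fold(spec, tr, va, cfg_f, fold = f)
    models[[f]] <- fit$model
    results[[f]] <- fit$result
  }
  list(models = models, fold_results = results, folds = folds,
       metrics = collapse_fold_metrics(results))
}

# Collapse fold contingency tables into per-head metrics.
collapse_fold_metrics <- function(fold_results) {
  collapse <- function(head) {
    tabs <- lapply(fold_results, function(r) r$tables[[head]])
    total <- list(hits = sum(vapply(tabs, `[[`, 0, "hits")),
                  misses = sum(vapply(tabs, `[[`, 0, "misses")),
                  false_alarms = sum(vapply(tabs, `[[`, 0, "false_alarms")),
                  correct_rejections =
                    sum(vapply(tabs, `[[`, 0, "correct_rejections")))
    total$n <- total$hits + total$misses + total$false_alarms +
      total$correct_rejections
    class(total) <- "contingency_table"
    classification_metrics(total)
  }
  list(group = collapse("group"), lex = collapse("lex"))
}
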