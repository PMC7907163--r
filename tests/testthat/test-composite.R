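fake_family <- function(final_features, seed = 1) {
  structure(list(final_features = final_features, family_seed = seed),
            class = "family_result")
}

test_that("feature frequencies count final-set membership with bounds", {
  map <- feature_index_map(10)
  fams <- list(fake_family(c(1, 2, 3)), fake_family(c(2, 3, 4)),
               fake_family(c(3, 30)))
  counts <- feature_frequencies(fams, map)
  expect_equal(unname(counts[1:4]), c(1, 2, 3, 1))
  expect_equal(unname(counts[30]), 1)
  expect_equal(unname(counts[5]), 0)
  expect_true(all(counts <= length(fams)))
  bad <- list(fake_family(c(99999)))
  expect_error(feature_frequencies(bad, map), "not present")
})

test_that("composite selection is monotone in the reliability threshold", {
  map <- feature_index_map(10)
  fams <- lapply(1:6, function(k) fake_family(seq_len(10 - k)))
  counts <- feature_frequencies(fams, map)
  prev <- NULL
  for (k in 1:6) {
    sel <- select_composite(counts, map, composite_config(min_family_count = k))
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
  expect_equal(select_composite(counts, map,
                                composite_config(min_family_count = 1)),
               unname(which(counts > 0)))
  expect_error(select_composite(counts, map,
                                composite_config(min_family_count = 7)),
               "lower min_family_count")
})

test_that("the tuned threshold lands near the target composite size", {
  set.seed(4)
  counts <- rpois(6555, 0.8)
  k <- tune_min_family_count(counts, 6555, target_fraction = 0.05)
  expect_lte(sum(counts >= k), 0.05 * 6555)
  if (k > 1) expect_gt(sum(counts >= k - 1), 0.05 * 6555)
})

test_that("composite training evaluates every pattern once at the right width", {
  ps <- tiny_patterns()
  features <- sort(sample(ps$map$feature, 40))
  comp <- train_composite(ps, features, quick_config(max_epochs = 6,
                                                     patience = 5),
                          composite_config(composite_k_folds = 4))
  expect_s3_class(comp, "composite_result")
  expect_equal(comp$models[[1]]$spec$input_dim, 40)
  expect_equal(comp$models[[1]]$spec$hidden_sizes, hidden_layer_sizes(40))
  expect_equal(sum(vapply(comp$fold_results, function(r) nrow(r$prob), 0)),
               nrow(ps$features))
  expect_equal(dim(comp$signed_scores), c(40, 2))
})

test_that("relevance flagging matches the normal tail and sign convention", {
  ps <- tiny_patterns()
  features <- sort(sample(ps$map$feature, 60))
  comp <- structure(list(
    features = features,
    signed_scores = cbind(group = qnorm((1:60 - 0.5) / 60),
                          lex = qnorm((1:60 - 0.5) / 60) *
                            rep(c(-1, 1), 30)),
    map = fcfingerprint:::subset_patterns(ps, feature_idx = features)$map),
    class = "composite_result")
  edges <- flag_highly_relevant(comp, composite_config(z_threshold = 1))
  # scores are standard-normal by construction: flagged fraction ~ 2*pnorm(-1)
  frac <- sum(edges$head == "group") / 60
  expect_lt(abs(frac - 2 * pnorm(-1)), 0.1)
  # class follows the sign of the mean weight
  expect_true(all(edges$predicted_class[edges$head == "group" &
                                          edges$mean_weight < 0] == "poor"))
  expect_true(all(edges$predicted_class[edges$head == "group" &
                                          edges$mean_weight > 0] == "skilled"))
  expect_true(all(edges$predicted_class[edges$head == "lex" &
                                          edges$mean_weight < 0] == "pseudoword"))

  # monotone in the threshold
  e2 <- flag_highly_relevant(comp, composite_config(z_threshold = 1.5))
  expect_lte(nrow(e2), nrow(edges))

  comp0 <- comp
  comp0$signed_scores[, "group"] <- 1
  expect_error(flag_highly_relevant(comp0), "zero variance")
})

test_that("class adjacency holds mean connectivity of the predicted class only", {
  ps <- tiny_patterns()
  features <- sort(sample(ps$map$feature, 60))
  set.seed(9)
  comp <- structure(list(
    features = features,
    signed_scores = cbind(group = rnorm(60), lex = rnorm(60)),
    map = fcfingerprint:::subset_patterns(ps, feature_idx = features)$map),
    class = "composite_result")
  edges <- flag_highly_relevant(comp)
  adj <- build_class_adjacency(edges, ps)
  # symmetric, zero diagonal
  for (cl in c("poor", "skilled", "pseudoword", "word")) {
    expect_identical(adj[[cl]], t(adj[[cl]]))
    expect_true(all(diag(adj[[cl]]) == 0))
  }
  # a skilled-predictive edge holds the mean over skilled patterns only
  sk <- adj$edges[adj$edges$predicted_class == "skilled", ]
  if (nrow(sk) > 0) {
    k <- 1
    col <- match(sk$feature[k], ps$map$feature)
    expected <- mean(ps$features[ps$meta$group_label == 1, col])
    expect_equal(adj$skilled[sk$i[k], sk$j[k]], expected, tolerance = 1e-12)
    expect_equal(sk$mean_connectivity[k], expected, tolerance = 1e-12)
  }
  # cells off the flagged edges are zero
  n_cells_nonzero <- sum(vapply(c("poor", "skilled", "pseudoword", "word"),
                                function(cl) sum(adj[[cl]] != 0), 0))
  expect_equal(n_cells_nonzero, 2 * nrow(adj$edges))
  # node strength columns match row sums
  expect_equal(adj$node_strength[, "word"], rowSums(adj$word))
})
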