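# brute-force oracle: enumerate every hidden-unit path input -> head
enumerate_path_sum <- function(model, head) {
  W <- lapply(model$layers, `[[`, "W")
  w_head <- model[[head]]$w
  f <- nrow(W[[1]])
  out <- numeric(f)
  for (i in seq_len(f))
    for (a in seq_len(ncol(W[[1]])))
      for (b in seq_len(ncol(W[[2]])))
        for (c_ in seq_len(ncol(W[[3]])))
          out[i] <- out[i] +
            W[[1]][i, a] * W[[2]][a, b] * W[[3]][b, c_] * w_head[c_]
  out
}

test_that("summed path weights equal exhaustive path enumeration", {
  # all-ones tiny net: every feature has two unit paths to the single head
  m <- initialize_model(architecture_spec(2), seed = 1)
  m$layers[[1]]$W <- matrix(1, 2, 16)
  m$layers[[2]]$W <- matrix(0, 16, 8); m$layers[[2]]$W[1, 1] <- 1
  m$layers[[3]]$W <- matrix(0, 8, 8)
  m$layers[[3]]$W[1, 1] <- 1; m$layers[[3]]$W[1, 2] <- 1
  m$head_group$w <- c(1, 1, rep(0, 6))
  spw <- summed_path_weights(m)
  expect_equal(unname(spw[, "group"]), c(2, 2))

  # random small nets vs brute force
  set.seed(13)
  for (rep in 1:3) {
    m <- initialize_model(architecture_spec(5), seed = rep)
    for (l in 1:3) m$layers[[l]]$W <- m$layers[[l]]$W + rnorm(1, sd = 0.01)
    spw <- summed_path_weights(m)
    expect_equal(unname(spw[, "group"]), enumerate_path_sum(m, "head_group"),
                 tolerance = 1e-9)
    expect_equal(unname(spw[, "lex"]), enumerate_path_sum(m, "head_lex"),
                 tolerance = 1e-9)
  }

  # negating the group head flips group scores only
  m2 <- m
  m2$head_group$w <- -m2$head_group$w
  spw2 <- summed_path_weights(m2)
  expect_equal(spw2[, "group"], -spw[, "group"], tolerance = 1e-12)
  expect_identical(spw2[, "lex"], spw[, "lex"])
})

test_that("decimation removes the union of the two bottom deciles", {
  # disjoint bottom deciles: 100 - 20 survive
  s <- cbind(group = c(1:10 / 100, runif(90, 0.5, 1)),
             lex = c(runif(90, 0.5, 1), 1:10 / 100))
  expect_length(decimate_features(s), 80)

  # identical rankings: 100 - 10 survive
  v <- seq(0.01, 1, length.out = 100)
  expect_length(decimate_features(cbind(v, v)), 90)

  # ceiling rule at F = 10: exactly one marked per head
  s10 <- cbind(c(0.05, runif(9, 0.5, 1)), c(runif(9, 0.5, 1), 0.05))
  expect_equal(decimate_features(s10), 2:9)

  # ties broken toward the smaller feature index
  tie <- cbind(rep(1, 10), rep(1, 10))
  surv <- decimate_features(tie)
  expect_equal(surv, 2:10)

  expect_error(decimate_features(cbind(1:5 / 5, 1:5 / 5)), "too few")
})

test_that("one generation trains, scores, and decimates within bounds", {
  ps <- tiny_patterns()
  retained <- ps$map$feature
  gen <- run_generation(ps, retained, quick_config(max_epochs = 8,
                                                   patience = 7), seed = 21)
  expect_s3_class(gen, "generation_result")
  expect_true(all(gen$retained_out %in% retained))
  removed <- length(retained) - length(gen$retained_out)
  f <- length(retained)
  expect_gte(removed, ceiling(0.1 * f))
  expect_lte(removed, 2 * ceiling(0.1 * f))
  expect_equal(dim(gen$scores), c(f, 2))
  expect_true(all(is.finite(gen$scores)))
  # |signed mean| can never exceed the fold-summed absolute scores
  expect_true(all(abs(gen$signed_scores) * length(gen$fold_results) <=
                    gen$scores + 1e-9))
  # architecture re-derived from the current width
  expect_equal(gen$hidden_sizes, hidden_layer_sizes(f))
})

test_that("a family decimates to the stop threshold with strictly shrinking sets", {
  ps <- tiny_patterns()
  n_full <- nrow(feature_index_map(tiny_spec()$n_roi))
  fam <- run_family(ps, quick_config(max_epochs = 8, patience = 7),
                    family_seed = 5, stop_fraction = 0.3)
  expect_s3_class(fam, "family_result")
  counts <- vapply(fam$generations, function(g) length(g$retained_in), 0)
  expect_true(all(diff(counts) < 0))
  expect_lte(length(fam$final_features), floor(0.3 * n_full))
  expect_equal(fam$n_decimating_generations, length(fam$generations))
  expect_equal(fam$n_generations, length(fam$generations) + 1L)
  # the final evaluation generation trains on the final set, undecimated
  expect_identical(fam$final_generation$retained_in, fam$final_features)
  expect_identical(fam$final_generation$retained_out, fam$final_features)
  # chaining: each generation consumes the previous output
  for (g in seq_along(fam$generations)[-1])
    expect_identical(fam$generations[[g]]$retained_in,
                     fam$generations[[g - 1]]$retained_out)
})

test_that("families are independent, reproducible and generally distinct", {
  ps <- tiny_patterns()
  cfg <- quick_config(max_epochs = 6, patience = 5, seed = 77)
  fams <- run_families(ps, n_families = 2, config = cfg, stop_fraction = 0.4)
  expect_length(fams, 2)
  expect_false(identical(fams[[1]]$final_features, fams[[2]]$final_features))
  fams2 <- run_families(ps, n_families = 2, config = cfg, stop_fraction = 0.4)
  expect_identical(fams[[1]]$final_features, fams2[[1]]$final_features)
  expect_identical(fams[[2]]$final_generation$signed_scores,
                   fams2[[2]]$final_generation$signed_scores)
})

test_that("planted features outlive unplanted features under decimation", {
  md <- medium_patterns()
  ps <- md$patterns
  truth <- md$cohort$truth
  cfg <- quick_config(max_epochs = 16, patience = 15, seed = 8)
  # pool survival generations over three independent families
  surv_planted <- c(); surv_other <- c()
  for (fs in 1:3) {
    fam <- run_family(ps, cfg, family_seed = fs, stop_fraction = 0.08)
    survival <- setNames(rep(0L, nrow(ps$map)), ps$map$feature)
    for (g in seq_along(fam$generations)) {
      keep <- as.character(fam$generations[[g]]$retained_out)
      survival[keep] <- g
    }
    planted <- as.character(truth$group_feature_idx)
    planted <- planted[planted %in% names(survival)]
    other <- setdiff(names(survival), planted)
    surv_planted <- c(surv_planted, survival[planted])
    surv_other <- c(surv_other, survival[other])
  }
  w <- wilcox.test(surv_planted, surv_other, alternative = "greater",
                   exact = FALSE)
  expect_gt(mean(surv_planted), mean(surv_other))
  expect_lt(w$p.value, 1e-4)
})
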