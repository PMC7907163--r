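test_that("default cluster assignment yields exactly 253 within-cluster pairs", {
  assignment <- default_cluster_assignment(115)
  pairs <- fcfingerprint:::within_cluster_pairs(assignment)
  expect_equal(nrow(pairs), 253)
  sizes <- table(assignment)
  expect_equal(sum(sizes * (sizes - 1) / 2), 253)
})

test_that("run covariance honours deltas, bounds and the identity case", {
  sp <- tiny_spec()
  co <- tiny_cohort()
  truth <- co$truth
  base <- truth$base

  # all-zero deltas: output is the base, exactly
  truth0 <- truth
  truth0$delta_group <- rep(0, nrow(truth0$group_edges))
  truth0$delta_condition <- rep(0, nrow(truth0$condition_edges))
  expect_identical(build_run_covariance(base, truth0, 1, 1), base)
  expect_identical(build_run_covariance(base, truth, 0, 0), base)

  # planted increment survives the PSD repair (alternating projections)
  cov11 <- build_run_covariance(base, truth, 1, 1)
  target <- base[truth$group_edges] + truth$delta_group
  expect_lt(max(abs(cov11[truth$group_edges] - target)), 0.02)

  # an increment pushing past 1 is clipped to 0.99 before repair; jointly
  # infeasible clipped cells fall back to nearest-PSD with a warning
  truth_big <- truth
  truth_big$delta_group <- rep(2, nrow(truth$group_edges))
  cov_big <- NULL
  expect_warning(cov_big <- build_run_covariance(base, truth_big, 1, 0),
                 "infeasible")
  expect_lte(max(cov_big[truth$group_edges]), 0.99)

  expect_error(build_run_covariance(matrix(1:6, 2, 3), truth, 1, 1), "square")
  asym <- base; asym[1, 2] <- asym[1, 2] + 0.5
  expect_error(build_run_covariance(asym, truth, 1, 1), "symmetric")
})

test_that("every emitted covariance is PSD with unit diagonal", {
  co <- tiny_cohort()
  for (g in 0:1) for (cnd in 0:1) {
    cov <- build_run_covariance(co$truth$base, co$truth, g, cnd)
    expect_equal(unname(diag(cov)), rep(1, nrow(cov)))
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("cohort generation obeys the shape contract and determinism", {
  sp <- tiny_spec(n_per_group = 4)
  co <- generate_cohort(sp)
  expect_equal(length(co$runs), 8 * 4)  # 8 participants x (2 cond x 2 runs)
  expect_equal(dim(co$runs[[1]]$values), c(80, 20))
  expect_equal(length(unique(vapply(co$runs, `[[`, "", "participant_id"))), 8)
  grp <- vapply(co$runs, function(r) r$group_label, numeric(1))
  expect_equal(sum(grp == 1), sum(grp == 0))

  co2 <- generate_cohort(sp)
  expect_identical(co$runs[[7]]$values, co2$runs[[7]]$values)
  # ground truth maps to valid upper-triangle feature indices
  n_feat <- sp$n_roi * (sp$n_roi - 1) / 2
  expect_true(all(co$truth$group_feature_idx %in% seq_len(n_feat)))
  map <- feature_index_map(sp$n_roi)
  pos <- match(co$truth$group_feature_idx, map$feature)
  expect_equal(unname(as.matrix(map[pos, c("i", "j")])),
               unname(co$truth$group_edges))
})

test_that("planted group effect is recovered in sample correlations", {
  # pooled over several seeds: mean residualized sample correlation
  # difference (skilled - poor) within +-0.05 of delta_group
  diffs <- vapply(1:6, function(s) {
    co <- generate_cohort(tiny_spec(seed = s, delta_group = 0.4))
    vals <- vapply(co$runs, function(run) {
      r <- residualize(run)
      mean(cor(r$values)[co$truth$group_edges])
    }, numeric(1))
    grp <- vapply(co$runs, function(r) r$group_label, numeric(1))
    mean(vals[grp == 1]) - mean(vals[grp == 0])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 0.4), 0.05)
})

test_that("a null cohort is exchangeable across groups and conditions", {
  # pooled edge correlations from the two groups follow one distribution
  pool <- function(seed) {
    co <- generate_cohort(tiny_spec(seed = seed, delta_group = 0,
                                    delta_condition = 0))
    grp <- vapply(co$runs, function(r) r$group_label, numeric(1))
    idx <- which(upper.tri(diag(co$spec$n_roi)), arr.ind = TRUE)
    rs <- t(vapply(co$runs, function(run)
      cor(residualize(run)$values)[idx[seq(1, nrow(idx), by = 7), ]],
      numeric(length(seq(1, nrow(idx), by = 7)))))
    list(g0 = as.numeric(rs[grp == 0, ]), g1 = as.numeric(rs[grp == 1, ]))
  }
  ps <- lapply(1:4, pool)
  g0 <- unlist(lapply(ps, `[[`, "g0"))
  g1 <- unlist(lapply(ps, `[[`, "g1"))
  expect_gt(suppressWarnings(ks.test(g0, g1)$p.value), 0.01)
})

test_that("sample correlations converge at the 1/sqrt(T) rate", {
  rms <- function(volumes) {
    sp <- tiny_spec(seed = 3, volumes_per_run = volumes)
    co <- generate_cohort(sp)
    cov11 <- build_run_covariance(co$truth$base, co$truth, 1, 1)
    errs <- unlist(lapply(co$runs, function(run) {
      if (run$group_label != 1 || run$condition_label != 1) return(NULL)
      cor(residualize(run)$values)[co$truth$group_edges] -
        cov11[co$truth$group_edges]
    }))
    sqrt(mean(errs^2))
  }
  ratio <- rms(320) / rms(160)
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.2 / sqrt(2))
})

test_that("transfer cohorts share the group fingerprint but not the task", {
  co <- tiny_cohort()
  tsp <- tiny_spec(n_per_group = 3)
  tc <- generate_transfer_cohort(tsp, co$truth)
  expect_equal(length(tc$runs), 6 * 2)
  grp <- vapply(tc$runs, function(r) r$group_label, numeric(1))
  expect_equal(sum(grp == 1), sum(grp == 0))
  expect_true(all(vapply(tc$runs, function(r)
    identical(r$condition_label, "transfer"), logical(1))))
  # fresh task edges are disjoint from the training planted edges
  t_idx <- fcfingerprint:::upper_pair_index(tc$truth$transfer_edges[, 1],
                                            tc$truth$transfer_edges[, 2],
                                            tsp$n_roi)
  expect_length(intersect(t_idx, c(co$truth$group_feature_idx,
                                   co$truth$condition_feature_idx)), 0)

  # group effect present, training-task effect absent (pooled over seeds)
  gdiff <- c(); cdiff <- c()
  for (s in 1:6) {
    tc_s <- generate_transfer_cohort(tiny_spec(n_per_group = 3, seed = s),
                                     co$truth)
    vals_g <- vapply(tc_s$runs, function(run)
      mean(cor(residualize(run)$values)[co$truth$group_edges]), numeric(1))
    vals_c <- vapply(tc_s$runs, function(run)
      mean(cor(residualize(run)$values)[co$truth$condition_edges]),
      numeric(1))
    grp_s <- vapply(tc_s$runs, function(r) r$group_label, numeric(1))
    gdiff <- c(gdiff, mean(vals_g[grp_s == 1]) - mean(vals_g[grp_s == 0]))
    cdiff <- c(cdiff, mean(vals_c[grp_s == 1]) - mean(vals_c[grp_s == 0]))
  }
  expect_lt(abs(mean(gdiff) - mean(co$truth$delta_group)), 0.07)
  expect_lt(abs(mean(cdiff)), 0.03)
})
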