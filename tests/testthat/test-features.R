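make_run <- function(values, nuisance = NULL) {
  structure(list(values = values, participant_id = "sub-001",
                 group_label = 1, condition_label = 0, run_index = 1,
                 timepoint = 1,
                 nuisance = nuisance %||% matrix(0, nrow(values), 0)),
            class = "roi_run")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("residualization removes trend and nuisance structure", {
  t_len <- 60
  nuis <- matrix(rnorm(t_len), ncol = 1)
  ramp <- seq_len(t_len)
  run <- make_run(cbind(ramp, rnorm(t_len) + 2 * nuis[, 1], rnorm(t_len)),
                  nuisance = nuis)
  res <- residualize(run)
  # a pure linear ramp is annihilated
  expect_lt(max(abs(res$values[, 1])), 1e-10)
  # residuals orthogonal to the nuisance column
  expect_lt(abs(cor(res$values[, 2], nuis[, 1])), 1e-10)
  # idempotence
  res2 <- residualize(res)
  expect_lt(max(abs(res2$values - res$values)), 1e-10)
})

test_that("split-half augmentation partitions the run", {
  run <- make_run(matrix(rnorm(180 * 4), 180, 4))
  hs <- split_halves(run)
  expect_equal(nrow(hs$first$values), 90)
  expect_equal(nrow(hs$second$values), 90)
  expect_identical(rbind(hs$first$values, hs$second$values), run$values)

  run_odd <- make_run(matrix(rnorm(181 * 4), 181, 4))
  hs_odd <- split_halves(run_odd)
  expect_equal(nrow(hs_odd$first$values), 90)
  expect_equal(nrow(hs_odd$second$values), 91)
  expect_error(split_halves(make_run(matrix(1:12, 4, 3))), "8 time points")
})

test_that("pearson matrix honours exact dependencies and chance level", {
  x <- rnorm(50)
  m <- pearson_matrix(cbind(x, x, -x, rnorm(50)))
  expect_equal(m[1, 2], 1)
  expect_equal(m[1, 3], -1)
  expect_error(pearson_matrix(cbind(x, rep(1, 50))), "zero-variance")

  # mean |r| for independent normals, T = 90: sqrt(2 / (pi * (T - 1)))
  set.seed(4)
  rs <- replicate(200, {
    m <- pearson_matrix(matrix(rnorm(90 * 2), 90, 2))
    abs(m[1, 2])
  })
  expect_equal(mean(rs), sqrt(2 / (pi * 89)), tolerance = 0.15)
})

test_that("binned XMI attains its analytic values", {
  # strictly monotone pair, T a multiple of B: joint is diagonal -> log2(B)
  x <- as.numeric(1:96)
  m <- xmi_matrix(cbind(x, x^3), connectivity_config(xmi_bins = 8))
  expect_equal(m[1, 2], 3, tolerance = 1e-12)
  # diagonal = binned entropy (equal-frequency bins -> log2 B)
  expect_equal(m[1, 1], 3, tolerance = 1e-12)

  # degenerate column rejected
  expect_error(xmi_matrix(cbind(x, rep(c(1, 2), 48))), "degenerate")

  # independent columns: mean estimate within a factor of 2 of the
  # plug-in bias (B-1)^2 / (2 T ln 2)
  set.seed(5)
  v <- replicate(200, {
    m <- xmi_matrix(matrix(rnorm(90 * 2), 90, 2))
    m[1, 2]
  })
  bias <- 49 / (2 * 90 * log(2))
  expect_gt(mean(v), bias / 2)
  expect_lt(mean(v), bias * 2)

  # symmetric and invariant to monotone transforms (rank binning)
  set.seed(6)
  s <- matrix(rnorm(80 * 5), 80, 5)
  m1 <- xmi_matrix(s)
  expect_lt(max(abs(m1 - t(m1))), 1e-12)
  m2 <- xmi_matrix(exp(s))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("upper-triangle vectorization is row-major and invertible", {
  m3 <- matrix(c(0, 10, 20, 10, 0, 30, 20, 30, 0), 3, 3)
  v <- vectorize_upper(m3)
  expect_equal(v$features, c(10, 20, 30))

  expect_equal(nrow(feature_index_map(115)), 6555)

  # property: length N(N-1)/2 and exact round trip
  set.seed(7)
  for (n in c(3, 8, 17, 40, 130)) {
    s <- matrix(rnorm(n * n), n, n)
    s <- s + t(s); diag(s) <- 0
    v <- vectorize_upper(s)
    expect_length(v$features, n * (n - 1) / 2)
    expect_equal(unvectorize_upper(v$features, v$map), s, tolerance = 1e-12)
  }
  expect_error(vectorize_upper(matrix(1:6, 2, 3)), "square")
})

test_that("rescale-and-sqrt fixes endpoints and reduces positive skew", {
  expect_equal(rescale_and_sqrt(c(-1, 0, 1)), c(0, sqrt(0.5), 1))
  v <- c(0, 0.3, 0.6, 1)
  expect_equal(range(rescale_and_sqrt(v)), c(0, 1))
  expect_error(rescale_and_sqrt(rep(0.4, 10)), "constant")

  set.seed(8)
  x <- rnorm(2000)^2  # positively skewed
  skew <- function(z) mean((z - mean(z))^3) / sd(z)^3
  expect_lt(skew(rescale_and_sqrt(x)), skew(x))
  # rank order preserved
  expect_equal(order(rescale_and_sqrt(x)), order(x))
})

test_that("within-cluster masking drops exactly the flagged pairs", {
  assignment <- default_cluster_assignment(115)
  expect_equal(length(assignment), 115)
  map <- feature_index_map(115, assignment)
  expect_equal(sum(map$within_cluster), 253)

  ps <- tiny_patterns()
  full <- build_pattern_set(tiny_cohort(), apply_mask = FALSE)
  n_wc <- sum(full$map$within_cluster)
  expect_equal(ncol(ps$features), ncol(full$features) - n_wc)
  # surviving features keep their original ROI pair identity
  k <- sample(nrow(ps$map), 1)
  orig <- full$map[full$map$feature == ps$map$feature[k], ]
  expect_equal(c(orig$i, orig$j), c(ps$map$i[k], ps$map$j[k]))
  # empty mask is the identity
  same <- apply_feature_mask(full, rep(FALSE, nrow(full$map)))
  expect_identical(same$features, full$features)
  expect_error(apply_feature_mask(full, TRUE), "mask length")
})

test_that("pattern sets carry the full augmentation and labels", {
  co <- tiny_cohort()
  ps <- tiny_patterns()
  n_runs <- length(co$runs)
  expect_equal(nrow(ps$features), n_runs * 2 * 2)  # halves x methods
  expect_true(all(is.finite(ps$features)))
  expect_true(all(ps$features >= 0 & ps$features <= 1))
  expect_setequal(unique(ps$meta$lexicality_label), c("0", "1"))
  expect_setequal(unique(ps$meta$half), c("first", "second"))

  # word runs carry lexicality 1, pseudoword 0
  word_runs <- vapply(co$runs, function(r) identical(r$condition_label, 1L) ||
                        identical(r$condition_label, 1), logical(1))
  expect_equal(sum(ps$meta$lexicality_label == "1"),
               sum(word_runs) * 4)

  # pearson- and xmi-derived patterns from the same half are distinct views
  pe <- which(ps$meta$method == "pearson")[1]
  match_row <- which(ps$meta$method == "xmi" &
                     ps$meta$participant_id == ps$meta$participant_id[pe] &
                     ps$meta$run_index == ps$meta$run_index[pe] &
                     ps$meta$half == ps$meta$half[pe] &
                     ps$meta$lexicality_label == ps$meta$lexicality_label[pe])[1]
  expect_lt(cor(ps$features[pe, ], ps$features[match_row, ]), 0.999)
})

test_that("cross-method pattern correlation is positive but non-redundant", {
  ps <- medium_patterns()$patterns
  pe <- ps$meta$method == "pearson"
  xm <- ps$meta$method == "xmi"
  key <- function(m) paste(m$participant_id, m$lexicality_label,
                           m$run_index, m$half)
  ord <- match(key(ps$meta[pe, ]), key(ps$meta[xm, ]))
  cors <- vapply(seq_len(sum(pe)), function(r)
    cor(ps$features[which(pe)[r], ], ps$features[which(xm)[ord[r]], ]),
    numeric(1))
  expect_gt(mean(cors), 0)
  expect_lt(mean(cors), 0.9)
})
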