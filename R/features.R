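#' Feature index map for the strictly-upper-triangle vectorization
#'
#' Enumerates the ROI pairs `(i, j)` with `i < j` in row-major order — the
#' order in which [vectorize_upper()] emits features — and flags the pairs
#' falling inside one functional cluster (the "trivially correlated"
#' short-distance connections that are excluded before classification).
#'
#' @param n_roi Number of ROIs.
#' @param cluster_assignment Optional integer cluster id per ROI; when given,
#'   the `within_cluster` column marks same-cluster pairs.
#' @param roi_names Optional ROI names (default `roi_001`, ...).
#' @return A data.frame of class `feature_index_map` with columns `feature`,
#'   `i`, `j`, `within_cluster`, plus attribute `roi_names`.
#' @export
feature_index_map <- function(n_roi, cluster_assignment = NULL,
                              roi_names = sprintf("roi_%03d", seq_len(n_roi))) {
  stopifnot(n_roi >= 2)
  i <- rep(seq_len(n_roi - 1), times = (n_roi - 1):1)
  j <- unlist(lapply(seq_len(n_roi - 1), function(r) (r + 1):n_roi))
  wc <- if (is.null(cluster_assignment)) rep(FALSE, length(i)) else {
    stopifnot(length(cluster_assignment) == n_roi)
    cluster_assignment[i] == cluster_assignment[j]
  }
  map <- data.frame(feature = seq_along(i), i = i, j = j, within_cluster = wc)
  attr(map, "roi_names") <- roi_names
  class(map) <- c("feature_index_map", "data.frame")
  map
}

#' Remove trend and nuisance structure from a run
#'
#' Replaces every ROI time series by its least-squares residual against an
#' intercept, a linear trend, and the run's nuisance regressors (the
#' synthetic analogue of detrending plus white-matter/CSF regression).
#'
#' @param run An `roi_run`.
#' @return The run with residualized `values` (and a `residualized` flag).
#' @export
residualize <- function(run) {
  stopifnot(inherits(run, "roi_run"))
  y <- run$values
  t_len <- nrow(y)
  if (t_len < 4) stop_input("need at least 4 time points to residualize")
  x <- cbind(intercept = 1, trend = seq_len(t_len) - (t_len + 1) / 2,
             run$nuisance)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dep <- colnames(x)[setdiff(seq_len(ncol(x)), qrx$pivot[seq_len(qrx$rank)])]
    stop_input("rank-deficient nuisance design; dependent columns: ",
               paste(dep, collapse = ", "))
  }
  run$values <- qr.resid(qrx, y)
  run$residualized <- TRUE
  run
}

#' Split a run into its first and second half
#'
#' Split-half augmentation: the first half takes rows `1:floor(T/2)`, the
#' second the remainder; all labels are copied and the halves tagged.
#'
#' @param run An `roi_run` with at least 8 time points.
#' @return A list of two `roi_run` objects with a `half` field.
#' @export
split_halves <- function(run) {
  stopifnot(inherits(run, "roi_run"))
  t_len <- nrow(run$values)
  if (t_len < 8) stop_input("need at least 8 time points to split")
  cut <- floor(t_len / 2)
  make_half <- function(rows, tag) {
    h <- run
    h$values <- run$values[rows, , drop = FALSE]
    h$nuisance <- run$nuisance[rows, , drop = FALSE]
    h$half <- tag
    h
  }
  list(first = make_half(seq_len(cut), "first"),
       second = make_half((cut + 1):t_len, "second"))
}

#' Pearson correlation connectivity matrix
#'
#' @param series A time x ROI matrix with non-constant columns.
#' @return Symmetric unit-diagonal correlation matrix.
#' @export
pearson_matrix <- function(series) {
  stopifnot(is.matrix(series))
  v <- apply(series, 2, var)
  if (any(v <= 0)) {
    bad <- which(v <= 0)
    stop_input("zero-variance ROI column(s): ", paste(bad, collapse = ", "))
  }
  m <- cor(series)
  (m + t(m)) / 2
}

# Equal-frequency (quantile) binning into `bins` bins. Errors when the column
# has too few distinct values to occupy every bin.
quantile_bin <- function(x, bins) {
  if (length(unique(x)) < bins)
    stop_input("degenerate column: fewer than ", bins,
               " distinct values under quantile binning")
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(bins * r / length(x)))
}

#' Cross-mutual-information connectivity matrix
#'
#' Zero-lag plug-in mutual information (in bits) between every pair of ROI
#' time series after equal-frequency binning of each column into
#' `config$xmi_bins` bins. The diagonal holds the binned entropy of each
#' column. Quantile binning makes the estimate invariant to any monotone
#' transform of the series; a strictly monotone pair attains exactly
#' `log2(bins)` bits when `T` is a multiple of the bin count.
#'
#' @param series A time x ROI matrix, `nrow(series) >= bins`.
#' @param config A [connectivity_config()] (only `xmi_bins` is used).
#' @return Symmetric nonnegative ROI x ROI matrix in bits.
#' @export
xmi_matrix <- function(series, config = connectivity_config()) {
  stopifnot(is.matrix(series))
  bins <- config$xmi_bins
  t_len <- nrow(series)
  if (t_len < bins) stop_input("need at least ", bins, " time points")
  binned <- apply(series, 2, quantile_bin, bins = bins)
  storage.mode(binned) <- "integer"
  xmi_matrix_cpp(binned, bins, config$xmi_lag)
}

#' Vectorize the strictly-upper triangle of a symmetric matrix
#'
#' Emits the `N(N-1)/2` above-diagonal values in row-major order — pair
#' `(1,2), (1,3), ..., (1,N), (2,3), ...` — together with the feature map
#' identifying each value's ROI pair.
#'
#' @param matrix A square symmetric matrix.
#' @param map Optional precomputed [feature_index_map()] to reuse.
#' @return A list with `features` (numeric vector) and `map`.
#' @export
vectorize_upper <- function(matrix, map = NULL) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop_input("input must be a square matrix")
  n <- nrow(matrix)
  if (is.null(map)) map <- feature_index_map(n)
  if (nrow(map) != n * (n - 1) / 2)
    stop_input("feature map has ", nrow(map), " rows but a ", n, "-ROI ",
               "matrix vectorizes to ", n * (n - 1) / 2,
               " features (was a masked map passed?)")
  # row-major upper triangle == column-major lower triangle of the transpose
  tm <- t(matrix)
  list(features = tm[lower.tri(tm)], map = map)
}

#' Reconstruct a symmetric matrix from an upper-triangle feature vector
#'
#' Inverse of [vectorize_upper()] (diagonal set to `diag_value`).
#'
#' @param features Feature vector in row-major upper-triangle order.
#' @param map The [feature_index_map()] describing the vector.
#' @param diag_value Value placed on the diagonal (default 0).
#' @return A symmetric matrix.
#' @export
unvectorize_upper <- function(features, map, diag_value = 0) {
  stopifnot(length(features) == nrow(map))
  n <- max(map$j)
  m <- matrix(diag_value, n, n) * diag(n)
  m[cbind(map$i, map$j)] <- features
  m[cbind(map$j, map$i)] <- features
  diag(m) <- diag_value
  m
}

#' Min-max rescale to `[0, 1]` followed by a square-root transform
#'
#' The per-pattern min-max rescale maps connectivity values onto `[0, 1]`;
#' the square root then reduces the positive skew typical of connectivity
#' distributions. Rank order is preserved and `[0, 1]` is closed under both
#' steps.
#'
#' @param features A non-constant numeric vector.
#' @return Vector in `[0, 1]`.
#' @export
rescale_and_sqrt <- function(features) {
  rng <- range(features)
  if (!all(is.finite(rng))) stop_input("non-finite feature values")
  if (rng[2] - rng[1] <= 0) stop_input("constant feature vector: zero range")
  sqrt((features - rng[1]) / (rng[2] - rng[1]))
}

#' Connectivity featurization configuration
#'
#' @param methods Character subset of `c("pearson", "xmi")`.
#' @param xmi_bins Number of equal-frequency bins for the XMI estimator.
#' @param xmi_lag Time lag for XMI (default 0; nonzero lags shift the second
#'   series before binning).
#' @return An object of class `connectivity_config`.
#' @export
connectivity_config <- function(methods = c("pearson", "xmi"), xmi_bins = 8,
                                xmi_lag = 0) {
  methods <- match.arg(methods, c("pearson", "xmi"), several.ok = TRUE)
  stopifnot(xmi_bins >= 2, length(methods) >= 1)
  structure(list(methods = methods, xmi_bins = as.integer(xmi_bins),
                 xmi_lag = as.integer(xmi_lag)),
            class = "connectivity_config")
}

#' Drop within-cluster features from a pattern set
#'
#' Removes the masked (within-cluster) features from every pattern and from
#' the feature map; surviving features keep their original ROI-pair identity
#' and full-map feature index.
#'
#' @param set A `pattern_set`.
#' @param mask Logical vector over the set's current features (default: the
#'   map's `within_cluster` column); `TRUE` = drop.
#' @return The filtered `pattern_set`.
#' @export
apply_feature_mask <- function(set, mask = set$map$within_cluster) {
  stopifnot(inherits(set, "pattern_set"))
  if (length(mask) != nrow(set$map))
    stop_input("mask length ", length(mask), " != feature count ",
               nrow(set$map))
  keep <- !mask
  set$features <- set$features[, keep, drop = FALSE]
  set$map <- set$map[keep, , drop = FALSE]
  set
}

run_to_patterns <- function(run, config, map) {
  res <- if (isTRUE(run$residualized)) run else residualize(run)
  halves <- split_halves(res)
  out <- list()
  for (half in halves) {
    for (method in config$methods) {
      m <- if (method == "pearson") pearson_matrix(half$values)
           else xmi_matrix(half$values, config)
      vec <- vectorize_upper(m, map)$features
      out[[length(out) + 1L]] <- list(
        features = rescale_and_sqrt(vec),
        participant_id = run$participant_id,
        group_label = run$group_label,
        lexicality_label = run$condition_label,
        run_index = run$run_index,
        half = half$half,
        method = method)
    }
  }
  out
}

#' Build a labelled pattern set from a cohort's runs
#'
#' The full featurization path of the study: residualize each run, split it
#' in half, compute each enabled connectivity estimate on each half,
#' vectorize the upper triangle, min-max rescale and square-root transform,
#' and (optionally) drop the within-cluster feature mask. Each run therefore
#' contributes `2 x length(methods)` patterns carrying its labels.
#'
#' @param runs A `cohort` or list of `roi_run` objects.
#' @param config A [connectivity_config()].
#' @param map Optional [feature_index_map()]; defaults to the map implied by
#'   the first run (with the cohort's cluster assignment when available).
#' @param apply_mask Drop within-cluster features after featurization
#'   (default TRUE).
#' @return An object of class `pattern_set`: list with `features` (pattern x
#'   feature matrix), `meta` (data.frame of labels), `map`, `config`.
#' @export
build_pattern_set <- function(runs, config = connectivity_config(),
                              map = NULL, apply_mask = TRUE) {
  assignment <- NULL
  if (inherits(runs, "cohort")) {
    assignment <- runs$spec$cluster_assignment
    runs <- runs$runs
  }
  stopifnot(length(runs) >= 1)
  n_roi <- ncol(runs[[1]]$values)
  if (is.null(map)) map <- feature_index_map(n_roi, assignment)
  pats <- unlist(lapply(runs, run_to_patterns, config = config, map = map),
                 recursive = FALSE)
  features <- do.call(rbind, lapply(pats, `[[`, "features"))
  meta <- do.call(rbind, lapply(pats, function(p)
    data.frame(participant_id = p$participant_id,
               group_label = p$group_label,
               lexicality_label = as.character(p$lexicality_label),
               run_index = p$run_index, half = p$half, method = p$method,
               stringsAsFactors = FALSE)))
  set <- structure(list(features = features, meta = meta, map = map,
                        config = config), class = "pattern_set")
  if (apply_mask) set <- apply_feature_mask(set) else set
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: %d patterns x %d features (%d participants)\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$meta$participant_id))))
  invisible(x)
}

# Subset a pattern set's patterns (rows) and/or features (columns).
subset_patterns <- function(set, rows = NULL, feature_idx = NULL) {
  if (!is.null(rows)) {
    set$features <- set$features[rows, , drop = FALSE]
    set$meta <- set$meta[rows, , drop = FALSE]
  }
  if (!is.null(feature_idx)) {
    pos <- match(feature_idx, set$map$feature)
    if (anyNA(pos)) stop_input("unknown feature indices requested")
    set$features <- set$features[, pos, drop = FALSE]
    set$map <- set$map[pos, , drop = FALSE]
  }
  set
}
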