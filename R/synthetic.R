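#' Default ROI-to-cluster assignment
#'
#' The packaged parcellation emulates a task-defined set of 115 ROIs obtained
#' by subdividing functional clusters along anatomical boundaries: ten
#' multi-ROI clusters of sizes 10, 10, 10, 10, 9, 6, 5, 4, 3, 3 plus 45
#' singleton ROIs. The pairs of ROIs falling inside one multi-ROI cluster are
#' the "trivially correlated" short-distance connections; with these sizes
#' there are exactly `sum(k * (k - 1) / 2) = 253` such pairs.
#'
#' @param n_roi Number of ROIs (default 115). For other values the same
#'   cluster sizes are kept while they fit, so small test parcellations still
#'   have a non-empty within-cluster mask.
#' @return Integer vector of length `n_roi`: cluster id per ROI.
#' @export
default_cluster_assignment <- function(n_roi = 115) {
  stopifnot(n_roi >= 3)
  sizes <- c(10, 10, 10, 10, 9, 6, 5, 4, 3, 3)
  sizes <- sizes[cumsum(sizes) <= max(0, n_roi - 2)]
  assignment <- rep(seq_along(sizes), times = sizes)
  n_single <- n_roi - length(assignment)
  c(assignment, length(sizes) + seq_len(n_single))
}

#' Specification of a synthetic ROI time-series cohort
#'
#' Collects every knob of the synthetic-cohort generator. The defaults
#' reproduce the reference design the rest of the pipeline is tested against:
#' 14 + 14 participants, 115 ROIs, 4 word + 4 pseudoword runs of 180 volumes
#' at TR = 2 s (6 min), 40 planted group-coupling edges at +0.3 and 40
#' disjoint planted lexicality-coupling edges at +0.15, and a packaged
#' cluster assignment whose within-cluster mask holds 253 ROI pairs.
#'
#' @param n_per_group Participants per reading-skill group.
#' @param n_roi Number of ROIs.
#' @param runs_per_condition Runs per lexicality condition per participant.
#' @param volumes_per_run Time points per run.
#' @param tr_seconds Sampling interval in seconds (metadata only).
#' @param cluster_assignment Integer vector of cluster ids per ROI.
#' @param n_group_edges,n_condition_edges Number of planted edges per effect.
#' @param delta_group,delta_condition Correlation increments for planted
#'   edges (scalar or per-edge vector).
#' @param base_density Fraction of between-cluster ROI pairs given a nonzero
#'   background correlation.
#' @param base_strength Maximum magnitude of the background correlations.
#' @param within_cluster_r Background correlation inside multi-ROI clusters.
#' @param nuisance_amplitude Scale of the linear drift and of the two shared
#'   nuisance signals, relative to the unit-variance neural signal.
#' @param participant_jitter_sd SD of the per-participant perturbation of the
#'   between-cluster couplings: each participant carries an idiosyncratic,
#'   condition-stable connectivity fingerprint on top of the group/condition
#'   structure, emulating the stable individual differences that task-based
#'   connectomes show. Set to 0 for a cohort with no individual signature.
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   spec including this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 14,
                        n_roi = 115,
                        runs_per_condition = 4,
                        volumes_per_run = 180,
                        tr_seconds = 2.0,
                        cluster_assignment = default_cluster_assignment(n_roi),
                        n_group_edges = 40,
                        n_condition_edges = 40,
                        delta_group = 0.3,
                        delta_condition = 0.15,
                        base_density = 0.15,
                        base_strength = 0.3,
                        within_cluster_r = 0.5,
                        nuisance_amplitude = 0.5,
                        participant_jitter_sd = 0,
                        seed = 1L) {
  stopifnot(n_per_group >= 1, n_roi >= 3, runs_per_condition >= 1,
            volumes_per_run >= 4, length(cluster_assignment) == n_roi,
            n_group_edges >= 0, n_condition_edges >= 0,
            base_density >= 0, base_density <= 1,
            abs(base_strength) < 1, abs(within_cluster_r) < 1,
            nuisance_amplitude >= 0, participant_jitter_sd >= 0)
  spec <- list(n_per_group = as.integer(n_per_group),
               n_roi = as.integer(n_roi),
               runs_per_condition = as.integer(runs_per_condition),
               volumes_per_run = as.integer(volumes_per_run),
               tr_seconds = tr_seconds,
               cluster_assignment = as.integer(cluster_assignment),
               n_group_edges = as.integer(n_group_edges),
               n_condition_edges = as.integer(n_condition_edges),
               delta_group = delta_group,
               delta_condition = delta_condition,
               base_density = base_density,
               base_strength = base_strength,
               within_cluster_r = within_cluster_r,
               nuisance_amplitude = nuisance_amplitude,
               participant_jitter_sd = participant_jitter_sd,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

# Row-major strictly-upper-triangle feature index of pair (i, j), i < j.
upper_pair_index <- function(i, j, n) {
  stopifnot(all(i < j), all(j <= n), all(i >= 1))
  (i - 1) * n - i * (i + 1) / 2 + j
}

# All upper-triangle pairs of `assignment` lying inside one cluster of size>1.
within_cluster_pairs <- function(assignment) {
  n <- length(assignment)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  same <- assignment[pairs[, 1]] == assignment[pairs[, 2]]
  cbind(i = pairs[same, 1], j = pairs[same, 2])
}

#' Repair a symmetric matrix to a unit-diagonal PSD correlation
#'
#' Alternating projections between the positive-semidefinite cone
#' (eigenvalue clipping at a small floor, then rescaling back to unit
#' diagonal) and, optionally, the affine set holding a list of cells at
#' their requested values — so that planted couplings survive the repair
#' essentially unchanged. Off-diagonals are clipped to `[-0.99, 0.99]`.
#'
#' @param mat Symmetric matrix with unit diagonal (approximately).
#' @param eig_floor Eigenvalue floor used when clipping (default 1e-6).
#' @param max_iter Maximum repair iterations.
#' @param fixed_cells Optional two-column matrix of (i, j) cells to hold at
#'   their values in `mat` (clipped to `[-0.99, 0.99]`).
#' @return A symmetric positive-semidefinite correlation matrix.
#' @export
repair_correlation <- function(mat, eig_floor = 1e-6, max_iter = 200,
                               fixed_cells = NULL) {
  clip01 <- function(m) {
    off <- row(m) != col(m)
    m[off] <- pmin(pmax(m[off], -0.99), 0.99)
    diag(m) <- 1
    m
  }
  m <- clip01((mat + t(mat)) / 2)
  targets <- NULL
  if (!is.null(fixed_cells) && nrow(fixed_cells) > 0)
    targets <- pmin(pmax(m[fixed_cells], -0.99), 0.99)
  reinstate <- function(m) {
    if (is.null(targets)) return(m)
    m[fixed_cells] <- targets
    m[fixed_cells[, c(2, 1), drop = FALSE]] <- targets
    m
  }
  for (iter in seq_len(max_iter)) {
    ev <- eigen(m, symmetric = TRUE)
    if (min(ev$values) > 0) break
    vals <- pmax(ev$values, eig_floor)
    m <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    m <- reinstate(clip01((m + t(m)) / 2))
  }
  ev_min <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    if (!is.null(targets)) {
      # the requested cells are jointly infeasible (e.g. increments clipped
      # at the 0.99 bound on edges sharing a node); fall back to plain
      # clipping so the cells move as little as the PSD cone allows
      warning("planted cells are jointly infeasible as stated; ",
              "nearest-PSD repair moved them", call. = FALSE)
      return(repair_correlation(mat, eig_floor, max_iter))
    }
    stop_input("correlation repair failed to converge (min eigenvalue ",
               format(ev_min), ")")
  }
  m
}

#' Construct the generative covariance for one group x condition cell
#'
#' Starts from the shared base correlation matrix, adds the planted deltas of
#' the edges active for the requested group/condition, clips cells to
#' `[-0.99, 0.99]`, and repairs the result to the nearest unit-diagonal
#' positive-semidefinite correlation matrix.
#'
#' @param base Symmetric unit-diagonal base correlation matrix.
#' @param truth A `ground_truth` object (see [generate_cohort()]).
#' @param group 0 (poor) or 1 (highly skilled).
#' @param condition 0 (pseudoword), 1 (word), or `"transfer"`; planted
#'   condition edges are active for condition 1, and for `"transfer"` the
#'   transfer task edges (if any) are active instead.
#' @return A repaired correlation matrix.
#' @export
build_run_covariance <- function(base, truth, group, condition) {
  if (!is.matrix(base) || nrow(base) != ncol(base))
    stop_input("base must be a square matrix")
  if (max(abs(base - t(base))) > 1e-8)
    stop_input("base must be symmetric")
  m <- base
  add_edges <- function(m, edges, deltas) {
    if (is.null(edges) || nrow(edges) == 0) return(m)
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      m[i, j] <- m[i, j] + deltas[k]
      m[j, i] <- m[i, j]
    }
    m
  }
  active <- NULL
  if (identical(group, 1) || identical(group, 1L)) {
    m <- add_edges(m, truth$group_edges, truth$delta_group)
    active <- rbind(active, truth$group_edges)
  }
  if (identical(condition, 1) || identical(condition, 1L)) {
    m <- add_edges(m, truth$condition_edges, truth$delta_condition)
    active <- rbind(active, truth$condition_edges)
  } else if (identical(condition, "transfer")) {
    m <- add_edges(m, truth$transfer_edges, truth$delta_transfer)
    active <- rbind(active, truth$transfer_edges)
  }
  if (identical(m, base)) return(base)
  repair_correlation(m, fixed_cells = active)
}

sample_background <- function(spec) {
  n <- spec$n_roi
  m <- diag(n)
  wc <- within_cluster_pairs(spec$cluster_assignment)
  if (nrow(wc) > 0) {
    m[wc] <- spec$within_cluster_r
    m[wc[, c(2, 1), drop = FALSE]] <- spec$within_cluster_r
  }
  between <- which(upper.tri(m), arr.ind = TRUE)
  between <- between[spec$cluster_assignment[between[, 1]] !=
                       spec$cluster_assignment[between[, 2]], , drop = FALSE]
  n_bg <- round(spec$base_density * nrow(between))
  if (n_bg > 0) {
    pick <- between[sample.int(nrow(between), n_bg), , drop = FALSE]
    # predominantly positive couplings, as in empirical BOLD connectivity
    # (whose positively skewed distribution motivates the sqrt transform)
    vals <- runif(n_bg, -spec$base_strength / 3, spec$base_strength)
    m[pick] <- vals
    m[pick[, c(2, 1), drop = FALSE]] <- vals
  }
  list(base = repair_correlation(m), between = between)
}

sample_planted_edges <- function(between, n_group, n_cond) {
  need <- n_group + n_cond
  if (need > nrow(between))
    stop_input("not enough between-cluster pairs to plant ", need, " edges")
  pick <- between[sample.int(nrow(between), need), , drop = FALSE]
  list(group = pick[seq_len(n_group), , drop = FALSE],
       condition = pick[n_group + seq_len(n_cond), , drop = FALSE])
}

make_ground_truth <- function(spec, base, edges) {
  rep_len_num <- function(x, n) rep_len(as.numeric(x), n)
  truth <- list(
    group_edges = edges$group,
    condition_edges = edges$condition,
    delta_group = rep_len_num(spec$delta_group, nrow(edges$group)),
    delta_condition = rep_len_num(spec$delta_condition, nrow(edges$condition)),
    transfer_edges = NULL,
    delta_transfer = NULL,
    base = base,
    group_feature_idx = if (nrow(edges$group))
      as.integer(upper_pair_index(edges$group[, 1], edges$group[, 2],
                                  spec$n_roi)) else integer(0),
    condition_feature_idx = if (nrow(edges$condition))
      as.integer(upper_pair_index(edges$condition[, 1], edges$condition[, 2],
                                  spec$n_roi)) else integer(0)
  )
  class(truth) <- "ground_truth"
  truth
}

# Condition-stable idiosyncratic perturbation of the between-cluster
# couplings: one symmetric zero-diagonal jitter matrix per participant.
participant_jitter <- function(spec, between) {
  n <- spec$n_roi
  j <- matrix(0, n, n)
  if (spec$participant_jitter_sd > 0 && nrow(between) > 0) {
    vals <- rnorm(nrow(between), sd = spec$participant_jitter_sd)
    j[between] <- vals
    j[between[, c(2, 1), drop = FALSE]] <- vals
  }
  j
}

participant_chol <- function(cell_cov, jitter, spec) {
  cov <- if (any(jitter != 0)) repair_correlation(cell_cov + jitter)
         else cell_cov
  chol(cov + diag(1e-10, spec$n_roi))
}

simulate_run <- function(chol_upper, spec, participant_id, group, condition,
                         run_index, timepoint = 1L) {
  t_len <- spec$volumes_per_run
  n <- spec$n_roi
  z <- matrix(rnorm(t_len * n), t_len, n)
  values <- z %*% chol_upper
  # nuisance: linear drift (per-ROI slope) + two shared signals with
  # per-ROI loadings, all scaled by nuisance_amplitude
  ramp <- seq(-0.5, 0.5, length.out = t_len)
  slopes <- rnorm(n, sd = spec$nuisance_amplitude)
  freq <- runif(1, 1, 3)
  phase <- runif(1, 0, 2 * pi)
  s1 <- sin(2 * pi * freq * seq_len(t_len) / t_len + phase)
  rw <- cumsum(rnorm(t_len))
  s2 <- (rw - mean(rw)) / max(sd(rw), 1e-12)
  nuisance <- cbind(s1, s2)
  loadings <- matrix(rnorm(2 * n, sd = spec$nuisance_amplitude), 2, n)
  values <- values + outer(ramp, slopes) + nuisance %*% loadings
  structure(list(values = values,
                 participant_id = participant_id,
                 group_label = group,
                 condition_label = condition,
                 run_index = run_index,
                 timepoint = timepoint,
                 nuisance = nuisance),
            class = "roi_run")
}

#' Generate a synthetic two-group, two-condition ROI time-series cohort
#'
#' Each run is a stationary zero-mean multivariate normal draw from the
#' group/condition covariance (the shared base correlation plus planted
#' deltas, PSD-repaired), with an added linear drift and two shared nuisance
#' signals. Ground truth (which edges carry which effect) is returned
#' alongside so downstream recovery can be scored. The output is a
#' deterministic function of the spec.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort` with `runs` (list of `roi_run`), `truth`
#'   (a `ground_truth`), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    bg <- sample_background(spec)
    edges <- sample_planted_edges(bg$between, spec$n_group_edges,
                                  spec$n_condition_edges)
    truth <- make_ground_truth(spec, bg$base, edges)
    cell_cov <- list()
    for (g in 0:1) for (cnd in 0:1)
      cell_cov[[paste(g, cnd)]] <- build_run_covariance(bg$base, truth, g, cnd)
    runs <- list()
    pid <- 0L
    for (g in 0:1) {
      for (p in seq_len(spec$n_per_group)) {
        pid <- pid + 1L
        id <- sprintf("sub-%03d", pid)
        jit <- participant_jitter(spec, bg$between)
        for (cnd in 0:1) {
          ch <- participant_chol(cell_cov[[paste(g, cnd)]], jit, spec)
          for (r in seq_len(spec$runs_per_condition)) {
            runs[[length(runs) + 1L]] <-
              simulate_run(ch, spec, id, g, cnd, r)
          }
        }
      }
    }
    structure(list(runs = runs, truth = truth, spec = spec), class = "cohort")
  })
}

#' Generate a transfer cohort sharing the training cohort's group fingerprint
#'
#' Emulates a second task administered to fresh participants drawn from the
#' same population: the planted group edges and their deltas are inherited
#' from the training ground truth, while a fresh, independent set of task
#' edges (same count and delta as the training condition edges) replaces the
#' lexicality coupling. All runs carry `condition_label = "transfer"`.
#'
#' @param spec A [cohort_spec()] describing the transfer cohort (typically
#'   `n_per_group = 5`); its `runs_per_condition` is the number of transfer
#'   task runs per participant.
#' @param truth The `ground_truth` of a previously generated training cohort.
#' @return A `cohort` whose `truth` carries the inherited group edges plus
#'   the fresh `transfer_edges`.
#' @export
generate_transfer_cohort <- function(spec, truth) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ground_truth"))
  if (nrow(truth$base) != spec$n_roi)
    stop_input("spec n_roi does not match the training ground truth")
  with_seed(derive_seed(spec$seed, "transfer"), {
    assignment <- spec$cluster_assignment
    between <- which(upper.tri(truth$base), arr.ind = TRUE)
    between <- between[assignment[between[, 1]] != assignment[between[, 2]], ,
                       drop = FALSE]
    taken <- c(if (nrow(truth$group_edges)) truth$group_feature_idx,
               if (nrow(truth$condition_edges)) truth$condition_feature_idx)
    idx_all <- upper_pair_index(between[, 1], between[, 2], spec$n_roi)
    free <- between[!(idx_all %in% taken), , drop = FALSE]
    n_task <- nrow(truth$condition_edges)
    if (n_task > nrow(free))
      stop_input("not enough free between-cluster pairs for transfer task edges")
    task <- free[sample.int(nrow(free), n_task), , drop = FALSE]
    truth2 <- truth
    truth2$transfer_edges <- task
    truth2$delta_transfer <- rep_len(mean(truth$delta_condition), n_task)
    cell_cov <- list()
    for (g in 0:1)
      cell_cov[[as.character(g)]] <-
        build_run_covariance(truth$base, truth2, g, "transfer")
    runs <- list()
    pid <- 0L
    for (g in 0:1) {
      for (p in seq_len(spec$n_per_group)) {
        pid <- pid + 1L
        id <- sprintf("tsub-%03d", pid)
        jit <- participant_jitter(spec, between)
        ch <- participant_chol(cell_cov[[as.character(g)]], jit, spec)
        for (r in seq_len(spec$runs_per_condition)) {
          runs[[length(runs) + 1L]] <-
            simulate_run(ch, spec, id, g, "transfer", r)
        }
      }
    }
    structure(list(runs = runs, truth = truth2, spec = spec), class = "cohort")
  })
}
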