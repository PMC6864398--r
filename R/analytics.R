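#' Dynamic time warping distance between two series
#'
#' Dynamic-programming accumulated cost with absolute-difference local cost,
#' boundary-anchored warping path and no window constraint. Step patterns:
#' `"symmetric1"` uses `D(i,j) = d(i,j) + min(D(i-1,j-1), D(i-1,j), D(i,j-1))`;
#' `"symmetric2"` doubles the local cost on diagonal steps (the convention of
#' the reference DTW package).
#'
#' @param x,y numeric series (non-empty, possibly different lengths).
#' @param step_pattern `"symmetric1"` (default) or `"symmetric2"`.
#' @return Accumulated cost (>= 0).
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2))  # 1
#' @export
dtw_distance <- function(x, y, step_pattern = c("symmetric1", "symmetric2")) {
  step_pattern <- match.arg(step_pattern)
  if (!length(x) || !length(y)) stop("empty series")
  .dtw_cpp(as.numeric(x), as.numeric(y), step_pattern == "symmetric2")
}

#' Hierarchical clustering of trajectories
#'
#' Pairwise distances (DTW, Manhattan or Euclidean) followed by agglomerative
#' clustering (Lance-Williams updates via [stats::hclust()]) and a cut at `k`
#' clusters. Ward linkage uses the `ward.D2` convention (Ward's criterion on
#' squared distances).
#'
#' @param set a `trajectory_set`.
#' @param metric `"dtw"`, `"manhattan"` or `"euclidean"`.
#' @param linkage `"ward"`, `"complete"`, `"average"` or `"single"`.
#' @param k number of clusters (1 <= k <= number of cells).
#' @param step_pattern DTW step pattern (when `metric = "dtw"`).
#' @return An object of class `cluster_result`: list with `labels` (integer
#'   vector in 1..k), `hclust` (the dendrogram), `k`, `metric`, `linkage`.
#' @export
hcluster <- function(set, metric = c("dtw", "manhattan", "euclidean"),
                     linkage = c("ward", "complete", "average", "single"),
                     k, step_pattern = "symmetric1") {
  stopifnot(inherits(set, "trajectory_set"))
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  if (k < 1) stop("k must be >= 1")
  if (k > n_cells(set)) stop("k exceeds the number of cells")
  dmat <- switch(metric,
    dtw = stats::as.dist(.dtw_pairwise_cpp(set$values,
                                           step_pattern == "symmetric2")),
    manhattan = stats::dist(set$values, method = "manhattan"),
    euclidean = stats::dist(set$values, method = "euclidean"))
  hc <- stats::hclust(dmat, method = if (linkage == "ward") "ward.D2" else linkage)
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = unname(labels), hclust = hc, k = k,
                 metric = metric, linkage = linkage),
            class = "cluster_result")
}

#' Per-cluster mean curves and per-condition composition
#'
#' @param set a `trajectory_set`.
#' @param labels integer cluster labels, one per cell.
#' @param condition optional character vector of per-cell condition labels;
#'   default `treatment` pasted with `dose_ng_ml` from the metadata.
#' @return List with `means` (k x timepoints), `ci_half` (1.96 sd/sqrt(n),
#'   the normal-approximation 95 percent CI half-width), `n` (cells per
#'   cluster) and `composition` (conditions x clusters fractions, rows sum
#'   to 1; empty clusters get fraction 0).
#' @export
cluster_summary <- function(set, labels, condition = NULL) {
  stopifnot(inherits(set, "trajectory_set"),
            length(labels) == n_cells(set))
  ks <- sort(unique(labels))
  means <- t(vapply(ks, function(kk)
    colMeans(set$values[labels == kk, , drop = FALSE]), numeric(length(set$time))))
  sds <- t(vapply(ks, function(kk) {
    v <- set$values[labels == kk, , drop = FALSE]
    if (nrow(v) > 1) apply(v, 2, stats::sd) else rep(0, ncol(v))
  }, numeric(length(set$time))))
  nk <- vapply(ks, function(kk) sum(labels == kk), integer(1))
  ci <- 1.96 * sds / sqrt(nk)
  rownames(means) <- rownames(ci) <- paste0("cluster_", ks)
  if (is.null(condition))
    condition <- paste(set$meta$treatment, set$meta$dose_ng_ml, sep = "_")
  tab <- table(condition, factor(labels, levels = ks))
  comp <- sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/")
  colnames(comp) <- paste0("cluster_", ks)
  list(means = means, ci_half = ci, n = stats::setNames(nk, rownames(means)),
       composition = comp, time = set$time)
}

#' Jeffries-Matusita distance between two normalized histograms
#'
#' `d_JM = sum_i (sqrt(p_i) - sqrt(q_i))^2 = 2 (1 - sum_i sqrt(p_i q_i))`,
#' i.e. twice one minus the Bhattacharyya coefficient. Bounded on `[0, 2]`:
#' 0 for identical histograms and 2 for histograms with disjoint support,
#' however far apart they are.
#'
#' @param p,q non-negative histogram masses on a shared binning, each summing
#'   to 1 (within `1e-8`).
#' @return Distance in `[0, 2]`.
#' @examples
#' jm_distance(c(1, 0), c(0, 1))        # 2
#' jm_distance(c(1, 0), c(0.5, 0.5))    # 2 - sqrt(2)
#' @export
jm_distance <- function(p, q) {
  if (length(p) != length(q)) stop("histograms must share their binning")
  if (any(p < 0) || any(q < 0)) stop("histogram masses must be non-negative")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("histograms must be normalized to sum 1")
  sum((sqrt(p) - sqrt(q))^2)
}

#' Separability of two trajectory populations over time
#'
#' At every timepoint, the values of the two populations are binned on shared
#' equal-width bins spanning their pooled range and the Jeffries-Matusita
#' distance between the two normalized histograms is computed. The normalized
#' population distance is the area under the d_JM(t) curve as a fraction of
#' its maximum (`2 * dt * N`), i.e. `mean_k d_JM(k) / 2`, in `[0, 1]`.
#' If the pooled range at a timepoint is degenerate (all values equal in both
#' populations), d_JM is 0 there.
#'
#' @param a,b `trajectory_set`s on identical time grids.
#' @param n_bins number of histogram bins (>= 2; default 20).
#' @return An object of class `separability_result`: list with `time`,
#'   `d_jm` (per-timepoint distances), `dt` and `d_popul`.
#' @export
population_distance <- function(a, b, n_bins = 20) {
  stopifnot(inherits(a, "trajectory_set"), inherits(b, "trajectory_set"),
            n_bins >= 2)
  if (length(a$time) != length(b$time) ||
      max(abs(a$time - b$time)) > 1e-9)
    stop("mismatched time grids")
  djm <- vapply(seq_along(a$time), function(k) {
    va <- a$values[, k]; vb <- b$values[, k]
    rng <- range(c(va, vb))
    if (diff(rng) == 0) return(0)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    p <- tabulate(pmin(findInterval(va, edges, rightmost.closed = TRUE),
                       n_bins), n_bins) / length(va)
    q <- tabulate(pmin(findInterval(vb, edges, rightmost.closed = TRUE),
                       n_bins), n_bins) / length(vb)
    jm_distance(p, q)
  }, numeric(1))
  dt <- if (length(a$time) > 1) a$time[2] - a$time[1] else 1
  structure(list(time = a$time, d_jm = djm, dt = dt,
                 d_popul = mean(djm) / 2),
            class = "separability_result")
}

#' @export
print.separability_result <- function(x, ...) {
  cat(sprintf("separability_result: d_popul = %.4f over %d timepoints\n",
              x$d_popul, length(x$time)))
  invisible(x)
}

#' Pairwise separability matrix and dendrogram over conditions
#'
#' @param sets named list (>= 2) of `trajectory_set`s on a common grid.
#' @param n_bins histogram bins passed to [population_distance()].
#' @return List with `distance` (symmetric matrix, zero diagonal) and
#'   `hclust` (complete-linkage tree over conditions).
#' @export
separability_dendrogram <- function(sets, n_bins = 20) {
  if (length(sets) < 2) stop("need at least two conditions")
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("condition_", seq_along(sets))
  n <- length(sets)
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      d <- population_distance(sets[[i]], sets[[j]], n_bins)$d_popul
      m[i, j] <- d; m[j, i] <- d
    }
  list(distance = m, hclust = stats::hclust(stats::as.dist(m),
                                            method = "complete"))
}

#' PCA projection of trajectory sets
#'
#' Centered (unscaled) principal components of the cells-by-timepoints
#' matrix; an optional extra set (for example an unstimulated control) is
#' rotated into the fitted basis without refitting.
#'
#' @param set a `trajectory_set` (>= 2 cells).
#' @param extra optional `trajectory_set` on the same grid to project.
#' @return List with `scores`, `extra_scores` (or NULL), `explained`
#'   (variance fractions summing to 1) and the `prcomp` fit.
#' @export
pca_project <- function(set, extra = NULL) {
  stopifnot(inherits(set, "trajectory_set"), n_cells(set) >= 2)
  fit <- stats::prcomp(set$values, center = TRUE, scale. = FALSE)
  if (all(fit$sdev == 0)) stop("degenerate (rank-0) trajectory matrix")
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  extra_scores <- NULL
  if (!is.null(extra)) {
    stopifnot(inherits(extra, "trajectory_set"),
              length(extra$time) == length(set$time))
    extra_scores <- scale(extra$values, center = fit$center,
                          scale = FALSE) %*% fit$rotation
  }
  list(scores = fit$x, extra_scores = extra_scores, explained = expl,
       fit = fit)
}

#' Classify a trajectory as in-phase or anti-phase with a pulse train
#'
#' The trajectory restricted to the window from the second pulse onward is
#' mean-centered and correlated with the mean-centered stimulus square wave
#' at lag zero and at a lag of half the pulse period. `in_phase` requires the
#' lag-zero correlation to dominate and exceed +0.3; `anti_phase` requires
#' the half-period correlation to dominate with lag-zero correlation below
#' -0.3; anything else is `undetermined`. The first pulse is excluded because
#' the initial response transient is in phase at any dose.
#'
#' @param trajectory numeric series on the schedule grid.
#' @param schedule a multi-pulse `pulse_schedule` with at least 3 pulses of
#'   equal width and spacing.
#' @return `"in_phase"`, `"anti_phase"` or `"undetermined"`.
#' @export
classify_phase <- function(trajectory, schedule) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  eps <- schedule$episodes
  if (nrow(eps) < 3) stop("need at least 3 pulses")
  grid <- sample_grid(schedule)
  if (length(trajectory) != nrow(grid))
    stop("trajectory must be on the schedule grid")
  period <- eps$onset[2] - eps$onset[1]
  half_lag <- max(1, round(period / 2 / schedule$grid_step_min))
  t0 <- eps$onset[2]
  t1 <- min(eps$onset[nrow(eps)] + period, schedule$total_min)
  sel <- grid$time_min >= t0 & grid$time_min <= t1
  y <- trajectory[sel]
  u <- as.numeric(grid$dose_ng_ml[sel] > 0)
  idx <- which(sel)
  idx_sh <- idx - half_lag
  ok <- idx_sh >= 1
  y0 <- y - mean(y); u0 <- u - mean(u)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  c_lag0 <- safe_cor(y0, u0)
  c_half <- safe_cor(trajectory[idx_sh[ok]] - mean(trajectory[idx_sh[ok]]),
                     u0[ok])
  if (c_lag0 >= c_half && c_lag0 > 0.3) return("in_phase")
  if (c_half > c_lag0 && c_lag0 < -0.3) return("anti_phase")
  "undetermined"
}
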