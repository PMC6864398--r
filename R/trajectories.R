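#' Single-cell trajectory sets
#'
#' A `trajectory_set` stores a cells-by-timepoints value matrix on a common,
#' uniformly spaced time grid, together with per-cell metadata (cell id,
#' treatment label, dose).
#'
#' @param values numeric matrix, one row per cell.
#' @param time numeric vector of timepoints (minutes), strictly increasing
#'   with uniform step, length `ncol(values)`.
#' @param meta data.frame with one row per cell; columns `cell_id`,
#'   `treatment`, `dose_ng_ml` (filled with defaults if missing).
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(values, time, meta = NULL) {
  values <- as.matrix(values)
  if (length(time) != ncol(values))
    stop("time length must match number of columns")
  if (length(time) > 1) {
    steps <- diff(time)
    if (any(steps <= 0)) stop("time must be strictly increasing")
    if (max(steps) - min(steps) > 1e-9 * max(steps, 1))
      stop("time grid must be uniform")
  }
  if (any(!is.finite(values))) stop("values must be finite (no missing values)")
  n <- nrow(values)
  if (is.null(meta)) meta <- data.frame(cell_id = as.character(seq_len(n)))
  if (is.null(meta$cell_id)) meta$cell_id <- as.character(seq_len(n))
  if (is.null(meta$treatment)) meta$treatment <- ""
  if (is.null(meta$dose_ng_ml)) meta$dose_ng_ml <- NA_real_
  if (nrow(meta) != n) stop("meta must have one row per cell")
  rownames(values) <- meta$cell_id
  structure(list(values = values, time = time, meta = meta),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("trajectory_set:", nrow(x$values), "cells x", length(x$time),
      "timepoints, t in [", min(x$time), ",", max(x$time), "] min\n")
  invisible(x)
}

#' @export
dim.trajectory_set <- function(x) dim(x$values)

#' Number of cells in a trajectory set
#' @param set a `trajectory_set`.
#' @export
n_cells <- function(set) nrow(set$values)

#' Subset a trajectory set by cells
#' @param set a `trajectory_set`.
#' @param idx logical or integer cell index.
#' @export
subset_cells <- function(set, idx) {
  trajectory_set(set$values[idx, , drop = FALSE], set$time,
                 set$meta[idx, , drop = FALSE])
}

#' Normalize trajectories to their own pre-stimulation baseline
#'
#' Each trajectory is divided by its own mean over the baseline window
#' (typically `t` in `[0, 40]` or `[36, 40]` minutes). Cells with a
#' non-positive baseline mean cannot be normalized; they are dropped with a
#' message, and the count is recorded in the `dropped` attribute.
#'
#' @param set a `trajectory_set`.
#' @param window `c(t0, t1)` baseline window in minutes (closed interval).
#' @return Normalized `trajectory_set`.
#' @export
normalize_baseline <- function(set, window = c(0, 40)) {
  stopifnot(inherits(set, "trajectory_set"), length(window) == 2)
  sel <- set$time >= window[1] & set$time <= window[2]
  if (!any(sel)) stop("baseline window contains no timepoints")
  base <- rowMeans(set$values[, sel, drop = FALSE])
  bad <- !(base > 0)
  if (any(bad)) {
    message(sum(bad), " cell(s) dropped: non-positive baseline mean")
    set <- subset_cells(set, !bad)
    base <- base[!bad]
  }
  out <- trajectory_set(set$values / base, set$time, set$meta)
  attr(out, "dropped") <- sum(bad)
  out
}

#' Read single-cell trajectories from a long-format CSV
#'
#' Expected columns: `cell_id`, `treatment`, `dose_ng_ml`, `time_min`,
#' `value`. Rows with missing values are dropped (and counted in the
#' `dropped_rows` attribute); cells are ordered by first appearance.
#'
#' @param path CSV file path.
#' @param treatment,dose optional condition filter.
#' @return A `trajectory_set`.
#' @export
read_trajectories <- function(path, treatment = NULL, dose = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- as.data.frame(data.table::fread(path))
  need <- c("cell_id", "treatment", "dose_ng_ml", "time_min", "value")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("malformed trajectory table, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  n0 <- nrow(dt)
  # metadata may legitimately be NA (e.g. dose for untreated controls);
  # only missing identifiers, times or values invalidate a row
  dt <- dt[stats::complete.cases(dt[, c("cell_id", "time_min", "value")]), ,
           drop = FALSE]
  dropped <- n0 - nrow(dt)
  if (!is.null(treatment)) dt <- dt[dt$treatment %in% treatment, ]
  if (!is.null(dose)) dt <- dt[dt$dose_ng_ml %in% dose, ]
  if (nrow(dt) == 0) stop("empty selection")
  cells <- unique(dt$cell_id)
  tt <- sort(unique(dt$time_min))
  mat <- matrix(NA_real_, length(cells), length(tt),
                dimnames = list(cells, NULL))
  mat[cbind(match(dt$cell_id, cells), match(dt$time_min, tt))] <- dt$value
  if (any(is.na(mat))) stop("non-uniform grid: cells observed at different times")
  first <- dt[!duplicated(dt$cell_id), ]
  meta <- data.frame(cell_id = as.character(first$cell_id),
                     treatment = first$treatment,
                     dose_ng_ml = first$dose_ng_ml)
  out <- trajectory_set(mat, tt, meta)
  attr(out, "dropped_rows") <- dropped
  out
}

#' Write a trajectory set as a long-format CSV
#'
#' Deterministic row order (cell, then time); values round-trip exactly
#' through [read_trajectories()].
#'
#' @param set a `trajectory_set`.
#' @param path output CSV path.
#' @export
write_trajectories <- function(set, path) {
  stopifnot(inherits(set, "trajectory_set"))
  n <- n_cells(set); m <- length(set$time)
  dt <- data.table::data.table(
    cell_id = rep(set$meta$cell_id, each = m),
    treatment = rep(set$meta$treatment, each = m),
    dose_ng_ml = rep(set$meta$dose_ng_ml, each = m),
    time_min = rep(set$time, times = n),
    # 17 significant digits: doubles round-trip exactly through the text
    value = sprintf("%.17g", as.vector(t(set$values))))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}
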