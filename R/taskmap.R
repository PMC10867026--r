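#' Specification of the 5x5 target grid
#'
#' The task workspace is a square grid of `n_rows` x `n_cols` cells. Continuous
#' cursor coordinates live in `[0, n_cols * cell_extent] x [0, n_rows *
#' cell_extent]` grid units, with row 1 at the top: cell `(i, j)` occupies
#' `x` in `[(j-1), j) * cell_extent` and `y` in `[(i-1), i) * cell_extent`
#' (half-open, so boundary positions belong to exactly one cell).
#'
#' @param n_rows,n_cols Grid dimensions (default 5 x 5).
#' @param cell_extent Side length of one cell in grid units.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(n_rows = 5L, n_cols = 5L, cell_extent = 1) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_extent > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_extent = cell_extent),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, cell extent %g grid units\n",
              x$n_rows, x$n_cols, x$cell_extent))
  invisible(x)
}

grid_center <- function(grid = grid_spec()) {
  c(x = grid$n_cols * grid$cell_extent / 2,
    y = grid$n_rows * grid$cell_extent / 2)
}

#' Cell numbering on the 5x5 grid
#'
#' Cells are numbered `k = 5 i + j - 5` from row index `i` and column index
#' `j` (both 1-based, row 1 at top), so `k` runs 1..25 left-to-right,
#' top-to-bottom. `cell_index()` and `cell_coords()` are mutual inverses.
#'
#' @param i,j Row and column indices in `1..n_rows`, `1..n_cols`.
#' @param k Cell number in `1..n_rows*n_cols`.
#' @param grid A [grid_spec()].
#' @return `cell_index()`: integer cell numbers. `cell_coords()`: a tibble
#'   with columns `i`, `j`. `cell_center()`: a tibble with the cell-center
#'   coordinates `x`, `y` in grid units.
#' @export
cell_index <- function(i, j, grid = grid_spec()) {
  if (any(i < 1 | i > grid$n_rows | j < 1 | j > grid$n_cols) ||
      any(i != round(i)) || any(j != round(j))) {
    stop("cell_index: (i, j) must be integers within the grid", call. = FALSE)
  }
  as.integer(grid$n_cols * i + j - grid$n_cols)
}

#' @rdname cell_index
#' @export
cell_coords <- function(k, grid = grid_spec()) {
  n_cells <- grid$n_rows * grid$n_cols
  if (any(k < 1 | k > n_cells) || any(k != round(k))) {
    stop("cell_coords: k must be an integer in 1..", n_cells, call. = FALSE)
  }
  tibble::tibble(
    i = as.integer((k - 1) %/% grid$n_cols + 1),
    j = as.integer((k - 1) %% grid$n_cols + 1)
  )
}

#' @rdname cell_index
#' @export
cell_center <- function(k, grid = grid_spec()) {
  ij <- cell_coords(k, grid)
  tibble::tibble(
    x = (ij$j - 0.5) * grid$cell_extent,
    y = (ij$i - 0.5) * grid$cell_extent
  )
}

#' Cell containing a continuous cursor position
#'
#' Positions outside the grid bounds get `NA` (the off-grid sentinel).
#'
#' @param x,y Cursor coordinates in grid units (vectorized).
#' @param grid A [grid_spec()].
#' @return Integer vector of cell numbers, `NA` where off-grid.
#' @export
cell_at <- function(x, y, grid = grid_spec()) {
  ce <- grid$cell_extent
  j <- floor(x / ce) + 1
  i <- floor(y / ce) + 1
  ok <- is.finite(x) & is.finite(y) &
    i >= 1 & i <= grid$n_rows & j >= 1 & j <= grid$n_cols
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(grid$n_cols * i[ok] + j[ok] - grid$n_cols)
  out
}

#' Printed target sequences of the main session
#'
#' Each 12-trial block visits four target cells in a fixed order: variant 1
#' (triangle) uses cells 13, 3, 25, 21; variant 2 (inverted triangle) uses
#' cells 13, 23, 5, 1. Each target appears exactly three times per block and
#' the cyclically repeated sequence traverses all 12 ordered pairs of the four
#' targets.
#'
#' @param variant 1 or 2.
#' @return Integer vector of 12 target cell numbers.
#' @export
target_sequence <- function(variant) {
  stopifnot(length(variant) == 1)
  switch(as.character(variant),
    "1" = c(13L, 3L, 25L, 21L, 13L, 25L, 3L, 21L, 25L, 13L, 21L, 3L),
    "2" = c(13L, 23L, 5L, 1L, 13L, 5L, 23L, 1L, 5L, 13L, 1L, 23L),
    stop("target_sequence: variant must be 1 or 2", call. = FALSE)
  )
}

#' Count distinct target-to-target transition paths
#'
#' A path is an ordered pair of distinct consecutive targets. With
#' `cyclic = TRUE` the wrap-around pair (last trial of one block to the first
#' trial of the next repeat) is included, matching back-to-back block repeats.
#'
#' @param seq Integer vector of target cells.
#' @param cyclic Include the last-to-first pair? Default `TRUE`.
#' @return Number of distinct ordered pairs with distinct endpoints.
#' @export
count_transition_paths <- function(seq, cyclic = TRUE) {
  stopifnot(length(seq) >= 1)
  from <- seq
  to <- c(seq[-1], seq[1])
  if (!cyclic) {
    from <- from[-length(from)]
    to <- to[-length(to)]
  }
  keep <- from != to
  nrow(dplyr::distinct(tibble::tibble(from = from[keep], to = to[keep])))
}

#' Trial success rate from a cursor trajectory
#'
#' The proportion of trajectory samples whose containing grid cell equals the
#' target cell -- the fraction of the trial during which the target shows red.
#'
#' @param traj Data frame with columns `x`, `y` (grid units), one row per
#'   sample of a single trial.
#' @param target_cell Target cell number.
#' @param grid A [grid_spec()].
#' @return Scalar in `[0, 1]`.
#' @export
success_rate <- function(traj, target_cell, grid = grid_spec()) {
  stopifnot(is.data.frame(traj), all(c("x", "y") %in% names(traj)))
  if (nrow(traj) == 0) stop("success_rate: empty trajectory", call. = FALSE)
  cells <- cell_at(traj$x, traj$y, grid)   # off-grid samples are never on target
  mean(!is.na(cells) & cells == target_cell)
}

sensor_matrix <- function(calib) {
  if (is.matrix(calib)) {
    s <- calib
  } else {
    stopifnot(is.data.frame(calib))
    cols <- paste0("s", 1:14)
    if (!all(cols %in% names(calib))) {
      stop("calibration data must have sensor columns s1..s14", call. = FALSE)
    }
    s <- as.matrix(calib[cols])
  }
  if (ncol(s) != 14) stop("expected 14 sensor channels", call. = FALSE)
  if (!all(is.finite(s))) stop("non-finite sensor values", call. = FALSE)
  s
}

#' Fit the hand-to-cursor mapping by PCA
#'
#' The two rows of the mapping matrix `A` are the first two principal
#' components of the sensor covariance from free-movement calibration data,
#' so the cursor `r = A s + r0` tracks the two dominant directions of finger
#' motion. The sign of each component is fixed so its largest-magnitude
#' loading is positive. With `scale = "grid"` (default) each row is scaled so
#' +/-2 SD of the corresponding latent PC score spans the grid, and the offset
#' `r0` places the calibration-mean posture at the grid center; with
#' `scale = "unit"` the rows stay unit-norm principal axes.
#'
#' @param calib Calibration data: a data frame with columns `s1..s14` (e.g.
#'   from [simulate_calibration()]) or an n x 14 matrix.
#' @param grid A [grid_spec()].
#' @param scale `"grid"` or `"unit"` (see Details).
#' @return A `cursor_mapping` object with fields `A` (2 x 14), `r0`
#'   (length 2), `score_sd` (SDs of the two PC scores), `center` (mean
#'   posture) and the grid.
#' @export
fit_mapping <- function(calib, grid = grid_spec(), scale = c("grid", "unit")) {
  scale <- match.arg(scale)
  s <- sensor_matrix(calib)
  if (nrow(s) < 15) stop("fit_mapping: need at least 15 calibration frames",
                         call. = FALSE)
  cv <- stats::cov(s)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= max(eg$values[1] * 1e-10, 0)) {
    stop("fit_mapping: degenerate calibration (sensor covariance rank < 2)",
         call. = FALSE)
  }
  v <- t(eg$vectors[, 1:2, drop = FALSE])   # 2 x 14, unit-norm rows
  for (r in 1:2) {
    if (v[r, which.max(abs(v[r, ]))] < 0) v[r, ] <- -v[r, ]
  }
  ctr <- colMeans(s)
  score_sd <- sqrt(eg$values[1:2])
  if (scale == "grid") {
    half <- unname(grid_center(grid))          # half-span of each axis
    a <- v * (half / (2 * score_sd))           # +/-2 SD of scores spans grid
  } else {
    a <- v
  }
  r0 <- unname(grid_center(grid)) - as.vector(a %*% ctr)
  structure(
    list(A = a, r0 = r0, score_sd = score_sd, center = ctr,
         grid = grid, scale = scale),
    class = "cursor_mapping"
  )
}

#' @export
print.cursor_mapping <- function(x, ...) {
  cat(sprintf("<cursor_mapping> 2 x 14, scale = %s, PC score SDs %.3g / %.3g\n",
              x$scale, x$score_sd[1], x$score_sd[2]))
  invisible(x)
}

#' Map glove postures to cursor positions
#'
#' Applies the affine map `r = A s + r0` exactly.
#'
#' @param m A `cursor_mapping` from [fit_mapping()].
#' @param s A length-14 posture vector, or an n x 14 matrix / data frame with
#'   columns `s1..s14` for a whole series.
#' @return A tibble with columns `x`, `y` in grid units.
#' @export
map_posture <- function(m, s) {
  stopifnot(inherits(m, "cursor_mapping"))
  if (is.numeric(s) && is.null(dim(s))) s <- matrix(s, nrow = 1)
  s <- sensor_matrix(s)
  r <- s %*% t(m$A)
  tibble::tibble(x = r[, 1] + m$r0[1], y = r[, 2] + m$r0[2])
}

#' Check that all grid cells are reachable
#'
#' Evaluates the image of the sensor working range under the mapping on a
#' dense lattice of its 2-D latent preimage: postures `center + t1 * w1 +
#' t2 * w2` for `t1, t2` on an `n_lattice` grid over `[-1, 1]`, where `w1`,
#' `w2` are the per-channel half-ranges signed to move maximally along each
#' principal axis. A cell is reachable when some lattice image lands in it.
#'
#' @param m A `cursor_mapping`.
#' @param sensor_box 14 x 2 matrix (or data frame) of per-channel `min`, `max`.
#' @param grid A [grid_spec()].
#' @param n_lattice Lattice resolution per latent axis (default 101).
#' @return A tibble with columns `cell` (1..25) and `reachable` (logical).
#' @export
check_reachability <- function(m, sensor_box, grid = grid_spec(),
                               n_lattice = 101) {
  stopifnot(inherits(m, "cursor_mapping"))
  box <- as.matrix(sensor_box)
  stopifnot(nrow(box) == 14, ncol(box) == 2, all(is.finite(box)))
  lo <- pmin(box[, 1], box[, 2]); hi <- pmax(box[, 1], box[, 2])
  ctr <- (lo + hi) / 2
  hw <- (hi - lo) / 2
  if (sum(rowSums(abs(m$A)) > 0) == 0) {
    stop("check_reachability: degenerate mapping", call. = FALSE)
  }
  w1 <- hw * sign(m$A[1, ]); w2 <- hw * sign(m$A[2, ])
  tt <- seq(-1, 1, length.out = n_lattice)
  lat <- expand.grid(t1 = tt, t2 = tt)
  s <- outer(lat$t1, w1) + outer(lat$t2, w2)
  s <- sweep(s, 2, ctr, "+")
  pos <- map_posture(m, s)
  hit <- cell_at(pos$x, pos$y, grid)
  n_cells <- grid$n_rows * grid$n_cols
  tibble::tibble(
    cell = seq_len(n_cells),
    reachable = seq_len(n_cells) %in% hit[!is.na(hit)]
  )
}
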