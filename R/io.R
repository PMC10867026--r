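#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' preserve the data array and the voxel-to-world affine losslessly.
#'
#' @param x Numeric array (3D or 4D).
#' @param path File path (`.nii` or `.nii.gz`).
#' @param affine Optional 4x4 voxel-to-world affine.
#' @param voxel_size Voxel dimensions in mm when no affine is given.
#' @return `read_nifti()` returns a list with `data` (plain array) and
#'   `affine`; `write_nifti()` returns `path` invisibly.
#' @export
write_nifti <- function(x, path, affine = NULL, voxel_size = c(2, 2, 2)) {
  img <- RNifti::asNifti(x * 1)   # logical masks become numeric
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  nd <- length(dim(img))
  RNifti::pixdim(img) <- c(sqrt(colSums(affine[1:3, 1:3]^2)),
                           rep(1, max(0, nd - 3)))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Read and write behavior trial tables
#'
#' Tab-separated with a header; columns are matched by name, so shuffled
#' column order parses identically.
#'
#' @param behavior Behavior tibble.
#' @param path TSV path.
#' @return `read_behavior_tsv()` returns the behavior tibble.
#' @export
write_behavior_tsv <- function(behavior, path) {
  readr::write_tsv(behavior, path)
  invisible(path)
}

behavior_cols <- c("subject", "run", "block", "block_in_run",
                   "trial_in_block", "trial_in_run", "condition",
                   "target_cell", "onset", "duration", "success_rate")

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(behavior_cols, names(out))
  if (length(missing)) {
    stop("read_behavior_tsv: missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dplyr::relocate(out, dplyr::all_of(behavior_cols))
}

#' Serialize a cursor mapping to JSON
#'
#' Stores `A` row-major, the offset `r0`, PC score SDs, the calibration mean
#' posture, and the grid spec.
#'
#' @param m A `cursor_mapping`.
#' @param path JSON path.
#' @return `read_mapping()` reconstructs the `cursor_mapping`.
#' @export
write_mapping <- function(m, path) {
  stopifnot(inherits(m, "cursor_mapping"))
  obj <- list(
    A = as.vector(t(m$A)), r0 = m$r0, score_sd = m$score_sd,
    center = m$center, scale = m$scale,
    grid = list(n_rows = m$grid$n_rows, n_cols = m$grid$n_cols,
                cell_extent = m$grid$cell_extent)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(A = matrix(obj$A, nrow = 2, byrow = TRUE),
         r0 = obj$r0, score_sd = obj$score_sd, center = obj$center,
         grid = grid_spec(obj$grid$n_rows, obj$grid$n_cols,
                          obj$grid$cell_extent),
         scale = obj$scale),
    class = "cursor_mapping"
  )
}

#' Round-trip a design matrix to TSV plus JSON sidecar
#'
#' The TSV holds the regressor columns (one per label); the sidecar records
#' the censor mask, column kinds/conditions and the run id.
#'
#' @param d A `design_matrix`.
#' @param path TSV path; the sidecar is `path` with extension `.json`.
#' @return `read_design()` reconstructs the `design_matrix`.
#' @export
write_design <- function(d, path) {
  stopifnot(inherits(d, "design_matrix"))
  readr::write_tsv(tibble::as_tibble(as.data.frame(d$X)), path)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(censor = d$censor, kind = d$kind, condition = d$condition,
         run = d$run),
    side, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  X <- as.matrix(readr::read_tsv(path, show_col_types = FALSE))
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  new_design_matrix(X, kind = side$kind,
                    condition = as.character(side$condition),
                    censor = side$censor, run = side$run)
}

#' Write a ROC curve to CSV with a JSON summary
#' @param roc A `roc_curve`.
#' @param path CSV path; the summary goes to `path` with extension `.json`.
#' @export
write_roc <- function(roc, path) {
  readr::write_csv(tibble::as_tibble(roc), path)
  jsonlite::write_json(as.list(glance(roc)), sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
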