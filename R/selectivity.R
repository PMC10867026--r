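as_mask_vector <- function(mask, template) {
  if (is.logical(mask) && is.null(dim(mask))) return(mask)
  as.logical(mask)[as.logical(template)]
}

#' ROC analysis of a statistical map against an anatomical mask
#'
#' For each threshold `theta` in the sweep, sensitivity is the fraction of
#' target-mask voxels with `z >= theta` and specificity the fraction of
#' non-target brain voxels with `z < theta`. The curve is the
#' `(1 - specificity, sensitivity)` polyline with anchored endpoints (0,0)
#' and (1,1); AUC is its trapezoidal area. Defaults follow the z sweep from
#' -8 to 8 in steps of 0.5.
#'
#' @param zmap Statistical map: a `group_stat`, a 3D array, or an in-mask
#'   vector.
#' @param target_mask Logical 3D target mask (e.g. the striatum).
#' @param brain_mask Logical 3D analysis mask containing the target.
#' @param z_min,z_max,z_step Threshold sweep (defaults -8, 8, 0.5).
#' @return A `roc_curve` tibble with columns `threshold`, `sensitivity`,
#'   `specificity`, and attributes `auc`, `n_target`, `n_nontarget`.
#' @export
roc_curve <- function(zmap, target_mask, brain_mask,
                      z_min = -8, z_max = 8, z_step = 0.5) {
  if (inherits(zmap, "group_stat")) {
    brain_mask <- if (missing(brain_mask)) zmap$mask else brain_mask
    zmap <- stat_array(zmap, "z")
  }
  bm <- as.logical(brain_mask)
  tm <- as.logical(target_mask)
  if (!is.null(dim(zmap))) {
    z <- zmap[array(bm, dim(zmap))]
    is_target <- tm[bm]
  } else {
    z <- zmap
    is_target <- if (length(tm) == length(z)) tm else tm[bm]
  }
  stopifnot(length(is_target) == length(z))
  n_t <- sum(is_target); n_n <- sum(!is_target)
  if (n_t == 0 || n_n == 0) {
    stop("roc_curve: target must be a nonempty proper subset of the brain mask",
         call. = FALSE)
  }
  thr <- seq(z_min, z_max, by = z_step)
  sens <- vapply(thr, function(th) mean(z[is_target] >= th), numeric(1))
  spec <- vapply(thr, function(th) mean(z[!is_target] < th), numeric(1))
  curve <- tibble::tibble(threshold = thr, sensitivity = sens,
                          specificity = spec)
  fpr <- c(0, rev(1 - spec), 1)
  tpr <- c(0, rev(sens), 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(curve, auc = auc, n_target = n_t, n_nontarget = n_n,
            class = c("roc_curve", class(curve)))
}

#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_target = attr(x, "n_target"),
                 n_nontarget = attr(x, "n_nontarget"),
                 n_thresholds = nrow(x))
}

#' Area under a ROC curve
#' @param x A `roc_curve`.
#' @return The trapezoidal AUC in `[0, 1]`.
#' @export
auc <- function(x) {
  stopifnot(inherits(x, "roc_curve"))
  attr(x, "auc")
}

#' Mean coefficient within a region of interest
#'
#' @param map 3D array (NA allowed outside data) or in-mask vector.
#' @param mask Logical 3D ROI mask; for vector input, a logical vector of the
#'   same length or a 3D mask plus `brain_mask`.
#' @param brain_mask Brain mask defining vector input's voxel order.
#' @return Arithmetic mean of the map over in-mask voxels.
#' @export
roi_mean <- function(map, mask, brain_mask = NULL) {
  if (!is.null(dim(map))) {
    v <- map[as.logical(mask)]
  } else {
    sel <- if (!is.null(brain_mask)) as.logical(mask)[as.logical(brain_mask)]
           else as.logical(mask)
    stopifnot(length(sel) == length(map))
    v <- map[sel]
  }
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("roi_mean: mask does not intersect the data",
                           call. = FALSE)
  mean(v)
}

#' Split a mask at the anterior/posterior boundary
#'
#' Anterior voxels have world Y above the gap band, posterior below: with a
#' `gap`-voxel band, voxels whose center world-Y satisfies
#' `|Y| <= gap * voxel_size_Y / 2` are excluded to reduce partial-volume
#' effects, and `anterior + gap + posterior` partitions the parent exactly.
#'
#' @param mask Logical 3D mask spanning Y = 0.
#' @param affine 4x4 voxel-to-world affine (0-based voxel indices).
#' @param gap Gap width in voxels (default 1).
#' @return List with logical arrays `anterior`, `posterior`, `gap`, and
#'   `warning` flag set when the mask lies entirely on one side.
#' @export
split_anterior_posterior <- function(mask, affine, gap = 1) {
  stopifnot(length(dim(mask)) == 3)
  d <- dim(mask)
  # world Y of every voxel center (0-based indices through the affine)
  idx <- which(array(TRUE, d))
  ijk <- arrayInd(idx, d) - 1
  y <- affine[2, 1] * ijk[, 1] + affine[2, 2] * ijk[, 2] +
    affine[2, 3] * ijk[, 3] + affine[2, 4]
  yarr <- array(y, d)
  vox_y <- sqrt(sum(affine[1:3, 2]^2))
  half_gap <- gap * vox_y / 2
  anterior <- mask & (yarr > half_gap)
  posterior <- mask & (yarr < -half_gap)
  gap_band <- mask & !(anterior | posterior)
  one_sided <- !any(anterior) || !any(posterior)
  list(anterior = anterior, posterior = posterior, gap = gap_band,
       warning = one_sided)
}

#' Extract per-subject ROI means into a tidy summary
#'
#' @param fits List of `subject_glm` fits (one per subject).
#' @param rois Named list of logical 3D ROI masks.
#' @param labels Regressor labels to extract (default: all parametric task
#'   labels present).
#' @return A `roi_summary` tibble: `subject`, `region`, `label`,
#'   `condition`, `mean_beta`.
#' @export
roi_summary <- function(fits, rois, labels = NULL) {
  if (is.null(labels)) {
    labels <- grep("^param_", fits[[1]]$labels, value = TRUE)
  }
  out <- purrr::map_dfr(seq_along(fits), function(s) {
    purrr::map_dfr(names(rois), function(rg) {
      purrr::map_dfr(labels, function(lb) {
        tibble::tibble(
          subject = s, region = rg, label = lb,
          condition = sub("^(param|boxcar)_", "", lb),
          mean_beta = roi_mean(beta_map(fits[[s]], lb), rois[[rg]])
        )
      })
    })
  })
  class(out) <- c("roi_summary", class(out))
  out
}

#' Paired contrast of two conditions within a region
#'
#' Two-sided paired t-test of per-subject ROI means between conditions.
#'
#' @param summary A [roi_summary()] tibble (optionally pre-filtered to one
#'   region).
#' @param cond_a,cond_b Condition labels to contrast (`a - b`).
#' @param region Optional region to filter on.
#' @return A tibble from [paired_t_two_sided()] with the region attached.
#' @export
condition_contrast <- function(summary, cond_a, cond_b, region = NULL) {
  df <- summary
  if (!is.null(region)) df <- df[df$region == region, ]
  a <- df[df$condition == cond_a, ]
  b <- df[df$condition == cond_b, ]
  a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
  if (!identical(a$subject, b$subject)) {
    stop("condition_contrast: subjects are not paired across conditions",
         call. = FALSE)
  }
  res <- paired_t_two_sided(a$mean_beta, b$mean_beta)
  res$region <- if (is.null(region)) NA_character_ else region
  res$contrast <- paste(cond_a, ">", cond_b)
  res
}
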