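# coerce one run to a volumes x brain-voxel matrix
run_to_matrix <- function(run, brain_idx, dim3) {
  if (is.matrix(run)) return(run)
  stopifnot(length(dim(run)) == 4)
  nxyz <- prod(dim(run)[1:3])
  m <- matrix(run, nrow = nxyz)
  t(m[brain_idx, , drop = FALSE])
}

#' Fit the subject-level voxel-wise GLM
#'
#' Ordinary least squares per voxel over the concatenated runs: task columns
#' (parametric and boxcar regressors) are shared across runs by label, while
#' drift and motion nuisances enter block-diagonally per run. Censored
#' volumes are dropped (row deletion).
#'
#' @param runs List of runs: 4D arrays or volumes x brain-voxel matrices
#'   (as produced by [simulate_bold()]).
#' @param designs List of `design_matrix` objects, one per run.
#' @param mask Logical 3D brain mask (defines the voxel set and, for 4D
#'   input, the extraction).
#' @return A `subject_glm` object: `beta` (labels x voxels), `sigma2`,
#'   `dof`, `labels`, `mask`, `dim`.
#' @export
fit_subject <- function(runs, designs, mask) {
  stopifnot(length(runs) == length(designs))
  brain_idx <- which(mask)
  dim3 <- dim(mask)
  task_labels <- unique(unlist(lapply(designs, function(d) {
    d$labels[d$kind %in% c("parametric", "boxcar")]
  })))
  ylist <- list(); xlist <- list()
  n_nuis <- vapply(designs, function(d) {
    sum(!(d$kind %in% c("parametric", "boxcar")))
  }, integer(1))
  nuis_offsets <- cumsum(c(0, n_nuis[-length(n_nuis)]))
  p <- length(task_labels) + sum(n_nuis)
  for (r in seq_along(runs)) {
    d <- designs[[r]]
    y <- run_to_matrix(runs[[r]], brain_idx, dim3)
    if (nrow(y) != nrow(d$X)) {
      stop("fit_subject: run ", r, " length does not match its design",
           call. = FALSE)
    }
    keep <- !d$censor
    if (!any(keep)) stop("fit_subject: run ", r, " fully censored",
                         call. = FALSE)
    x <- matrix(0, sum(keep), p)
    is_task <- d$kind %in% c("parametric", "boxcar")
    x[, match(d$labels[is_task], task_labels)] <-
      d$X[keep, is_task, drop = FALSE]
    ncol_n <- n_nuis[r]
    x[, length(task_labels) + nuis_offsets[r] + seq_len(ncol_n)] <-
      d$X[keep, !is_task, drop = FALSE]
    ylist[[r]] <- y[keep, , drop = FALSE]
    xlist[[r]] <- x
  }
  X <- do.call(rbind, xlist)
  Y <- do.call(rbind, ylist)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    stop("fit_subject: design rank-deficient after censoring (rank ",
         qrx$rank, " < ", ncol(X), ")", call. = FALSE)
  }
  beta <- qr.coef(qrx, Y)
  res <- qr.resid(qrx, Y)
  dof <- nrow(X) - qrx$rank
  sigma2 <- colSums(res^2) / dof
  nuis_labels <- unlist(lapply(seq_along(designs), function(r) {
    d <- designs[[r]]
    paste0("run", r, "_", d$labels[!(d$kind %in% c("parametric", "boxcar"))])
  }))
  rownames(beta) <- c(task_labels, nuis_labels)
  structure(list(beta = beta, sigma2 = sigma2, dof = dof,
                 labels = task_labels, mask = mask, dim = dim3,
                 n_vols_used = nrow(X)),
            class = "subject_glm")
}

#' @export
print.subject_glm <- function(x, ...) {
  cat(sprintf("<subject_glm> %d voxels, %d retained volumes, dof %d\n",
              ncol(x$beta), x$n_vols_used, x$dof))
  cat("  task regressors:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
glance.subject_glm <- function(x, ...) {
  tibble::tibble(n_voxels = ncol(x$beta), n_volumes = x$n_vols_used,
                 dof = x$dof, n_task_regressors = length(x$labels),
                 median_sigma2 = stats::median(x$sigma2))
}

#' Extract a coefficient map from a subject fit
#'
#' @param fit A `subject_glm`.
#' @param label Regressor label, e.g. `"param_on"`.
#' @param as Return a 3D `"array"` (NA outside the mask) or the in-mask
#'   `"vector"`.
#' @return 3D array or numeric vector of beta estimates.
#' @export
beta_map <- function(fit, label, as = c("array", "vector")) {
  as <- match.arg(as)
  if (!label %in% rownames(fit$beta)) {
    stop("beta_map: no regressor labeled '", label, "'", call. = FALSE)
  }
  v <- fit$beta[label, ]
  if (as == "vector") return(v)
  arr <- array(NA_real_, fit$dim)
  arr[fit$mask] <- v
  arr
}

#' Group-level one-sample t-test with z conversion
#'
#' Per-voxel one-sample t against 0 across subjects, converted to z scores
#' through the t CDF (`z = qnorm(pt(t, n - 1))`), which preserves sign and
#' rank order. Zero-variance voxels are capped at |z| = 40 and flagged.
#'
#' @param betas Subjects x voxels matrix, or a list of `subject_glm` fits
#'   combined via `label`.
#' @param label Regressor label when `betas` is a list of fits.
#' @param mask Logical 3D mask matching the voxel set.
#' @param cap Cap on |t| and |z| for degenerate voxels (default 40).
#' @return A `group_stat` object with `t`, `z` (in-mask vectors), `n`, `df`,
#'   `label`, `mask`, `flagged`.
#' @export
group_ttest <- function(betas, label = NULL, mask = NULL, cap = 40) {
  if (is.list(betas) && !is.matrix(betas)) {
    stopifnot(!is.null(label))
    if (is.null(mask)) mask <- betas[[1]]$mask
    betas <- do.call(rbind, lapply(betas, beta_map, label = label,
                                   as = "vector"))
  }
  n <- nrow(betas)
  if (n < 3) stop("group_ttest: need at least 3 subjects", call. = FALSE)
  mu <- colMeans(betas)
  sdv <- apply(betas, 2, stats::sd)
  se <- sdv / sqrt(n)
  t <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, sign(mu) * cap))
  flagged <- se == 0 & mu != 0
  t <- pmin(pmax(t, -cap), cap)
  df <- n - 1
  z <- ifelse(
    t >= 0,
    -stats::qnorm(stats::pt(t, df, lower.tail = FALSE, log.p = TRUE),
                  log.p = TRUE),
    stats::qnorm(stats::pt(t, df, log.p = TRUE), log.p = TRUE)
  )
  z <- pmin(pmax(z, -cap), cap)
  z[flagged] <- sign(mu[flagged]) * cap   # degenerate voxels: capped, flagged
  structure(list(t = t, z = z, n = n, df = df, label = label, mask = mask,
                 flagged = flagged),
            class = "group_stat")
}

#' @export
print.group_stat <- function(x, ...) {
  cat(sprintf("<group_stat> '%s': n = %d subjects, %d voxels, max |z| = %.2f\n",
              x$label %||% "?", x$n, length(x$z), max(abs(x$z))))
  invisible(x)
}

#' @export
glance.group_stat <- function(x, ...) {
  tibble::tibble(label = x$label %||% NA_character_, n_subjects = x$n,
                 df = x$df, n_voxels = length(x$z),
                 max_abs_z = max(abs(x$z)), n_flagged = sum(x$flagged))
}

stat_array <- function(gs, what = c("z", "t")) {
  what <- match.arg(what)
  arr <- array(NA_real_, dim(gs$mask))
  arr[gs$mask] <- gs[[what]]
  arr
}

# FFT-based Gaussian smoothing of a 3D array (circular; fields restricted to
# an interior mask are effectively unaffected by wrap-around for small FWHM)
smooth_gaussian_fft <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  d <- dim(arr)
  k1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # wrapped coordinates
    k <- exp(-x^2 / (2 * sigma_vox^2))
    k / sum(k)
  }
  K <- outer(outer(k1(d[1]), k1(d[2])), k1(d[3]))
  Re(stats::fft(stats::fft(arr) * stats::fft(K), inverse = TRUE)) / prod(d)
}

# 6-face-connectivity connected components over TRUE voxels of a 3D mask
label_components <- function(supra) {
  d <- dim(supra)
  idx <- which(supra)
  if (length(idx) == 0) {
    return(list(labels = integer(0), idx = idx, sizes = integer(0)))
  }
  pos <- arrayInd(idx, d)
  key <- (pos[, 3] - 1) * (d[1] * d[2]) + (pos[, 2] - 1) * d[1] + pos[, 1]
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(key)) assign(as.character(key[i]), i, envir = lookup)
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  labels <- integer(length(idx))
  comp <- 0L
  for (i in seq_along(idx)) {
    if (labels[i] != 0L) next
    comp <- comp + 1L
    queue <- i
    labels[i] <- comp
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in 1:6) {
        nb <- pos[cur, ] + offsets[o, ]
        if (any(nb < 1) || any(nb > d)) next
        nkey <- as.character((nb[3] - 1) * (d[1] * d[2]) +
                               (nb[2] - 1) * d[1] + nb[1])
        j <- lookup[[nkey]]
        if (!is.null(j) && labels[j] == 0L) {
          labels[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  list(labels = labels, idx = idx, sizes = as.integer(table(labels)))
}

#' Monte-Carlo cluster-extent calibration
#'
#' Simulates Gaussian noise in the mask's bounding volume, smooths it to the
#' stated FWHM, standardizes within the mask, applies the two-sided
#' voxel-wise threshold, and records the largest 6-connected suprathreshold
#' component per iteration. The critical cluster size is the `1 - alpha`
#' quantile of that null max-size distribution: observed clusters at least
#' this large are significant at corrected `alpha`.
#'
#' @param mask Logical 3D mask.
#' @param fwhm Smoothness in mm (default 4).
#' @param voxel_size Voxel size in mm (default 2).
#' @param voxel_p Two-sided voxel-wise p threshold (default 0.001).
#' @param alpha Corrected cluster-wise alpha (default 0.01).
#' @param n_iter Monte-Carlo iterations (>= 200; default 500).
#' @param seed RNG seed.
#' @return A `cluster_calibration` with `critical_size`, `null_max_sizes`,
#'   and the thresholds used.
#' @export
cluster_calibrate <- function(mask, fwhm = 4, voxel_size = 2,
                              voxel_p = 0.001, alpha = 0.01, n_iter = 500,
                              seed = 1) {
  if (!any(mask)) stop("cluster_calibrate: empty mask", call. = FALSE)
  stopifnot(n_iter >= 200, voxel_p > 0, voxel_p < 1, alpha > 0, alpha <= 1)
  d <- dim(mask)
  sigma_vox <- fwhm / voxel_size / (2 * sqrt(2 * log(2)))
  zc <- stats::qnorm(1 - voxel_p / 2)
  in_mask <- which(mask)
  set.seed(seed)
  max_sizes <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    noise <- array(stats::rnorm(prod(d)), d)
    sm <- smooth_gaussian_fft(noise, sigma_vox)
    v <- sm[in_mask]
    v <- (v - mean(v)) / stats::sd(v)
    supra <- array(FALSE, d)
    supra[in_mask[abs(v) > zc]] <- TRUE
    comp <- label_components(supra)
    max_sizes[it] <- if (length(comp$sizes)) max(comp$sizes) else 0L
  }
  critical <- as.integer(stats::quantile(max_sizes, 1 - alpha, type = 1))
  structure(list(critical_size = critical, null_max_sizes = max_sizes,
                 voxel_p = voxel_p, alpha = alpha, fwhm = fwhm,
                 voxel_size = voxel_size, n_iter = n_iter,
                 z_threshold = zc),
            class = "cluster_calibration")
}

#' @export
print.cluster_calibration <- function(x, ...) {
  cat(sprintf(
    "<cluster_calibration> voxel p < %g (|z| > %.2f), FWHM %g mm, %d iters\n",
    x$voxel_p, x$z_threshold, x$fwhm, x$n_iter))
  cat(sprintf("  critical cluster size at corrected alpha = %g: %d voxels\n",
              x$alpha, x$critical_size))
  invisible(x)
}

#' Threshold a group map into significant clusters
#'
#' Applies the two-sided voxel threshold and the calibrated extent threshold,
#' then reports surviving 6-connected clusters sorted by size, with the peak
#' |z| voxel and its world coordinates.
#'
#' @param stat A `group_stat` from [group_ttest()].
#' @param calib A `cluster_calibration`, or `NULL` with explicit thresholds.
#' @param affine 4x4 voxel-to-world affine (for peak coordinates).
#' @param z_threshold,min_size Explicit thresholds if `calib` is `NULL`.
#' @return A tibble: `cluster`, `size`, `peak_z`, `peak_i/j/k`,
#'   `peak_x/y/z`. Empty when nothing survives.
#' @export
threshold_map <- function(stat, calib = NULL, affine = diag(4),
                          z_threshold = NULL, min_size = NULL) {
  if (!is.null(calib)) {
    z_threshold <- calib$z_threshold
    min_size <- calib$critical_size
  }
  stopifnot(!is.null(z_threshold), !is.null(min_size))
  zarr <- stat_array(stat, "z")
  supra <- !is.na(zarr) & abs(zarr) > z_threshold
  comp <- label_components(supra)
  empty <- tibble::tibble(cluster = integer(0), size = integer(0),
                          peak_z = numeric(0), peak_i = integer(0),
                          peak_j = integer(0), peak_k = integer(0),
                          peak_x = numeric(0), peak_y = numeric(0),
                          peak_z_mm = numeric(0))
  if (length(comp$sizes) == 0) return(empty)
  keep <- which(comp$sizes >= min_size)
  if (length(keep) == 0) return(empty)
  rows <- lapply(keep, function(cl) {
    vox <- comp$idx[comp$labels == cl]
    zv <- zarr[vox]
    pk <- vox[which.max(abs(zv))]
    ijk <- arrayInd(pk, dim(zarr))
    world <- affine %*% c(ijk - 1, 1)
    tibble::tibble(size = length(vox), peak_z = zv[which.max(abs(zv))],
                   peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
                   peak_x = world[1], peak_y = world[2], peak_z_mm = world[3])
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$size), ]
  out$cluster <- seq_len(nrow(out))
  dplyr::relocate(out, "cluster")
}
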