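ellipsoid_mask <- function(dim, center, radii) {
  dx <- (seq_len(dim[1]) - center[1]) / radii[1]
  dy <- (seq_len(dim[2]) - center[2]) / radii[2]
  dz <- (seq_len(dim[3]) - center[3]) / radii[3]
  d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  array(d2 <= 1, dim = dim)
}

# RAS-like affine: world = voxel_size * (ijk0 - (dim-1)/2); with even dims the
# Y = 0 plane falls between slice centers.
phantom_affine <- function(dim, voxel_size) {
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- -voxel_size * (dim - 1) / 2
  aff
}

default_gamma <- function() {
  conds <- c("on", "off", "test")
  g <- rbind(
    putamen_l_ant  = c(2.4, 2.0, 2.0),
    putamen_r_ant  = c(2.4, 2.0, 2.0),
    putamen_l_post = c(1.2, 1.0, 1.0),
    putamen_r_post = c(1.2, 1.0, 1.0),
    caudate_l_ant  = c(1.8, 2.6, 1.2),
    caudate_r_ant  = c(1.8, 2.6, 1.2),
    caudate_l_post = c(1.0, 1.4, 0.9),
    caudate_r_post = c(1.0, 1.4, 0.9),
    vmpfc          = c(1.6, 0.0, 1.6),
    v5             = c(-1.6, 0.0, -1.6),
    m1             = c(0.0, 0.0, 0.0)
  )
  colnames(g) <- conds
  g
}

default_boxcar_amp <- function() {
  conds <- c("on", "off", "test", "move")
  b <- rbind(
    putamen_l_ant  = c(0.8, 1.2, 0.8, 0.0),
    putamen_r_ant  = c(0.8, 1.2, 0.8, 0.0),
    putamen_l_post = c(0.8, 1.2, 0.8, 1.0),
    putamen_r_post = c(0.8, 1.2, 0.8, 1.0),
    caudate_l_ant  = c(0.5, 0.8, 0.5, 0.0),
    caudate_r_ant  = c(0.5, 0.8, 0.5, 0.0),
    caudate_l_post = c(0.5, 0.8, 0.5, 0.0),
    caudate_r_post = c(0.5, 0.8, 0.5, 0.0),
    vmpfc          = c(0.0, 0.0, 0.0, 0.0),
    v5             = c(1.0, 0.2, 1.0, 0.0),
    m1             = c(1.5, 2.2, 1.5, 2.0)
  )
  colnames(b) <- conds
  b
}

#' Build a brain phantom with labeled regions and ground-truth coupling
#'
#' Constructs a synthetic stand-in for the anatomical atlases: an ellipsoidal
#' brain containing bilateral "putamen" and "caudate" ellipsoids (each
#' crossing the world Y = 0 plane so anterior/posterior splits are nonempty),
#' a midline "vmPFC" blob, bilateral "V5" and "M1" blobs. The affine places
#' Y = 0 between slices. Each striatal structure is split into anterior and
#' posterior subregions that partition it exactly at Y = 0; the coupling matrix
#' `gamma` gives each subregion's BOLD response in percent signal change per
#' unit of mean-centered trial success rate, per condition, and `boxcar_amp`
#' gives the condition-average (boxcar) amplitudes, including the localizer
#' `move` condition.
#'
#' @param dim Volume shape, at least `c(24, 24, 24)`; default 32^3.
#' @param voxel_size Isotropic voxel size in mm (default 2).
#' @param noise_sd Voxel noise SD in percent of baseline (default 1).
#' @param rho AR(1) coefficient of the voxel noise in `[0, 1)` (default 0.3).
#' @param drift_coef Coefficients of the degree 1..4 drift components, in
#'   units of the unit-norm polynomial basis columns.
#' @param gamma,boxcar_amp Optional replacement coupling matrices
#'   (rows = regions, columns = conditions).
#' @return A `phantom_spec` with `masks` (named logical arrays: `brain`,
#'   `striatum`, parent structures, subregions, `vmpfc`, `v5`, `m1`),
#'   `affine`, couplings and noise parameters.
#' @export
make_phantom <- function(dim = c(32, 32, 32), voxel_size = 2,
                         noise_sd = 1, rho = 0.3,
                         drift_coef = c(6, 4, 3, 2),
                         gamma = NULL, boxcar_amp = NULL) {
  dim <- as.integer(dim)
  if (length(dim) != 3 || any(dim < 24)) {
    stop("make_phantom: shape must be at least 24 voxels per axis",
         call. = FALSE)
  }
  stopifnot(rho >= 0, rho < 1, noise_sd >= 0)
  f <- dim / 32
  ctr <- (dim + 1) / 2
  aff <- phantom_affine(dim, voxel_size)

  el <- function(dx, dy, dz, rx, ry, rz) {
    ellipsoid_mask(dim, ctr + c(dx, dy, dz) * f, c(rx, ry, rz) * f)
  }
  brain <- el(0, 0, 0, 14, 15, 12.5)
  put_l <- (el(-5.5, 0, -1.5, 2.2, 4.5, 3.0) & brain)
  put_r <- (el(+5.5, 0, -1.5, 2.2, 4.5, 3.0) & brain)
  cau_l <- el(-3.0, 0.5, 3.5, 1.6, 4.5, 2.2) & brain & !put_l
  cau_r <- el(+3.0, 0.5, 3.5, 1.6, 4.5, 2.2) & brain & !put_r
  vmpfc <- el(0, 9.5, -6, 2.5, 2.5, 2.0) & brain
  v5 <- (el(-8, -8.5, 0, 1.8, 2.0, 1.8) |
           el(+8, -8.5, 0, 1.8, 2.0, 1.8)) & brain
  m1 <- (el(-5, -2, 8.5, 2.5, 3.0, 2.5) |
           el(+5, -2, 8.5, 2.5, 3.0, 2.5)) & brain

  masks <- list(brain = brain,
                putamen_l = put_l, putamen_r = put_r,
                caudate_l = cau_l, caudate_r = cau_r,
                vmpfc = vmpfc, v5 = v5, m1 = m1)
  # coupling subregions partition the parent exactly (Y = 0 lies between
  # slices); the 1-voxel-gap convention belongs to the ROI split operation
  for (parent in c("putamen_l", "putamen_r", "caudate_l", "caudate_r")) {
    sp <- split_anterior_posterior(masks[[parent]], aff, gap = 0)
    masks[[paste0(parent, "_ant")]] <- sp$anterior
    masks[[paste0(parent, "_post")]] <- sp$posterior
  }
  masks$striatum <- put_l | put_r | cau_l | cau_r

  core <- c("putamen_l", "putamen_r", "caudate_l", "caudate_r",
            "vmpfc", "v5", "m1")
  if (any(!vapply(masks, any, logical(1)))) {
    stop("make_phantom: shape too small to host all regions", call. = FALSE)
  }
  overlap <- Reduce(`+`, lapply(masks[core], function(m) m * 1L))
  if (any(overlap > 1)) stop("make_phantom: labeled regions overlap",
                             call. = FALSE)
  if (!all(brain[overlap > 0])) stop("make_phantom: region outside brain",
                                     call. = FALSE)

  gamma <- if (is.null(gamma)) default_gamma() else gamma
  boxcar_amp <- if (is.null(boxcar_amp)) default_boxcar_amp() else boxcar_amp
  structure(list(dim = dim, voxel_size = voxel_size, affine = aff,
                 masks = masks, gamma = gamma, boxcar_amp = boxcar_amp,
                 noise_sd = noise_sd, rho = rho, drift_coef = drift_coef,
                 baseline = 100),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s voxels (%g mm), %d brain voxels, %d striatal\n",
              paste(x$dim, collapse = "x"), x$voxel_size,
              sum(x$masks$brain), sum(x$masks$striatum)))
  invisible(x)
}

#' Simulate a head-motion trace with planted spikes
#'
#' Six rigid-body parameters following a small-step random walk, plus abrupt
#' sustained steps (spikes) of magnitude `spike_mag` mm at known frames --
#' those frames, and only those, exceed the 0.4-mm censoring threshold.
#'
#' @param n_vols Number of volumes.
#' @param n_spikes Number of spike frames (default 2).
#' @param spike_mag Step magnitude in mm (default 0.8).
#' @param step_sd Background random-walk step SD (default 0.02 mm).
#' @param seed RNG seed.
#' @return List with `motion` (`n_vols` x 6) and sorted `spike_frames`.
#' @export
simulate_motion <- function(n_vols, n_spikes = 2, spike_mag = 0.8,
                            step_sd = 0.02, seed = 1) {
  set.seed(seed)
  steps <- matrix(stats::rnorm(n_vols * 6, sd = step_sd), n_vols, 6)
  steps[1, ] <- 0
  motion <- apply(steps, 2, cumsum)
  spike_frames <- integer(0)
  if (n_spikes > 0) {
    candidates <- seq(5, n_vols - 4)
    spike_frames <- sort(sample(candidates, n_spikes))
    while (any(diff(spike_frames) < 2) && length(spike_frames) > 1) {
      spike_frames <- sort(sample(candidates, n_spikes))
    }
    for (fidx in spike_frames) {
      p <- sample(1:3, 1)
      motion[fidx:n_vols, p] <- motion[fidx:n_vols, p] +
        spike_mag * sample(c(-1, 1), 1)
    }
  }
  list(motion = motion, spike_frames = spike_frames)
}

# region time courses for one run given its regressors
region_signal <- function(phantom, param_regs, boxcar_regs, n_vols,
                          conditions) {
  regions <- rownames(phantom$gamma)
  sig <- matrix(0, n_vols, length(regions),
                dimnames = list(NULL, regions))
  for (cc in conditions) {
    if (!is.null(param_regs[[cc]])) {
      sig <- sig + outer(as.numeric(param_regs[[cc]]), phantom$gamma[, cc])
    }
    if (!is.null(boxcar_regs[[cc]])) {
      sig <- sig + outer(as.numeric(boxcar_regs[[cc]]),
                         phantom$boxcar_amp[, cc])
    }
  }
  sig
}

ar1_noise <- function(n_vols, n_vox, sd, rho) {
  if (sd == 0) return(matrix(0, n_vols, n_vox))
  e <- matrix(0, n_vols, n_vox)
  e[1, ] <- stats::rnorm(n_vox, sd = sd)
  innov_sd <- sd * sqrt(1 - rho^2)
  for (t in 2:n_vols) {
    e[t, ] <- rho * e[t - 1, ] + stats::rnorm(n_vox, sd = innov_sd)
  }
  e
}

# assemble one run's brain-voxel matrix (volumes x brain voxels)
build_run_matrix <- function(phantom, sig, n_vols, noise, drift) {
  brain_idx <- which(phantom$masks$brain)
  n_vox <- length(brain_idx)
  dat <- matrix(phantom$baseline, n_vols, n_vox)
  if (drift && length(phantom$drift_coef) > 0) {
    basis <- drift_regressors(n_vols, length(phantom$drift_coef))[, -1,
                                                                  drop = FALSE]
    dat <- dat + as.numeric(basis %*% phantom$drift_coef)
  }
  if (noise) {
    dat <- dat + ar1_noise(n_vols, n_vox, phantom$noise_sd, phantom$rho)
  }
  for (rg in rownames(phantom$gamma)) {
    cols <- match(which(phantom$masks[[rg]]), brain_idx)
    cols <- cols[!is.na(cols)]
    if (length(cols)) dat[, cols] <- dat[, cols] + sig[, rg]
  }
  dat
}

embed_volume <- function(mat, phantom) {
  arr <- array(0, c(phantom$dim, nrow(mat)))
  brain_idx <- which(phantom$masks$brain)
  nxyz <- prod(phantom$dim)
  for (t in seq_len(nrow(mat))) {
    arr[brain_idx + (t - 1) * nxyz] <- mat[t, ]
  }
  arr
}

#' Simulate 4D BOLD runs for one subject
#'
#' Inverts the analysis model: each coupled region's signal is the sum of its
#' condition boxcars and its `gamma`-weighted mean-centered success-rate
#' pulses, all HRF-convolved exactly as the design module builds them, plus
#' polynomial drift and AR(1) + white Gaussian noise on every brain voxel,
#' around a baseline of 100 (as if intensity-scaled). Motion traces with
#' planted super-threshold spikes are generated per run.
#'
#' @param behavior One subject's behavior tibble from [simulate_session()].
#' @param phantom A [make_phantom()] spec.
#' @param cfg The [session_config()] used to generate the behavior.
#' @param hrf An [hrf_spec()].
#' @param seed RNG seed.
#' @param noise,drift Logical switches (turn off for noiseless oracles).
#' @param n_spikes Motion spikes per run.
#' @param output `"matrix"` (volumes x brain-voxel matrices; memory-lean) or
#'   `"array"` (full 4D arrays).
#' @return List with `runs`, `motion` (list of `n_vols` x 6 matrices),
#'   `spike_frames` (list), `truth` (gamma, boxcar amplitudes, condition
#'   means `abar`), `brain_idx`, and the inputs' timing.
#' @export
simulate_bold <- function(behavior, phantom, cfg = session_config(),
                          hrf = hrf_spec(), seed = 1, noise = TRUE,
                          drift = TRUE, n_spikes = 2,
                          output = c("matrix", "array")) {
  output <- match.arg(output)
  stopifnot(inherits(phantom, "phantom_spec"))
  runs_present <- sort(unique(behavior$run))
  if (!identical(as.integer(runs_present), seq_len(cfg$n_runs))) {
    stop("simulate_bold: behavior table does not match the session config",
         call. = FALSE)
  }
  n_vols <- run_volumes(cfg)
  abar <- tapply(behavior$success_rate, behavior$condition, mean)
  runs <- motion <- spikes <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    trials <- behavior[behavior$run == r, ]
    conds <- unique(trials$condition)
    blocks <- blocks_from_trials(trials)
    param_regs <- boxcar_regs <- list()
    for (cc in conds) {
      param_regs[[cc]] <- parametric_regressor(trials, cc, n_vols, cfg$tr,
                                               hrf, abar = abar[[cc]])
      boxcar_regs[[cc]] <- boxcar_regressor(blocks, cc, n_vols, cfg$tr, hrf)
    }
    sig <- region_signal(phantom, param_regs, boxcar_regs, n_vols, conds)
    set.seed(seed * 1000L + r)
    dat <- build_run_matrix(phantom, sig, n_vols, noise, drift)
    mt <- simulate_motion(n_vols, n_spikes = n_spikes,
                          seed = seed * 1000L + 500L + r)
    runs[[r]] <- if (output == "array") embed_volume(dat, phantom) else dat
    motion[[r]] <- mt$motion
    spikes[[r]] <- mt$spike_frames
  }
  list(runs = runs, motion = motion, spike_frames = spikes,
       truth = list(gamma = phantom$gamma, boxcar_amp = phantom$boxcar_amp,
                    abar = abar),
       brain_idx = which(phantom$masks$brain),
       n_vols = n_vols, tr = cfg$tr, output = output)
}

#' Simulate a localizer (Move/Stop) run
#'
#' Alternating 48-s Move and Stop blocks; motor regions carry the `move`
#' boxcar amplitude, Stop is baseline.
#'
#' @param phantom A [make_phantom()] spec.
#' @param n_cycles Move/Stop cycles (default 6).
#' @param block_dur Block duration in seconds (default 48).
#' @param tr Repetition time (default 2 s).
#' @param lead_in_vols Rest volumes prepended (default 12).
#' @inheritParams simulate_bold
#' @return List with `run`, `motion`, `spike_frames`, `blocks` (block table
#'   with `move`/`stop` conditions), `n_vols`.
#' @export
simulate_localizer_bold <- function(phantom, n_cycles = 6, block_dur = 48,
                                    tr = 2, lead_in_vols = 12,
                                    hrf = hrf_spec(), seed = 1, noise = TRUE,
                                    drift = TRUE,
                                    output = c("matrix", "array")) {
  output <- match.arg(output)
  lead_s <- lead_in_vols * tr
  n_vols <- lead_in_vols + n_cycles * 2 * block_dur / tr
  blocks <- tibble::tibble(
    onset = lead_s + (seq_len(2 * n_cycles) - 1) * block_dur,
    duration = block_dur,
    condition = rep(c("move", "stop"), n_cycles)
  )
  reg <- boxcar_regressor(blocks, "move", n_vols, tr, hrf)
  sig <- outer(as.numeric(reg), phantom$boxcar_amp[, "move"])
  set.seed(seed * 1000L + 99L)
  dat <- build_run_matrix(phantom, sig, n_vols, noise, drift)
  mt <- simulate_motion(n_vols, seed = seed * 1000L + 599L)
  list(run = if (output == "array") embed_volume(dat, phantom) else dat,
       motion = mt$motion, spike_frames = mt$spike_frames,
       blocks = blocks, n_vols = n_vols, tr = tr,
       brain_idx = which(phantom$masks$brain), output = output)
}
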