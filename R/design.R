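#' Double-gamma HRF specification
#'
#' Canonical hemodynamic response modeled as a difference of two gamma
#' densities: a positive peak (delay 6 s) minus an undershoot (delay 16 s)
#' scaled by `1/ratio`. Delays and dispersions are in seconds; the kernel is
#' evaluated on a fine grid of step `dt` over `length_s` seconds and
#' normalized to unit peak.
#'
#' @param peak_delay,undershoot_delay Gamma means in seconds.
#' @param peak_disp,undershoot_disp Dispersions (gamma scale parameters).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Kernel support in seconds.
#' @param dt Fine time-grid step in seconds.
#' @return An `hrf_spec` object.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_disp = 1, undershoot_disp = 1,
                     ratio = 6, length_s = 32, dt = 0.1) {
  if (peak_disp <= 0 || undershoot_disp <= 0) {
    stop("hrf_spec: dispersions must be positive", call. = FALSE)
  }
  stopifnot(peak_delay > 0, undershoot_delay > 0, ratio > 0,
            length_s > 0, dt > 0)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, length_s = length_s, dt = dt),
            class = "hrf_spec")
}

#' Sample the double-gamma HRF kernel
#'
#' @param spec An [hrf_spec()].
#' @return Numeric kernel sampled at the fine grid, with attribute `times`.
#'   `h(0) = 0` and the kernel peaks near 5 s for default parameters.
#' @export
hrf <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  t <- seq(0, spec$length_s, by = spec$dt)
  h <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_disp,
                     scale = spec$peak_disp) -
    stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_disp,
                  scale = spec$undershoot_disp) / spec$ratio
  h <- h / max(h)
  attr(h, "times") <- t
  h
}

# convolve a fine-grid signal with the HRF kernel, keeping the causal part
conv_hrf <- function(x, spec) {
  h <- hrf(spec)
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(h))), rev(h), type = "open")
  out[seq_len(n)]
}

# fine grid for one run and the left-edge indices of the TR samples
fine_grid <- function(n_vols, tr, dt) {
  n_fine <- round(n_vols * tr / dt)
  list(n_fine = n_fine,
       tr_idx = round((seq_len(n_vols) - 1) * tr / dt) + 1)
}

check_trial_cols <- function(trials) {
  need <- c("onset", "condition", "success_rate")
  if (!all(need %in% names(trials))) {
    stop("trial table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
}

#' Parametric-modulation regressor for one run
#'
#' A pulse of amplitude `a_k - abar` is placed at the offset of each matching
#' trial (end of its 4-s window), convolved with the double-gamma HRF on a
#' fine grid, and sampled at the TR grid (left edge). `abar` is the mean
#' success rate across trials of the same condition; by default it is computed
#' from the rows passed in, but for session-wide centering pass the mean over
#' all runs via `abar`. `condition = "all"` pools every trial with a single
#' mean (the single-regressor analysis mode).
#'
#' @param trials Trial table for one run with columns `onset` (s within run),
#'   `condition`, `success_rate`, and optionally `duration` (default 4 s).
#' @param condition `"on"`, `"off"`, `"test"` or `"all"`.
#' @param n_vols Number of volumes in the run.
#' @param tr Repetition time in seconds.
#' @param hrf An [hrf_spec()].
#' @param abar Optional pre-computed condition mean success rate.
#' @return Numeric regressor of length `n_vols` with attributes `label`,
#'   `kind`, `condition`.
#' @export
parametric_regressor <- function(trials, condition, n_vols, tr = 2,
                                 hrf = hrf_spec(), abar = NULL) {
  check_trial_cols(trials)
  sel <- if (identical(condition, "all")) rep(TRUE, nrow(trials))
         else trials$condition == condition
  if (!any(sel)) {
    stop("parametric_regressor: no trials with condition '", condition, "'",
         call. = FALSE)
  }
  tt <- trials[sel, ]
  dur <- if ("duration" %in% names(tt)) tt$duration else rep(4, nrow(tt))
  if (is.null(abar)) abar <- mean(tt$success_rate)
  g <- fine_grid(n_vols, tr, hrf$dt)
  x <- numeric(g$n_fine)
  idx <- round((tt$onset + dur) / hrf$dt) + 1
  ok <- idx >= 1 & idx <= g$n_fine
  amp <- tt$success_rate - abar
  for (p in which(ok)) x[idx[p]] <- x[idx[p]] + amp[p]
  reg <- conv_hrf(x, hrf)[g$tr_idx]
  structure(reg, label = paste0("param_", condition), kind = "parametric",
            condition = condition)
}

#' Condition boxcar regressor for one run
#'
#' Unit-height boxcar spanning each matching block's task time, convolved
#' with the HRF and sampled at the TR grid. These columns absorb the
#' condition-average activity and the finger-movement confound (movement is
#' larger with the cursor hidden), so the parametric coefficients can be
#' compared across feedback conditions.
#'
#' @param blocks Block table with columns `onset` (s within run), `duration`
#'   (s) and `condition`.
#' @param condition Condition tag to match, or `"all"` for every block.
#' @inheritParams parametric_regressor
#' @return Numeric regressor of length `n_vols` with attributes.
#' @export
boxcar_regressor <- function(blocks, condition, n_vols, tr = 2,
                             hrf = hrf_spec()) {
  need <- c("onset", "duration", "condition")
  if (!all(need %in% names(blocks))) {
    stop("block table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sel <- if (identical(condition, "all")) rep(TRUE, nrow(blocks))
         else blocks$condition == condition
  bb <- blocks[sel, , drop = FALSE]
  ord <- order(bb$onset)
  bb <- bb[ord, , drop = FALSE]
  if (nrow(bb) > 1 &&
      any(bb$onset[-1] < (bb$onset + bb$duration)[-nrow(bb)] - 1e-9)) {
    stop("boxcar_regressor: overlapping blocks", call. = FALSE)
  }
  g <- fine_grid(n_vols, tr, hrf$dt)
  x <- numeric(g$n_fine)
  for (b in seq_len(nrow(bb))) {
    i0 <- round(bb$onset[b] / hrf$dt) + 1
    i1 <- round((bb$onset[b] + bb$duration[b]) / hrf$dt)
    if (i1 >= 1 && i0 <= g$n_fine) x[max(i0, 1):min(i1, g$n_fine)] <- 1
  }
  reg <- conv_hrf(x, hrf)[g$tr_idx]
  structure(reg, label = paste0("boxcar_", condition), kind = "boxcar",
            condition = condition)
}

#' Polynomial drift regressors
#'
#' A discretely orthogonal polynomial basis (constant plus
#' [stats::poly()] terms) of degrees 0..`order` over the run, one set per
#' run. `order = 4` gives the five columns modeling up to quartic trends.
#'
#' @param n_vols Number of volumes.
#' @param order Maximum polynomial degree (default 4).
#' @return `n_vols` x `(order+1)` matrix with column names `drift0..driftN`;
#'   columns are exactly orthogonal and unit-norm.
#' @export
drift_regressors <- function(n_vols, order = 4) {
  if (n_vols <= order) stop("drift_regressors: need n_vols > order",
                            call. = FALSE)
  m <- unname(cbind(rep(1 / sqrt(n_vols), n_vols),
                    unclass(stats::poly(seq_len(n_vols), degree = order))))
  colnames(m) <- paste0("drift", 0:order)
  m
}

#' Motion censoring mask
#'
#' Flags volumes whose frame-to-frame head displacement exceeds the
#' threshold: the Euclidean norm of the first difference of the six rigid-body
#' parameters (3 translations in mm, 3 rotations in degrees treated as
#' mm-equivalent, the AFNI enorm convention). The first volume's difference is
#' defined as 0, so it is never flagged.
#'
#' @param motion `n_vols` x 6 matrix of motion parameters.
#' @param threshold Displacement threshold in mm (default 0.4).
#' @return Logical vector, `TRUE` for volumes to exclude.
#' @export
censor_mask <- function(motion, threshold = 0.4) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("censor_mask: expected 6 motion parameters",
                              call. = FALSE)
  d <- rbind(rep(0, 6), diff(motion))
  sqrt(rowSums(d^2)) > threshold
}

blocks_from_trials <- function(trials) {
  stopifnot(all(c("block_in_run", "onset", "condition") %in% names(trials)))
  dur <- if ("duration" %in% names(trials)) trials$duration else rep(4, nrow(trials))
  trials$duration <- dur
  dplyr::summarise(
    dplyr::group_by(trials, .data$block_in_run, .data$condition),
    onset = min(.data$onset),
    duration = sum(.data$duration),
    .groups = "drop"
  )
}

new_design_matrix <- function(X, kind, condition, censor, run) {
  stopifnot(!anyDuplicated(colnames(X)))
  structure(list(X = X, labels = colnames(X), kind = kind,
                 condition = condition, censor = censor, run = run),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> run %s: %d volumes x %d regressors (%d censored)\n",
              as.character(x$run), nrow(x$X), ncol(x$X), sum(x$censor)))
  cat("  ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.design_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$X))
  out$volume <- seq_len(nrow(x$X))
  out$censored <- x$censor
  tidyr::pivot_longer(out, cols = -c("volume", "censored"),
                      names_to = "regressor", values_to = "value")
}

#' Assemble the GLM design matrix for one run
#'
#' Columns are `[parametric x conditions | boxcar x conditions | drift 0..4 |
#' motion x 6]` with labels, plus the attached censor mask. Modes:
#' `"split-conditions"` builds one parametric and one boxcar column per
#' condition present in the run; `"single-parametric"` pools all trials into
#' one mean-centered parametric column plus an all-task boxcar; `"move-stop"`
#' uses a Move boxcar only (events = block table with conditions
#' `move`/`stop`; Stop is the implicit baseline, so the Move > Stop contrast
#' is the Move coefficient against 0).
#'
#' @param events For trial modes, a trial table for one run (columns `onset`,
#'   `condition`, `success_rate`, `block_in_run`, optionally `duration`); for
#'   `"move-stop"`, a block table (`onset`, `duration`, `condition`).
#' @param motion `n_vols` x 6 motion-parameter matrix.
#' @param n_vols,tr Run length in volumes and TR in seconds.
#' @param mode Design mode (see Details).
#' @param hrf An [hrf_spec()].
#' @param abar Optional named vector of session-wide condition mean success
#'   rates (names = conditions, plus `"all"`), used to center parametric
#'   pulses consistently across runs.
#' @param drift_order Polynomial drift order (default 4).
#' @param censor_threshold Displacement threshold in mm (default 0.4).
#' @param run Run identifier carried through for bookkeeping.
#' @return A `design_matrix` object.
#' @export
build_design <- function(events, motion, n_vols, tr = 2,
                         mode = c("split-conditions", "single-parametric",
                                  "move-stop"),
                         hrf = hrf_spec(), abar = NULL, drift_order = 4,
                         censor_threshold = 0.4, run = NA) {
  mode <- match.arg(mode)
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) == n_vols)
  drift <- drift_regressors(n_vols, drift_order)
  mot <- motion
  colnames(mot) <- paste0("motion", 1:6)
  censor <- censor_mask(motion, censor_threshold)

  if (mode == "move-stop") {
    task <- cbind(boxcar_move = as.numeric(
      boxcar_regressor(events, "move", n_vols, tr, hrf)))
    kinds <- "boxcar"; conds <- "move"
  } else if (mode == "single-parametric") {
    task <- cbind(
      param_all = as.numeric(parametric_regressor(
        events, "all", n_vols, tr, hrf, abar = abar[["all"]])),
      boxcar_all = as.numeric(boxcar_regressor(
        blocks_from_trials(events), "all", n_vols, tr, hrf)))
    kinds <- c("parametric", "boxcar"); conds <- c("all", "all")
  } else {
    conds_here <- intersect(c("on", "off", "test"), unique(events$condition))
    if (length(conds_here) == 0) {
      stop("build_design: no task conditions present in this run",
           call. = FALSE)
    }
    blocks <- blocks_from_trials(events)
    pcols <- lapply(conds_here, function(cc) as.numeric(
      parametric_regressor(events, cc, n_vols, tr, hrf,
                           abar = if (is.null(abar)) NULL else abar[[cc]])))
    bcols <- lapply(conds_here, function(cc) as.numeric(
      boxcar_regressor(blocks, cc, n_vols, tr, hrf)))
    task <- do.call(cbind, c(pcols, bcols))
    colnames(task) <- c(paste0("param_", conds_here),
                        paste0("boxcar_", conds_here))
    kinds <- rep(c("parametric", "boxcar"), each = length(conds_here))
    conds <- rep(conds_here, 2)
  }

  keep <- !censor
  zero_task <- apply(task[keep, , drop = FALSE], 2, function(v) all(v == 0))
  if (any(zero_task)) {
    stop("build_design: task column(s) all zero after censoring: ",
         paste(colnames(task)[zero_task], collapse = ", "), call. = FALSE)
  }
  X <- cbind(task, drift, mot)
  new_design_matrix(
    X,
    kind = c(kinds, rep("drift", ncol(drift)), rep("motion", 6)),
    condition = c(conds, rep(NA_character_, ncol(drift) + 6)),
    censor = censor, run = run
  )
}
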