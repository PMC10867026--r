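#' Session configuration for the main task
#'
#' Encodes the study timing: six runs (four learning runs with alternating
#' cursor-on/cursor-off blocks, starting with on, then two cursor-on test
#' runs using the alternate target set), 12 blocks of 12 four-second trials
#' per run (576 s of task per run), TR 2 s, with `lead_in_vols` rest volumes
#' prepended to each run so that an acquired run has `lead_in_vols + 288`
#' volumes.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param n_runs Total runs (default 6).
#' @param n_learning_runs Learning runs preceding the test runs (default 4).
#' @param blocks_per_run,trials_per_block Block structure (12 x 12).
#' @param trial_dur Trial duration in seconds (default 4).
#' @param tr Repetition time in seconds (default 2).
#' @param lead_in_vols Rest volumes prepended per run (default 12).
#' @param sample_rate Cursor sampling rate inside a trial, Hz (default 50).
#' @param sequence_learning,sequence_test Target-sequence variants for the
#'   learning and test phases (defaults 1 and 2).
#' @return A `session_config` object.
#' @export
session_config <- function(n_subjects = 24, n_runs = 6, n_learning_runs = 4,
                           blocks_per_run = 12, trials_per_block = 12,
                           trial_dur = 4, tr = 2, lead_in_vols = 12,
                           sample_rate = 50,
                           sequence_learning = 1, sequence_test = 2) {
  stopifnot(n_runs > n_learning_runs, blocks_per_run >= 1,
            trials_per_block >= 1, trial_dur > 0, tr > 0, lead_in_vols >= 0,
            sample_rate > 0)
  structure(list(
    n_subjects = n_subjects, n_runs = n_runs,
    n_learning_runs = n_learning_runs, blocks_per_run = blocks_per_run,
    trials_per_block = trials_per_block, trial_dur = trial_dur, tr = tr,
    lead_in_vols = lead_in_vols, sample_rate = sample_rate,
    sequence_learning = sequence_learning, sequence_test = sequence_test
  ), class = "session_config")
}

run_task_seconds <- function(cfg) {
  cfg$blocks_per_run * cfg$trials_per_block * cfg$trial_dur
}

run_volumes <- function(cfg) {
  cfg$lead_in_vols + run_task_seconds(cfg) / cfg$tr
}

#' Learner-model parameters
#'
#' The synthetic participant is a noisy proportional controller in the 2-D
#' latent (cursor) plane: each 20-ms step moves a fraction of the remaining
#' distance to the target center and adds Gaussian execution noise whose
#' stationary positional SD is `sigma_b = noise_asymptote + (noise_sd0 -
#' noise_asymptote) * exp(-learning_rate * (block - 1))`, multiplied by
#' `off_noise_mult` in cursor-off blocks (no online feedback means noisier
#' control and more movement). Units: grid units for SDs, per-block for the
#' learning rate, per-second for the gain.
#'
#' @param noise_sd0 Initial stationary execution-noise SD (grid units).
#' @param noise_asymptote Asymptotic SD after learning.
#' @param learning_rate Exponential decay rate of the SD per block.
#' @param off_noise_mult Noise multiplier in cursor-off blocks (>= 1).
#' @param gain Proportional controller gain toward the target, 1/s.
#' @param trial_jitter Log-normal SD of a per-trial multiplier on the
#'   execution noise, modeling attentional trial-to-trial fluctuation (so
#'   success rates keep varying even at the learning plateau).
#' @param subject_sd Between-subject heterogeneity: log-normal SD applied to
#'   `noise_sd0`, `noise_asymptote`, `learning_rate` and `off_noise_mult`
#'   when a group is simulated (0 makes all subjects identical).
#' @return A `learner_params` object.
#' @export
learner_params <- function(noise_sd0 = 0.8, noise_asymptote = 0.22,
                           learning_rate = 0.08, off_noise_mult = 3,
                           gain = 3, trial_jitter = 0.35,
                           subject_sd = 0.25) {
  stopifnot(noise_sd0 > 0, noise_asymptote > 0, learning_rate > 0,
            off_noise_mult >= 1, gain > 0, trial_jitter >= 0,
            subject_sd >= 0)
  structure(list(noise_sd0 = noise_sd0, noise_asymptote = noise_asymptote,
                 learning_rate = learning_rate,
                 off_noise_mult = off_noise_mult, gain = gain,
                 trial_jitter = trial_jitter, subject_sd = subject_sd),
            class = "learner_params")
}

# draw one subject's parameters around the group values
draw_subject_params <- function(lp, seed) {
  if (lp$subject_sd == 0) return(lp)
  set.seed(seed)
  jit <- function(v) v * stats::rlnorm(1, sdlog = lp$subject_sd)
  learner_params(
    noise_sd0 = jit(lp$noise_sd0),
    noise_asymptote = jit(lp$noise_asymptote),
    learning_rate = jit(lp$learning_rate),
    off_noise_mult = max(1, jit(lp$off_noise_mult)),
    gain = lp$gain, trial_jitter = lp$trial_jitter, subject_sd = 0
  )
}

#' Simulate glove calibration data
#'
#' Free natural-speed finger movement as seen by a 14-channel data glove:
#' a smooth 2-D latent trajectory (stationary AR(1) with coefficient
#' `latent_smoothness`) projected through a fixed orthonormal 14 x 2 loading,
#' plus independent per-channel sensor noise. The sensor covariance therefore
#' has two dominant eigenvalues, which is what the PCA mapping fit relies on.
#'
#' @param n_samples Number of frames (default 3000; at least 100).
#' @param rate Nominal sampling rate, Hz.
#' @param latent_smoothness AR(1) coefficient of the latent walk in `[0, 1)`.
#' @param latent_sd Stationary SDs of the two latent dimensions (anisotropic
#'   by default: a dominant and a secondary movement axis).
#' @param noise_sd Per-channel sensor noise SD.
#' @param n_blocks Number of movement blocks the frames are tagged with
#'   (mirrors the localizer's Move blocks; the fit consumes whatever slice it
#'   is given, defaulting to everything).
#' @param seed RNG seed.
#' @return A tibble with columns `time`, `block`, `s1..s14`; attributes
#'   `rate` and `loading` (the true 14 x 2 latent loading).
#' @export
simulate_calibration <- function(n_samples = 3000, rate = 50,
                                 latent_smoothness = 0.98,
                                 latent_sd = c(1, 0.6),
                                 noise_sd = 0.05, n_blocks = 2, seed = 1) {
  stopifnot(n_samples >= 100, latent_smoothness >= 0, latent_smoothness < 1)
  latent_sd <- rep_len(latent_sd, 2)
  set.seed(seed)
  w <- qr.Q(qr(matrix(stats::rnorm(14 * 2), 14, 2)))   # orthonormal loading
  lat <- vapply(1:2, function(d) {
    innov_sd <- latent_sd[d] * sqrt(1 - latent_smoothness^2)
    as.numeric(stats::filter(stats::rnorm(n_samples, sd = innov_sd),
                             latent_smoothness, method = "recursive",
                             init = stats::rnorm(1, sd = latent_sd[d])))
  }, numeric(n_samples))
  s <- lat %*% t(w) + matrix(stats::rnorm(n_samples * 14, sd = noise_sd),
                             n_samples, 14)
  out <- tibble::as_tibble(as.data.frame(s), .name_repair = "minimal")
  names(out) <- paste0("s", 1:14)
  out <- dplyr::bind_cols(
    tibble::tibble(
      time = (seq_len(n_samples) - 1) / rate,
      block = as.integer(ceiling(seq_len(n_samples) / (n_samples / n_blocks)))
    ), out)
  attr(out, "rate") <- rate
  attr(out, "loading") <- w
  out
}

# trial/block layout for one subject session: onsets are seconds within the
# run's task period plus the lead-in
session_layout <- function(cfg) {
  lead_s <- cfg$lead_in_vols * cfg$tr
  purrr::map_dfr(seq_len(cfg$n_runs), function(r) {
    learning <- r <= cfg$n_learning_runs
    variant <- if (learning) cfg$sequence_learning else cfg$sequence_test
    seq12 <- target_sequence(variant)
    purrr::map_dfr(seq_len(cfg$blocks_per_run), function(b) {
      condition <- if (!learning) "test" else if (b %% 2 == 1) "on" else "off"
      tibble::tibble(
        run = r, block_in_run = b,
        block = (r - 1) * cfg$blocks_per_run + b,
        trial_in_block = seq_len(cfg$trials_per_block),
        trial_in_run = (b - 1) * cfg$trials_per_block +
          seq_len(cfg$trials_per_block),
        condition = condition,
        target_cell = rep_len(seq12, cfg$trials_per_block),
        onset = lead_s + ((b - 1) * cfg$trials_per_block +
                            seq_len(cfg$trials_per_block) - 1) * cfg$trial_dur,
        duration = cfg$trial_dur
      )
    })
  })
}

#' Simulate one subject's session
#'
#' Runs the noisy proportional controller through the full session layout and
#' scores every 4-s trial with [success_rate()]. Execution noise decays
#' across blocks and is multiplied in cursor-off blocks, which produces the
#' qualitative learning pattern of the task: block-wise improvement, higher
#' success with the cursor visible, and a larger improvement in the on
#' condition.
#'
#' @param cfg A [session_config()].
#' @param lp A [learner_params()].
#' @param grid A [grid_spec()].
#' @param seed RNG seed.
#' @param subject Subject label carried into the output.
#' @param keep_trajectories Also return the cursor trajectories?
#' @return A list with `behavior` (trial tibble: subject, run, block,
#'   block_in_run, trial columns, condition, target_cell, onset, duration,
#'   success_rate) and, if requested, `trajectories` (run, time, x, y).
#' @export
simulate_session <- function(cfg = session_config(), lp = learner_params(),
                             grid = grid_spec(), seed = 1, subject = 1,
                             keep_trajectories = FALSE) {
  stopifnot(inherits(cfg, "session_config"), inherits(lp, "learner_params"))
  set.seed(seed)
  spt <- round(cfg$trial_dur * cfg$sample_rate)     # samples per trial
  g <- lp$gain / cfg$sample_rate                    # per-step gain
  if (g >= 1) stop("simulate_session: gain too high for the sample rate",
                   call. = FALSE)
  ctr <- grid_center(grid)
  layout <- session_layout(cfg)
  trials_per_run <- cfg$blocks_per_run * cfg$trials_per_block

  behavior <- list(); trajs <- list()
  for (r in seq_len(cfg$n_runs)) {
    lay <- layout[layout$run == r, ]
    # stationary execution-noise SD per trial (block-wise decay; off blocks
    # keep decaying with overall block number so off-only learning occurs)
    sigma_b <- lp$noise_asymptote + (lp$noise_sd0 - lp$noise_asymptote) *
      exp(-lp$learning_rate * (lay$block - 1))
    sigma_b <- sigma_b * ifelse(lay$condition == "off", lp$off_noise_mult, 1)
    if (lp$trial_jitter > 0) {
      sigma_b <- sigma_b * stats::rlnorm(length(sigma_b),
                                         sdlog = lp$trial_jitter)
    }
    step_sd <- rep(sigma_b * sqrt(2 * g - g^2), each = spt)
    tgt <- cell_center(lay$target_cell, grid)
    target_x <- rep(tgt$x, each = spt)
    target_y <- rep(tgt$y, each = spt)
    n <- trials_per_run * spt
    # p[t+1] = (1-g) p[t] + g target[t] + noise: one linear recursion per axis
    ux <- g * target_x + stats::rnorm(n, sd = step_sd)
    uy <- g * target_y + stats::rnorm(n, sd = step_sd)
    x <- as.numeric(stats::filter(ux, 1 - g, method = "recursive",
                                  init = ctr[["x"]]))
    y <- as.numeric(stats::filter(uy, 1 - g, method = "recursive",
                                  init = ctr[["y"]]))
    cells <- cell_at(x, y, grid)
    on_target <- !is.na(cells) & cells == rep(lay$target_cell, each = spt)
    rate <- colMeans(matrix(on_target, nrow = spt))
    behavior[[r]] <- dplyr::mutate(lay, success_rate = rate)
    if (keep_trajectories) {
      trajs[[r]] <- tibble::tibble(
        run = r, time = (seq_len(n) - 1) / cfg$sample_rate, x = x, y = y,
        trial_in_run = rep(lay$trial_in_run, each = spt)
      )
    }
  }
  behavior <- dplyr::bind_cols(
    tibble::tibble(subject = rep(subject, nrow(layout))),
    dplyr::bind_rows(behavior))
  behavior$trial <- seq_len(nrow(behavior))
  out <- list(behavior = behavior)
  if (keep_trajectories) out$trajectories <- dplyr::bind_rows(trajs)
  out
}

#' Simulate a group of subjects' behavior
#'
#' @inheritParams simulate_session
#' @param seed Base seed; subject `s` uses `seed + s - 1`.
#' @return A single behavior tibble over all subjects.
#' @export
simulate_behavior_group <- function(cfg = session_config(),
                                    lp = learner_params(),
                                    grid = grid_spec(), seed = 1) {
  purrr::map_dfr(seq_len(cfg$n_subjects), function(s) {
    lps <- draw_subject_params(lp, seed = seed * 10000L + s)
    simulate_session(cfg, lps, grid, seed = seed + s - 1,
                     subject = s)$behavior
  })
}
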