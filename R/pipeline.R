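#' Simulate a complete synthetic study on disk
#'
#' Writes a BIDS-inspired dataset (without claiming BIDS compliance):
#' `sub-XX/func/sub-XX_run-X_bold.nii.gz` plus motion TSVs, a behavior TSV
#' per subject, shared masks under `masks/`, and `truth.json` recording the
#' planted couplings, condition means, spike frames and seeds. Deterministic
#' for a fixed seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [session_config()].
#' @param lp A [learner_params()].
#' @param phantom A [make_phantom()] spec.
#' @param seed Base seed; subject `s` derives behavior seed `seed + s - 1`
#'   and BOLD seed `seed * 100 + s`.
#' @param hrf An [hrf_spec()].
#' @param behavior_only Skip BOLD simulation and write behavior tables only.
#' @return The manifest (list), invisibly; also written as `manifest.json`.
#' @export
simulate_study <- function(out_dir, cfg = session_config(),
                           lp = learner_params(), phantom = make_phantom(),
                           seed = 1, hrf = hrf_spec(),
                           behavior_only = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  if (!behavior_only) {
    for (nm in names(phantom$masks)) {
      write_nifti(phantom$masks[[nm]],
                  file.path(mask_dir, paste0(nm, "_mask.nii.gz")),
                  affine = phantom$affine)
    }
  }
  truth <- list(seed = seed, gamma = phantom$gamma,
                boxcar_amp = phantom$boxcar_amp,
                noise_sd = phantom$noise_sd, rho = phantom$rho,
                spike_frames = list(), abar = list())
  t0 <- Sys.time()
  for (s in seq_len(cfg$n_subjects)) {
    sub_id <- sprintf("sub-%02d", s)
    func_dir <- file.path(out_dir, sub_id, "func")
    dir.create(func_dir, recursive = TRUE, showWarnings = FALSE)
    lps <- draw_subject_params(lp, seed = seed * 10000L + s)
    beh <- simulate_session(cfg, lps, seed = seed + s - 1,
                            subject = s)$behavior
    write_behavior_tsv(beh, file.path(func_dir,
                                      paste0(sub_id, "_behavior.tsv")))
    if (!behavior_only) {
      bold <- simulate_bold(beh, phantom, cfg, hrf, seed = seed * 100 + s,
                            output = "array")
      for (r in seq_len(cfg$n_runs)) {
        write_nifti(bold$runs[[r]],
                    file.path(func_dir,
                              sprintf("%s_run-%d_bold.nii.gz", sub_id, r)),
                    affine = phantom$affine)
        readr::write_tsv(
          tibble::as_tibble(as.data.frame(bold$motion[[r]]),
                            .name_repair = ~ paste0("motion", 1:6)),
          file.path(func_dir, sprintf("%s_run-%d_motion.tsv", sub_id, r)))
      }
      truth$spike_frames[[sub_id]] <- bold$spike_frames
      truth$abar[[sub_id]] <- as.list(bold$truth$abar)
    }
    message(sprintf("[simulate] %s done (%.1f s, seed %d)", sub_id,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    seed))
  }
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  cfg_out <- list(session = unclass(cfg), learner = unclass(lp),
                  phantom_dim = phantom$dim, seed = seed)
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- dataset_manifest(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a subject group and fit their GLMs in memory
#'
#' Convenience wrapper tying the generator to the GLM: for each subject it
#' draws learner parameters, simulates the session and its BOLD runs, builds
#' the per-run designs with session-wide condition centering, and fits the
#' voxel-wise GLM. Seeds are derived from the base seed (subject `s` uses
#' `seed * 10000 + s` for learner parameters, `seed * 100 + s` for behavior,
#' `seed * 1000 + s` for BOLD noise), so results are reproducible from
#' `seed` alone.
#'
#' @param n_subjects Number of subjects.
#' @param phantom A [make_phantom()] spec.
#' @param cfg A [session_config()].
#' @param lp A [learner_params()].
#' @param seed Base seed.
#' @param mode GLM design mode.
#' @param hrf An [hrf_spec()].
#' @param noise,drift Passed to [simulate_bold()].
#' @return List with `fits` (per-subject `subject_glm`), `behavior`
#'   (combined tibble) and `phantom`.
#' @export
simulate_and_fit_group <- function(n_subjects, phantom = make_phantom(),
                                   cfg = session_config(),
                                   lp = learner_params(), seed = 1,
                                   mode = "split-conditions",
                                   hrf = hrf_spec(), noise = TRUE,
                                   drift = TRUE) {
  fits <- vector("list", n_subjects)
  behaviors <- vector("list", n_subjects)
  n_vols <- run_volumes(cfg)
  for (s in seq_len(n_subjects)) {
    lps <- draw_subject_params(lp, seed = seed * 10000L + s)
    beh <- simulate_session(cfg, lps, seed = seed * 100L + s,
                            subject = s)$behavior
    bold <- simulate_bold(beh, phantom, cfg, hrf, seed = seed * 1000L + s,
                          noise = noise, drift = drift)
    abar <- tapply(beh$success_rate, beh$condition, mean)
    abar <- c(as.list(abar), list(all = mean(beh$success_rate)))
    designs <- lapply(seq_len(cfg$n_runs), function(r) {
      build_design(beh[beh$run == r, ], bold$motion[[r]], n_vols = n_vols,
                   tr = cfg$tr, mode = mode, hrf = hrf, abar = abar, run = r)
    })
    fits[[s]] <- fit_subject(bold$runs, designs, phantom$masks$brain)
    behaviors[[s]] <- beh
  }
  list(fits = fits, behavior = dplyr::bind_rows(behaviors),
       phantom = phantom)
}

dataset_manifest <- function(dir) {
  files <- sort(setdiff(
    list.files(dir, recursive = TRUE),
    "manifest.json"))
  sums <- tools::md5sum(file.path(dir, files))
  list(version = as.character(utils::packageVersion("denovofmri")),
       n_files = length(files),
       files = stats::setNames(as.list(unname(sums)), files))
}

read_study_subject <- function(dir, s, cfg) {
  sub_id <- sprintf("sub-%02d", s)
  func_dir <- file.path(dir, sub_id, "func")
  beh <- read_behavior_tsv(file.path(func_dir,
                                     paste0(sub_id, "_behavior.tsv")))
  runs <- motion <- list()
  for (r in seq_len(cfg$n_runs)) {
    bold_path <- file.path(func_dir,
                           sprintf("%s_run-%d_bold.nii.gz", sub_id, r))
    if (file.exists(bold_path)) {
      runs[[r]] <- read_nifti(bold_path)$data
      motion[[r]] <- as.matrix(readr::read_tsv(
        file.path(func_dir, sprintf("%s_run-%d_motion.tsv", sub_id, r)),
        show_col_types = FALSE))
    }
  }
  list(behavior = beh, runs = runs, motion = motion)
}

#' Analyze a simulated (or conforming) dataset end to end
#'
#' Runs the full pipeline: per-subject GLM with the chosen design mode,
#' group t-test with z conversion per parametric regressor, Monte-Carlo
#' cluster calibration and cluster table, ROC selectivity of each group z
#' map against the striatum mask, ROI summaries with anterior/posterior
#' splits, and the behavioral block statistics. All stage outputs plus a
#' manifest are written under `out_dir`.
#'
#' @param dataset_dir Dataset directory from [simulate_study()].
#' @param out_dir Output directory.
#' @param mode GLM design mode (`"split-conditions"` or
#'   `"single-parametric"`).
#' @param cfg The [session_config()] the dataset was simulated with.
#' @param hrf An [hrf_spec()].
#' @param cluster_iters Monte-Carlo iterations for the extent calibration
#'   (set to 0 to skip the calibration stage).
#' @param seed Seed for the calibration simulation.
#' @param behavior_only Analyze behavior only.
#' @return List of results (group stats, ROC curves, ROI summary, ANOVA,
#'   cluster table), invisibly; files under `out_dir`.
#' @export
analyze_study <- function(dataset_dir, out_dir,
                          mode = c("split-conditions", "single-parametric"),
                          cfg = session_config(), hrf = hrf_spec(),
                          cluster_iters = 500, seed = 1,
                          behavior_only = FALSE) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- sort(list.files(dataset_dir, pattern = "^sub-"))
  if (length(subjects) == 0) stop("analyze_study: no subjects found in ",
                                  dataset_dir, call. = FALSE)
  n_sub <- length(subjects)

  behaviors <- purrr::map_dfr(seq_len(n_sub), function(s) {
    read_behavior_tsv(file.path(dataset_dir, sprintf("sub-%02d", s), "func",
                                sprintf("sub-%02d_behavior.tsv", s)))
  })
  curve <- block_curve(behaviors)
  readr::write_csv(group_curve(curve),
                   file.path(out_dir, "block_curve.csv"))
  stats_report <- list()
  if (n_sub >= 3) {
    nlb <- cfg$n_learning_runs * cfg$blocks_per_run
    sc <- stage_condition_table(curve, n_learning_blocks = nlb)
    aov2 <- rm_anova_2way(sc, "mean_rate", "subject", "stage", "condition")
    stats_report$learning_anova <- tidy(aov2)
    off <- early_late_split(curve, "off", n_learning_blocks = nlb)
    stats_report$off_early_late <- paired_t_two_sided(
      off$mean_rate[off$stage == "late"], off$mean_rate[off$stage == "early"])
  }
  if (behavior_only) {
    jsonlite::write_json(stats_report, file.path(out_dir, "behavior_stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest <- dataset_manifest(out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(block_curve = curve, stats = stats_report)))
  }

  masks <- list()
  mask_files <- list.files(file.path(dataset_dir, "masks"),
                           pattern = "_mask\\.nii\\.gz$")
  if (length(mask_files) == 0) stop("analyze_study: no masks found",
                                    call. = FALSE)
  affine <- NULL
  for (mf in mask_files) {
    nm <- sub("_mask\\.nii\\.gz$", "", mf)
    img <- read_nifti(file.path(dataset_dir, "masks", mf))
    masks[[nm]] <- array(img$data > 0.5, dim(img$data))
    affine <- img$affine
  }
  brain <- masks$brain

  t0 <- Sys.time()
  fits <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    dat <- read_study_subject(dataset_dir, s, cfg)
    abar <- tapply(dat$behavior$success_rate, dat$behavior$condition, mean)
    abar <- c(as.list(abar), list(all = mean(dat$behavior$success_rate)))
    designs <- lapply(seq_len(cfg$n_runs), function(r) {
      build_design(dat$behavior[dat$behavior$run == r, ], dat$motion[[r]],
                   n_vols = run_volumes(cfg), tr = cfg$tr, mode = mode,
                   hrf = hrf, abar = abar, run = r)
    })
    fits[[s]] <- fit_subject(dat$runs, designs, brain)
    message(sprintf("[analyze] sub-%02d GLM done (%.1f s)", s,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  param_labels <- grep("^param_", fits[[1]]$labels, value = TRUE)
  calib <- NULL
  if (cluster_iters > 0) {
    calib <- cluster_calibrate(brain, fwhm = 4,
                               voxel_size = sqrt(sum(affine[1:3, 1]^2)),
                               n_iter = cluster_iters, seed = seed)
  }
  group <- list(); rocs <- list(); clusters <- list()
  for (lb in param_labels) {
    gs <- group_ttest(fits, label = lb, mask = brain)
    group[[lb]] <- gs
    write_nifti(stat_array(gs, "z"),
                file.path(out_dir, paste0(lb, "_zmap.nii.gz")),
                affine = affine)
    rocs[[lb]] <- roc_curve(gs, masks$striatum, brain)
    write_roc(rocs[[lb]], file.path(out_dir, paste0(lb, "_roc.csv")))
    if (!is.null(calib)) {
      cl <- threshold_map(gs, calib, affine = affine)
      cl$label <- if (nrow(cl)) lb else character(0)
      clusters[[lb]] <- cl
    }
  }
  if (length(clusters)) {
    readr::write_tsv(dplyr::bind_rows(clusters),
                     file.path(out_dir, "clusters.tsv"))
  }

  roi_names <- intersect(
    c("putamen_l_ant", "putamen_l_post", "putamen_r_ant", "putamen_r_post",
      "caudate_l_ant", "caudate_l_post", "caudate_r_ant", "caudate_r_post",
      "vmpfc", "v5"),
    names(masks))
  rois <- roi_summary(fits, masks[roi_names])
  readr::write_tsv(rois, file.path(out_dir, "roi_summary.tsv"))

  jsonlite::write_json(
    c(stats_report,
      list(roc_auc = purrr::map_dbl(rocs, auc),
           critical_cluster_size = if (is.null(calib)) NULL
                                   else calib$critical_size)),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- dataset_manifest(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fits = fits, group = group, roc = rocs,
                 clusters = if (length(clusters)) dplyr::bind_rows(clusters)
                            else NULL,
                 roi_summary = rois, block_curve = curve,
                 stats = stats_report, calibration = calib))
}
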