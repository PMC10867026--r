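test_that("calibration generator is seeded and low-rank as designed", {
  a <- simulate_calibration(n_samples = 500, seed = 5)
  b <- simulate_calibration(n_samples = 500, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_calibration(n_samples = 500, seed = 6)))
  # noiseless sensor covariance has rank <= 2 (latent dimension)
  noiseless <- simulate_calibration(n_samples = 500, noise_sd = 0, seed = 5)
  ev <- eigen(cov(as.matrix(noiseless[paste0("s", 1:14)])),
              symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[3] / ev[1], 1e-12)
  # eigengap lambda2/lambda3 > 5 at default settings, across seeds
  gaps <- vapply(1:20, function(sd) {
    cal <- simulate_calibration(seed = sd)
    ev <- eigen(cov(as.matrix(cal[paste0("s", 1:14)])),
                symmetric = TRUE, only.values = TRUE)$values
    ev[2] / ev[3]
  }, numeric(1))
  expect_true(all(gaps > 5))
})

test_that("session layout has the study's trial, block and condition structure", {
  cfg <- session_config()
  ses <- simulate_session(cfg, seed = 2)
  beh <- ses$behavior
  expect_equal(nrow(beh), 864)                       # 6 runs x 144 trials
  expect_equal(sum(beh$run <= 4), 4 * 144)
  # per learning run: 72 on trials and 72 off trials, alternating by block
  for (r in 1:4) {
    tab <- table(beh$condition[beh$run == r])
    expect_equal(as.integer(tab[c("on", "off")]), c(72L, 72L))
    first_block <- beh[beh$run == r & beh$block_in_run == 1, ]
    expect_true(all(first_block$condition == "on"))
  }
  expect_true(all(beh$condition[beh$run >= 5] == "test"))
  # learning runs use sequence 1, test runs sequence 2
  expect_equal(beh$target_cell[beh$run == 1][1:12], target_sequence(1))
  expect_equal(beh$target_cell[beh$run == 5][1:12], target_sequence(2))
  expect_true(all(beh$success_rate >= 0 & beh$success_rate <= 1))
  # trial onsets cover the 576-s task period after the lead-in
  r1 <- beh[beh$run == 1, ]
  expect_equal(min(r1$onset), cfg$lead_in_vols * cfg$tr)
  expect_equal(max(r1$onset) + 4, cfg$lead_in_vols * cfg$tr + 576)
  # determinism
  expect_identical(beh, simulate_session(cfg, seed = 2)$behavior)
})

test_that("learner controller responds to noise and gain as expected", {
  cfg <- small_cfg()
  # (near-)zero noise, high gain: success ~ 1 after the reaching transient
  quiet <- learner_params(noise_sd0 = 1e-4, noise_asymptote = 1e-5,
                          learning_rate = 1, off_noise_mult = 1, gain = 6,
                          trial_jitter = 0, subject_sd = 0)
  ses <- simulate_session(cfg, quiet, seed = 1)
  # only the reaching transient at each trial start keeps success below 1
  expect_gt(mean(ses$behavior$success_rate), 0.85)
  expect_true(all(ses$behavior$success_rate > 0.8))
  # huge off-block noise: off success collapses toward chance
  wild <- learner_params(noise_sd0 = 0.3, noise_asymptote = 0.2,
                         learning_rate = 0.1, off_noise_mult = 50,
                         trial_jitter = 0, subject_sd = 0)
  ses2 <- simulate_session(cfg, wild, seed = 1)
  off_rate <- mean(ses2$behavior$success_rate[ses2$behavior$condition == "off"])
  on_rate <- mean(ses2$behavior$success_rate[ses2$behavior$condition == "on"])
  expect_lt(off_rate, 0.1)
  expect_gt(on_rate, 0.3)
})

test_that("group simulation shows on > off and late > early success", {
  beh <- simulate_behavior_group(session_config(n_subjects = 8), seed = 31)
  per <- dplyr::summarise(
    dplyr::group_by(beh[beh$run <= 4, ], .data$subject, .data$condition,
                    early = .data$block <= 24),
    m = mean(.data$success_rate), .groups = "drop")
  wide <- tidyr::pivot_wider(per, names_from = c("condition", "early"),
                             values_from = "m")
  expect_true(all(wide$on_TRUE > wide$off_TRUE))
  expect_true(all(wide$on_FALSE > wide$on_TRUE))
  expect_true(all(wide$off_FALSE > wide$off_TRUE))
})

test_that("phantom regions are nonempty, disjoint, and crossed by Y = 0", {
  ph <- test_phantom()
  core <- c("putamen_l", "putamen_r", "caudate_l", "caudate_r",
            "vmpfc", "v5", "m1")
  for (nm in names(ph$masks)) expect_gt(sum(ph$masks[[nm]]), 0)
  overlap <- Reduce(`+`, lapply(ph$masks[core], function(m) m * 1L))
  expect_true(all(overlap <= 1))
  expect_true(all(ph$masks$brain[overlap > 0]))
  # anterior/posterior subregions partition each parent structure
  for (parent in c("putamen_l", "putamen_r", "caudate_l", "caudate_r")) {
    ant <- ph$masks[[paste0(parent, "_ant")]]
    post <- ph$masks[[paste0(parent, "_post")]]
    expect_gt(sum(ant), 0)
    expect_gt(sum(post), 0)
    expect_false(any(ant & post))
    expect_identical(ant | post, ph$masks[[parent]])
  }
  # striatum is a small fraction of the brain
  expect_lt(sum(ph$masks$striatum) / sum(ph$masks$brain), 0.05)
  expect_error(make_phantom(dim = c(16, 16, 16)), "at least 24")
})

test_that("motion spikes are exactly the frames censored at 0.4 mm", {
  for (sd in 1:5) {
    mt <- simulate_motion(300, n_spikes = 3, seed = sd)
    expect_identical(which(censor_mask(mt$motion)), mt$spike_frames)
  }
  calm <- simulate_motion(200, n_spikes = 0, seed = 1)
  expect_equal(sum(censor_mask(calm$motion)), 0)
})

test_that("BOLD simulation is deterministic and respects the coupling truth", {
  ph <- test_phantom()
  cfg <- small_cfg()
  ses <- simulate_session(cfg, seed = 4)
  b1 <- simulate_bold(ses$behavior, ph, cfg, seed = 8)
  b2 <- simulate_bold(ses$behavior, ph, cfg, seed = 8)
  expect_identical(b1$runs, b2$runs)
  expect_identical(b1$motion, b2$motion)
  # no coupling, no noise, no drift: baseline plus boxcar-only signal
  ph0 <- make_phantom(dim = c(24, 24, 24), gamma = ph$gamma * 0,
                      boxcar_amp = ph$boxcar_amp * 0)
  b0 <- simulate_bold(ses$behavior, ph0, cfg, seed = 8, noise = FALSE,
                      drift = FALSE)
  expect_true(all(b0$runs[[1]] == 100))
  # boxcar-coupled regions keep their boxcar signal when gamma = 0
  phb <- make_phantom(dim = c(24, 24, 24), gamma = ph$gamma * 0)
  bb <- simulate_bold(ses$behavior, phb, cfg, seed = 8, noise = FALSE,
                      drift = FALSE)
  brain_idx <- which(phb$masks$brain)
  m1_cols <- match(which(phb$masks$m1), brain_idx)
  other_cols <- match(which(phb$masks$vmpfc), brain_idx)
  expect_gt(stats::sd(bb$runs[[1]][, m1_cols[1]]), 0)
  expect_true(all(bb$runs[[1]][, other_cols] == 100))
})
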