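test_that("double-gamma HRF has the canonical shape", {
  h <- hrf(hrf_spec())
  t <- attr(h, "times")
  expect_equal(h[1], 0)
  peak_t <- t[which.max(h)]
  expect_gt(peak_t, 4)
  expect_lt(peak_t, 7)
  # exactly one sign change after the peak (the undershoot)
  after <- h[t > peak_t]
  flips <- sum(diff(sign(after[after != 0])) != 0)
  expect_equal(flips, 1)
  expect_gt(sum(h) * hrf_spec()$dt, 0)   # integrates to a positive value
  expect_error(hrf_spec(peak_disp = -1), "dispersions")
})

test_that("parametric regressor centers, gates and convolves correctly", {
  n_vols <- 150; tr <- 2
  # equal amplitudes within the condition annihilate to a zero regressor
  flat <- toy_trials(rep(0.7, 10))
  expect_equal(max(abs(parametric_regressor(flat, "on", n_vols, tr))), 0)
  # single unit-amplitude pulse reproduces the sampled HRF (direct oracle)
  spec <- hrf_spec()
  two <- toy_trials(c(1, 0), t0 = 40)      # abar = 0.5, amplitudes +/- 0.5
  reg <- parametric_regressor(two, "on", n_vols, tr, spec)
  h <- hrf(spec); ht <- attr(h, "times")
  oracle <- numeric(n_vols)
  for (k in 1:2) {
    offset <- two$onset[k] + 4
    amp <- two$success_rate[k] - 0.5
    tt <- (seq_len(n_vols) - 1) * tr - offset
    idx <- match(round(tt, 6), round(ht, 6))
    oracle <- oracle + ifelse(is.na(idx), 0, amp * h[idx])
  }
  expect_equal(as.numeric(reg), oracle, tolerance = 1e-10)
  # trials of other conditions contribute nothing
  mixed <- dplyr::bind_rows(toy_trials(c(0.2, 0.9), condition = "on"),
                            toy_trials(c(0.1, 0.8), condition = "off",
                                       t0 = 200))
  on_reg <- parametric_regressor(mixed, "on", n_vols, tr)
  expect_lt(max(abs(on_reg[((200 %/% tr) + 20):n_vols])), 1e-10)
  expect_error(parametric_regressor(mixed, "test", n_vols, tr),
               "no trials")
  # column sums vanish when the HRF tails are contained (centering conserved)
  long <- parametric_regressor(toy_trials(c(0.2, 0.5, 0.9, 0.4), t0 = 8),
                               "on", 100, tr)
  expect_equal(sum(long), 0, tolerance = 1e-9)
  # shift equivariance: delaying all trials by one TR shifts the column
  base <- parametric_regressor(toy_trials(c(0.2, 0.9), t0 = 40), "on",
                               n_vols, tr)
  shifted <- parametric_regressor(toy_trials(c(0.2, 0.9), t0 = 42), "on",
                                  n_vols, tr)
  expect_equal(as.numeric(shifted[-1]),
               as.numeric(base[-n_vols]), tolerance = 1e-10)
})

test_that("boxcar regressor plateaus over blocks and partitions by condition", {
  n_vols <- 100; tr <- 2
  blocks <- tibble::tibble(onset = 40, duration = 48, condition = "on")
  reg <- boxcar_regressor(blocks, "on", n_vols, tr)
  # convolution oracle on the fine grid
  spec <- hrf_spec()
  nf <- n_vols * tr / spec$dt
  x <- numeric(nf); x[(40 / spec$dt + 1):(88 / spec$dt)] <- 1
  h <- hrf(spec)
  oracle <- stats::convolve(c(x, numeric(length(h))), rev(h),
                            type = "open")[seq_len(nf)]
  oracle <- oracle[round((seq_len(n_vols) - 1) * tr / spec$dt) + 1]
  expect_equal(as.numeric(reg), oracle, tolerance = 1e-10)
  # plateau: once the kernel support is inside the block, the response is flat
  mid <- reg[37:43]
  expect_lt(max(mid) - min(mid), 0.02 * max(reg))
  # no matching blocks: zero column
  expect_equal(max(abs(boxcar_regressor(blocks, "off", n_vols, tr))), 0)
  # on-boxcar + off-boxcar = all-task boxcar when conditions partition blocks
  two <- tibble::tibble(onset = c(20, 80), duration = 48,
                        condition = c("on", "off"))
  lhs <- as.numeric(boxcar_regressor(two, "on", n_vols, tr)) +
    as.numeric(boxcar_regressor(two, "off", n_vols, tr))
  rhs <- as.numeric(boxcar_regressor(two, "all", n_vols, tr))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  overlapping <- tibble::tibble(onset = c(20, 40), duration = 48,
                                condition = "on")
  expect_error(boxcar_regressor(overlapping, "on", n_vols, tr),
               "overlapping")
})

test_that("drift basis is the orthogonal polynomial set of the stated order", {
  d <- drift_regressors(120, order = 4)
  expect_equal(ncol(d), 5)
  expect_equal(colnames(d), paste0("drift", 0:4))
  expect_equal(stats::sd(d[, 1]), 0)           # degree-0 column is constant
  gram <- unname(crossprod(d))
  expect_equal(gram, diag(diag(gram)), tolerance = 1e-10)
  expect_error(drift_regressors(4, order = 4), "n_vols > order")
})

test_that("censoring flags frame-to-frame displacement above threshold", {
  motion <- matrix(0.5, 50, 6)                 # constant: nothing censored
  expect_equal(sum(censor_mask(motion)), 0)
  motion[20:50, 1] <- 1.5                      # 1-mm step at frame 20
  cm <- censor_mask(motion)
  expect_identical(which(cm), 20L)
  expect_false(cm[1])
  expect_error(censor_mask(matrix(0, 10, 5)), "6 motion")
})

test_that("assembled designs have the study's column structure per mode", {
  cfg <- session_config()
  ses <- simulate_session(cfg, seed = 6)
  beh <- ses$behavior
  mt <- simulate_motion(300, seed = 3)
  abar <- c(as.list(tapply(beh$success_rate, beh$condition, mean)),
            list(all = mean(beh$success_rate)))
  d1 <- build_design(beh[beh$run == 1, ], mt$motion, 300, 2,
                     mode = "split-conditions", abar = abar, run = 1)
  expect_equal(ncol(d1$X), 15)     # 2 parametric + 2 boxcar + 5 drift + 6 motion
  expect_equal(sum(d1$kind == "parametric"), 2)
  expect_equal(sum(d1$kind == "boxcar"), 2)
  d5 <- build_design(beh[beh$run == 5, ], mt$motion, 300, 2,
                     mode = "split-conditions", abar = abar, run = 5)
  expect_equal(ncol(d5$X), 13)     # single condition + 11 nuisance columns
  ds <- build_design(beh[beh$run == 1, ], mt$motion, 300, 2,
                     mode = "single-parametric", abar = abar, run = 1)
  expect_true(all(c("param_all", "boxcar_all") %in% ds$labels))
  expect_equal(sum(ds$kind == "parametric"), 1)
  # parametric and boxcar columns for a condition are not collinear
  task <- d1$X[, d1$kind %in% c("parametric", "boxcar")]
  expect_lt(kappa(crossprod(task), exact = TRUE), 1e6)
  # move-stop mode: Move boxcar plus nuisances only
  blocks <- tibble::tibble(onset = 24 + (0:5) * 96, duration = 48,
                           condition = rep("move", 6))
  dm <- build_design(blocks, mt$motion, 300, 2, mode = "move-stop", run = 1)
  expect_equal(dm$labels[1], "boxcar_move")
  expect_equal(ncol(dm$X), 12)
  # censor mask is attached and matches the motion trace
  expect_identical(d1$censor, censor_mask(mt$motion))
})
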