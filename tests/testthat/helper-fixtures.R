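# Shared fixtures, built in code at test time.

# scaled-down session: 4 blocks x 6 trials per run, short lead-in
small_cfg <- function(n_subjects = 2, ...) {
  session_config(n_subjects = n_subjects, blocks_per_run = 4,
                 trials_per_block = 6, lead_in_vols = 4, sample_rate = 25,
                 ...)
}

# a hand-constructed mapping whose image is exactly the grid square:
# channels 1-2 map to x-y one-to-one, other channels ignored
identity_mapping <- function(r0 = c(0, 0), scale = 1) {
  a <- matrix(0, 2, 14)
  a[1, 1] <- scale
  a[2, 2] <- scale
  structure(list(A = a, r0 = r0, score_sd = c(1, 1),
                 center = rep(0, 14), grid = grid_spec(), scale = "grid"),
            class = "cursor_mapping")
}

# minimal trial table for design tests: n trials of 4 s back to back
toy_trials <- function(rates, condition = "on", t0 = 0, block_in_run = 1) {
  tibble::tibble(
    onset = t0 + (seq_along(rates) - 1) * 4,
    duration = 4,
    condition = condition,
    success_rate = rates,
    block_in_run = block_in_run
  )
}

# one cached 24^3 phantom for volumetric tests
test_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- make_phantom(dim = c(24, 24, 24))
    ph
  }
})

# minimal two-run fixture over a handful of voxels with known designs
make_tiny_fixture <- function(seed = 1, censor_at = integer(0)) {
  set.seed(seed)
  n_vols <- 40
  mask <- array(FALSE, c(5, 1, 1)); mask[1:5, 1, 1] <- TRUE
  designs <- list(); runs <- list()
  for (r in 1:2) {
    trials <- toy_trials(stats::runif(8), t0 = 8)
    motion <- matrix(stats::rnorm(n_vols * 6, sd = 0.01), n_vols, 6)
    if (r == 1 && length(censor_at)) {
      motion[censor_at:n_vols, 1] <- motion[censor_at:n_vols, 1] + 1
    }
    d <- build_design(trials, motion, n_vols, 2, mode = "split-conditions",
                      run = r)
    designs[[r]] <- d
    betas <- stats::rnorm(ncol(d$X))
    runs[[r]] <- d$X %*% matrix(rep(betas, 5), ncol(d$X), 5) +
      matrix(stats::rnorm(n_vols * 5, sd = 0.5), n_vols, 5)
  }
  list(runs = runs, designs = designs, mask = mask)
}

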