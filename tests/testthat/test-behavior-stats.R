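test_that("block curves average trials and summarize across subjects", {
  beh <- tibble::tibble(
    subject = rep(1:2, each = 6),
    block = rep(c(1, 1, 1, 2, 2, 2), 2),
    condition = rep(c("on", "on", "on", "off", "off", "off"), 2),
    success_rate = c(0, 0.5, 1, 0.2, 0.3, 0.4,
                     1, 1, 1, 0.6, 0.7, 0.8)
  )
  bc <- block_curve(beh)
  expect_equal(bc$mean_rate[bc$subject == 1 & bc$block == 1], 0.5)
  expect_equal(bc$mean_rate[bc$subject == 2 & bc$block == 2], 0.7)
  g <- group_curve(bc)
  expect_equal(g$mean[g$block == 1], 0.75)
  expect_equal(g$sem[g$block == 1], sd(c(0.5, 1)) / sqrt(2))
  # all-perfect performance: means 1, SEM 0
  perfect <- dplyr::mutate(beh, success_rate = 1)
  gp <- group_curve(block_curve(perfect))
  expect_true(all(gp$mean == 1))
  expect_true(all(gp$sem == 0))
  expect_error(block_curve(dplyr::mutate(beh, success_rate = NA)),
               "missing")
})

test_that("early/late splits take the exact printed block sets", {
  curve <- tidyr::expand_grid(subject = 1:3, block = 1:72) |>
    dplyr::mutate(
      condition = dplyr::case_when(
        block > 48 ~ "test",
        block %% 2 == 1 ~ "on",
        TRUE ~ "off"),
      mean_rate = block / 100 + subject / 10)
  all_split <- early_late_split(curve, "all")
  # Early = mean over blocks 1-24, Late over 25-48
  expect_equal(all_split$mean_rate[all_split$subject == 1 &
                                     all_split$stage == "early"],
               mean(1:24 / 100 + 0.1))
  expect_equal(all_split$mean_rate[all_split$subject == 1 &
                                     all_split$stage == "late"],
               mean(25:48 / 100 + 0.1))
  off_split <- early_late_split(curve, "off")
  expect_equal(off_split$mean_rate[off_split$subject == 2 &
                                     off_split$stage == "early"],
               mean(seq(2, 24, 2) / 100 + 0.2))
  # each off stage holds 12 blocks
  expect_equal(nrow(dplyr::filter(curve, block %in% seq(2, 24, 2))), 3 * 12)
  # constant performance: early equals late
  flat <- dplyr::mutate(curve, mean_rate = 0.4)
  fs <- early_late_split(flat, "all")
  expect_true(all(fs$mean_rate == 0.4))
  expect_error(early_late_split(curve[curve$block > 10, ], "all"),
               "expected learning blocks")
})

test_that("paired t-test matches the closed form and its symmetries", {
  x <- c(0.52, 0.61, 0.47, 0.58)
  y <- c(0.41, 0.50, 0.45, 0.49)
  res <- paired_t_two_sided(x, y)
  d <- x - y
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p,
               2 * pt(abs(res$t), 3, lower.tail = FALSE), tolerance = 1e-12)
  # identity: t = 0, p = 1
  same <- paired_t_two_sided(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # sign flip negates t, preserves p
  flipped <- paired_t_two_sided(y, x)
  expect_equal(flipped$t, -res$t, tolerance = 1e-12)
  expect_equal(flipped$p, res$p, tolerance = 1e-12)
  # constant nonzero differences: flagged degenerate
  degen <- paired_t_two_sided(c(1, 2, 3), c(0, 1, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$t, Inf)
  expect_error(paired_t_two_sided(1:2, 2:3), "at least 3")
})

test_that("2x2 repeated-measures ANOVA matches an independent SS oracle", {
  # worked 4-subject example, computed from sums of squares by hand below
  df <- tidyr::expand_grid(subject = 1:4, A = c("a1", "a2"),
                           B = c("b1", "b2"))
  df$y <- c(3, 5, 4, 8,
            5, 7, 7, 11,
            4, 6, 6, 9,
            6, 9, 8, 13)
  res <- tidy(rm_anova_2way(df, "y", "subject", "A", "B"))

  # independent oracle: classical within-subject sums-of-squares decomposition
  # m[i, a, b] = observation for subject i at levels a, b
  n <- 4
  m <- array(0, c(n, 2, 2))
  for (r in seq_len(nrow(df))) {
    m[df$subject[r], match(df$A[r], c("a1", "a2")),
      match(df$B[r], c("b1", "b2"))] <- df$y[r]
  }
  grand <- mean(m)
  y_a <- apply(m, 2, mean); y_b <- apply(m, 3, mean)
  y_ia <- apply(m, c(1, 2), mean); y_ib <- apply(m, c(1, 3), mean)
  y_i <- apply(m, 1, mean); y_ab <- apply(m, c(2, 3), mean)
  ss_a <- 2 * n * sum((y_a - grand)^2)
  ss_as <- 2 * sum((y_ia - outer(y_i, rep(1, 2)) -
                      outer(rep(1, n), y_a) + grand)^2)
  f_a_oracle <- ss_a / (ss_as / (n - 1))
  ss_b <- 2 * n * sum((y_b - grand)^2)
  ss_bs <- 2 * sum((y_ib - outer(y_i, rep(1, 2)) -
                      outer(rep(1, n), y_b) + grand)^2)
  f_b_oracle <- ss_b / (ss_bs / (n - 1))
  ss_ab <- n * sum((y_ab - outer(y_a, rep(1, 2)) -
                      outer(rep(1, 2), y_b) + grand)^2)
  resid <- m
  for (i in 1:n) for (a in 1:2) for (b in 1:2) {
    resid[i, a, b] <- m[i, a, b] - y_ab[a, b] - y_ia[i, a] - y_ib[i, b] +
      y_a[a] + y_b[b] + y_i[i] - grand
  }
  f_ab_oracle <- ss_ab / (sum(resid^2) / (n - 1))

  expect_equal(res$F[res$effect == "A"], f_a_oracle, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "B"], f_b_oracle, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "A:B"], f_ab_oracle, tolerance = 1e-8)
  expect_equal(res$df1, rep(1, 3))
  expect_equal(res$df2, rep(3, 3))

  # partial eta^2 definition
  raw <- rm_anova_2way(df, "y", "subject", "A", "B")$table
  expect_equal(raw$partial_eta_sq,
               raw$ss_effect / (raw$ss_effect + raw$ss_error))
  expect_equal(raw$ss_effect[1], ss_a, tolerance = 1e-8)
  expect_true(all(res$gg_epsilon == 1))

  # main-effect F equals the squared paired t of the marginal means
  t_a <- paired_t_two_sided(y_ia[, 2], y_ia[, 1])$t
  expect_equal(res$F[res$effect == "A"], t_a^2, tolerance = 1e-8)
  t_b <- paired_t_two_sided(y_ib[, 2], y_ib[, 1])$t
  expect_equal(res$F[res$effect == "B"], t_b^2, tolerance = 1e-8)

  # cell means exactly additive (subject-level interaction cancels out):
  # interaction sum of squares, hence its F, is zero
  add <- df
  add$y <- ifelse(add$A == "a2", 2, 0) + ifelse(add$B == "b2", 3, 0) +
    rep(1:4, each = 4) +
    ifelse(xor(add$A == "a2", add$B == "b2"), 1, -1) *
      rep(c(1, -1, 1, -1), each = 4)
  res_add <- tidy(rm_anova_2way(add, "y", "subject", "A", "B"))
  expect_equal(res_add$F[res_add$effect == "A:B"], 0, tolerance = 1e-10)

  # permuting subject labels leaves F unchanged
  perm <- df
  perm$subject <- c(3, 1, 4, 2)[perm$subject]
  expect_equal(tidy(rm_anova_2way(perm, "y", "subject", "A", "B"))$F,
               res$F, tolerance = 1e-10)

  expect_error(rm_anova_2way(df[-1, ], "y", "subject", "A", "B"),
               "fully crossed")
})
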