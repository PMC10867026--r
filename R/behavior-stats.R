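#' Block-wise learning curve
#'
#' Averages the 12 trial success rates within each block per subject, and
#' summarizes across subjects (group mean and SEM per block).
#'
#' @param behavior Behavior tibble (possibly several subjects) with columns
#'   `subject`, `block`, `condition`, `success_rate`.
#' @return A `block_curve` tibble: `subject`, `block`, `condition`,
#'   `mean_rate`, with attribute `group` (tibble of `block`, `condition`,
#'   `mean`, `sem`, `n`).
#' @export
block_curve <- function(behavior) {
  need <- c("subject", "block", "condition", "success_rate")
  if (!all(need %in% names(behavior))) {
    stop("block_curve: behavior table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyNA(behavior$success_rate)) {
    stop("block_curve: missing trial success rates", call. = FALSE)
  }
  per <- behavior |>
    dplyr::group_by(.data$subject, .data$block, .data$condition) |>
    dplyr::summarise(mean_rate = mean(.data$success_rate), .groups = "drop")
  group <- per |>
    dplyr::group_by(.data$block, .data$condition) |>
    dplyr::summarise(
      mean = mean(.data$mean_rate),
      sem = stats::sd(.data$mean_rate) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
  out <- structure(per, class = c("block_curve", class(per)))
  attr(out, "group") <- group
  out
}

#' Group summary of a block curve
#' @param x A `block_curve`.
#' @return Tibble of `block`, `condition`, `mean`, `sem`, `n`.
#' @export
group_curve <- function(x) {
  stopifnot(inherits(x, "block_curve"))
  attr(x, "group")
}

#' Early/late stage split of the learning blocks
#'
#' Stage definitions over the 48 learning blocks: scheme `"all"` takes Early
#' = blocks 1-24 and Late = blocks 25-48; `"off"` restricts to the even
#' (cursor-off) blocks, 12 per stage; `"on"` to the odd blocks. Per-subject
#' stage means are unweighted means over the included block means.
#'
#' @param curve A [block_curve()] (or its per-subject tibble).
#' @param scheme `"all"`, `"on"` or `"off"`.
#' @param n_learning_blocks Number of learning blocks (default 48).
#' @return Tibble of `subject`, `stage` (`early`/`late`), `mean_rate`.
#' @export
early_late_split <- function(curve, scheme = c("all", "on", "off"),
                             n_learning_blocks = 48) {
  scheme <- match.arg(scheme)
  blocks <- seq_len(n_learning_blocks)
  if (!all(blocks %in% curve$block)) {
    stop("early_late_split: expected learning blocks 1..", n_learning_blocks,
         call. = FALSE)
  }
  sel <- switch(scheme,
    all = blocks,
    on = blocks[blocks %% 2 == 1],
    off = blocks[blocks %% 2 == 0]
  )
  half <- n_learning_blocks / 2
  curve |>
    dplyr::filter(.data$block %in% sel) |>
    dplyr::mutate(stage = ifelse(.data$block <= half, "early", "late")) |>
    dplyr::group_by(.data$subject, .data$stage) |>
    dplyr::summarise(mean_rate = mean(.data$mean_rate), .groups = "drop")
}

#' Stage-by-condition table for the learning ANOVA
#'
#' Per-subject mean success rate in each stage (Early: blocks 1-24, Late:
#' 25-48) by feedback condition (on = odd blocks, off = even blocks) --
#' the fully crossed 2 x 2 within-subject layout.
#'
#' @param curve A [block_curve()].
#' @param n_learning_blocks Number of learning blocks (default 48).
#' @return Tibble of `subject`, `stage`, `condition`, `mean_rate`.
#' @export
stage_condition_table <- function(curve, n_learning_blocks = 48) {
  half <- n_learning_blocks / 2
  curve |>
    dplyr::filter(.data$block <= n_learning_blocks) |>
    dplyr::mutate(stage = ifelse(.data$block <= half, "early", "late")) |>
    dplyr::group_by(.data$subject, .data$stage, .data$condition) |>
    dplyr::summarise(mean_rate = mean(.data$mean_rate), .groups = "drop")
}

#' Two-sided paired t-test with degenerate-case guard
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1` via [stats::t.test()].
#' When all paired differences are identical the statistic is undefined:
#' all-zero differences give `t = 0, p = 1`; a constant nonzero difference is
#' flagged `degenerate` with `t = +/-Inf` and `p = 0`.
#'
#' @param x,y Equal-length paired samples, `n >= 3`.
#' @return One-row tibble: `estimate` (mean difference), `t`, `df`, `p`,
#'   `degenerate`.
#' @export
paired_t_two_sided <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("paired_t_two_sided: need at least 3 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(estimate = 0, t = 0, df = n - 1, p = 1,
                            degenerate = FALSE))
    }
    return(tibble::tibble(estimate = mean(d), t = sign(mean(d)) * Inf,
                          df = n - 1, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 degenerate = FALSE)
}

#' Two-way repeated-measures ANOVA (2 x 2 within-subject)
#'
#' Within-subject decomposition via [stats::aov()] with `Error(subject/(A*B))`
#' strata; reports F, degrees of freedom, p, and partial eta-squared
#' (`SS_effect / (SS_effect + SS_error)`) for both main effects and the
#' interaction. All factors here have two levels, so sphericity holds
#' trivially and the Greenhouse-Geisser epsilon is 1 (reported for
#' completeness; the correction is inert).
#'
#' @param data Long-format tibble.
#' @param value,subject,factor_a,factor_b Column names (strings) of the
#'   response, subject id, and the two within-subject factors.
#' @return An `rm_anova` object; see [tidy.rm_anova()].
#' @export
rm_anova_2way <- function(data, value, subject, factor_a, factor_b) {
  df <- data.frame(
    y = data[[value]],
    s = factor(data[[subject]]),
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]])
  )
  counts <- table(df$s, df$A, df$B)
  if (any(counts != 1)) {
    stop("rm_anova_2way: design must be fully crossed with one observation ",
         "per subject x cell", call. = FALSE)
  }
  if (nlevels(df$s) < 3) stop("rm_anova_2way: need at least 3 subjects",
                              call. = FALSE)
  fit <- stats::aov(y ~ A * B + Error(s / (A * B)), data = df)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    eff <- tab[match(term, rn), ]
    err <- tab[match("Residuals", rn), ]
    tibble::tibble(
      effect = term,
      df1 = eff$Df, df2 = err$Df,
      ss_effect = eff$`Sum Sq`, ss_error = err$`Sum Sq`,
      F = eff$`F value`, p = eff$`Pr(>F)`,
      partial_eta_sq = eff$`Sum Sq` / (eff$`Sum Sq` + err$`Sum Sq`)
    )
  }
  res <- dplyr::bind_rows(
    pick("Error: s:A", "A"),
    pick("Error: s:B", "B"),
    pick("Error: s:A:B", "A:B")
  )
  res$effect <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  res$gg_epsilon <- 1
  res$p_gg <- res$p     # 2-level factors: GG correction leaves p unchanged
  structure(list(table = res, n_subjects = nlevels(df$s),
                 factors = c(factor_a, factor_b)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> 2x2 within-subject, n = %d subjects\n",
              x$n_subjects))
  print(as.data.frame(x$table[, c("effect", "df1", "df2", "F", "p",
                                  "partial_eta_sq")]), row.names = FALSE)
  invisible(x)
}

#' Tidy a repeated-measures ANOVA
#' @param x An `rm_anova`.
#' @param ... Unused.
#' @return Tibble with one row per effect: `effect`, `df1`, `df2`, `F`, `p`,
#'   `p_gg`, `partial_eta_sq`, `gg_epsilon`.
#' @export
tidy.rm_anova <- function(x, ...) {
  x$table[, c("effect", "df1", "df2", "F", "p", "p_gg", "partial_eta_sq",
              "gg_epsilon")]
}

#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_effects = nrow(x$table),
                 min_p = min(x$table$p))
}
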