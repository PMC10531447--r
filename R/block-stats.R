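#' Partition a time span into fixed-length blocks
#'
#' Divides `[span[1], span[2])` into consecutive, non-overlapping, half-open
#' blocks of `block_length` ps; a trailing remainder shorter than one block
#' is dropped with a warning. With the trajectory design used for channel
#' comparisons (10-ns blocks), a 200-ns single-monomer span yields 20
#' replicate blocks and a 500-ns span over four monomers yields 200.
#'
#' @param span Length-2 numeric, ps.
#' @param block_length Block length in ps (default 10000, i.e. 10 ns).
#' @return A tibble with columns `block`, `start_ps`, `end_ps`.
#' @examples
#' partition_blocks(c(0, 200000))          # 20 blocks
#' partition_blocks(c(0, 25000), 10000)    # 2 blocks, 5 ns dropped
#' @export
partition_blocks <- function(span, block_length = 10000) {
  stopifnot(length(span) == 2, block_length > 0)
  total <- span[2] - span[1]
  if (total < block_length)
    abort("span is shorter than one block")
  n <- floor(total / block_length)
  if (total - n * block_length > 1e-9 * block_length)
    warn(sprintf("dropping %g ps remainder after %d full blocks",
                 total - n * block_length, n))
  tibble::tibble(block = seq_len(n),
                 start_ps = span[1] + (seq_len(n) - 1) * block_length,
                 end_ps = span[1] + seq_len(n) * block_length)
}

#' Per-block metric samples
#'
#' Evaluates one permeability or geometry indicator independently on each
#' block of a trajectory, yielding the replicate samples the block design
#' feeds into [compare_conditions()].
#'
#' Metrics: `"count"` — permeation events whose exit time falls in the
#' block; `"pf"` — osmotic permeability from the block's frames; and
#' `"mean_min_distance"` — mean of the per-frame minimal distance between
#' `sel_a` and `sel_b` over the block.
#'
#' @param traj A trajectory.
#' @param blocks Block table from [partition_blocks()].
#' @param metric `"count"`, `"pf"` or `"mean_min_distance"`.
#' @param cylinder `channel_cylinder` (count/pf metrics).
#' @param waters Water selection (count/pf; defaults to the topology's
#'   waters).
#' @param sel_a,sel_b Selections for `mean_min_distance`.
#' @param condition Condition label attached to each sample.
#' @param monomer Monomer label; defaults to the cylinder's (or `"A"`).
#' @param ... Passed to the underlying metric ([track_crossings()],
#'   [pf_estimate()] or [min_distance_series()]).
#' @return A tibble of `BlockSample` rows: `condition`, `monomer`, `block`,
#'   `start_ps`, `end_ps`, `metric`, `value` (`NA` where the metric is
#'   undefined on a block, e.g. pf on a one-frame block).
#' @export
per_block_metric <- function(traj, blocks, metric = c("count", "pf",
                                                      "mean_min_distance"),
                             cylinder = NULL, waters = NULL,
                             sel_a = NULL, sel_b = NULL,
                             condition = "condition", monomer = NULL, ...) {
  metric <- match.arg(metric)
  monomer <- monomer %||% (if (!is.null(cylinder)) cylinder$monomer else "A")
  base <- dplyr::mutate(blocks, condition = condition, monomer = monomer,
                        metric = metric, .before = 1)

  if (metric == "count") {
    stopifnot(!is.null(cylinder))
    events <- track_crossings(traj, cylinder, waters, ...)
    base$value <- vapply(seq_len(nrow(blocks)), function(i) {
      sum(events$exit_ps >= blocks$start_ps[i] & events$exit_ps < blocks$end_ps[i])
    }, numeric(1))
  } else if (metric == "pf") {
    stopifnot(!is.null(cylinder))
    base$value <- vapply(seq_len(nrow(blocks)), function(i) {
      keep <- which(traj$times >= blocks$start_ps[i] &
                      traj$times < blocks$end_ps[i])
      if (length(keep) < 10) return(NA_real_)
      sub <- traj_subset(traj, keep)
      pf_estimate(sub, cylinder_for_frames(cylinder, keep), waters, ...)$pf
    }, numeric(1))
  } else {
    stopifnot(!is.null(sel_a), !is.null(sel_b))
    ds <- min_distance_series(traj, sel_a, sel_b, ...)
    base$value <- vapply(seq_len(nrow(blocks)), function(i) {
      v <- ds$distance[ds$time_ps >= blocks$start_ps[i] &
                         ds$time_ps < blocks$end_ps[i]]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
  }
  if (anyNA(base$value))
    warn(sprintf("%d block(s) had an undefined %s sample (flagged NA)",
                 sum(is.na(base$value)), metric))
  dplyr::select(base, "condition", "monomer", "block", "start_ps", "end_ps",
                "metric", "value")
}

## restrict a per-frame cylinder to a frame subset
cylinder_for_frames <- function(cyl, frames) {
  if (nrow(cyl$centers) == 1) return(cyl)
  cyl$centers <- cyl$centers[frames, , drop = FALSE]
  cyl
}

#' Gated two-or-more-group comparison of block samples
#'
#' Implements the gated test choice used throughout the analysis: each
#' group's normality is checked with Shapiro-Wilk and the groups' variance
#' homogeneity with median-centred Levene (Brown-Forsythe), both at
#' `alpha`. If every gate passes, the comparison is parametric (Student's t
#' for two groups; one-way ANOVA with Tukey HSD beyond two); otherwise it is
#' non-parametric (Mann-Whitney for two groups; pairwise Wilcoxon rank-sum
#' with Bonferroni correction beyond two). The full decision trail is
#' recorded in the result.
#'
#' @param samples A tibble of block samples (e.g. from
#'   [per_block_metric()], or anything with a grouping column and a value
#'   column).
#' @param value,group Column names (strings) of the metric values and the
#'   condition labels; default `"value"` and `"condition"`.
#' @param alpha Gate significance level (default 0.05).
#' @return An object of class `condition_test`; see [tidy.condition_test()]
#'   and [glance.condition_test()].
#' @export
compare_conditions <- function(samples, value = "value", group = "condition",
                               alpha = 0.05) {
  x <- samples[[value]]
  g <- as.character(samples[[group]])
  keep <- !is.na(x)
  x <- x[keep]; g <- g[keep]
  groups <- unique(g)
  if (length(groups) < 2) abort("need at least two conditions to compare")
  ns <- table(g)
  if (any(ns < 3)) abort("every condition needs at least 3 samples")

  shapiro <- purrr::map_dfr(groups, function(gr) {
    v <- x[g == gr]
    p <- tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
    tibble::tibble(condition = gr, n = length(v), shapiro_p = p,
                   normal = !is.na(p) && p > alpha)
  })
  lev <- car::leveneTest(x ~ factor(g), center = stats::median)
  levene_p <- lev[["Pr(>F)"]][1]
  homoscedastic <- levene_p > alpha
  parametric <- all(shapiro$normal) && homoscedastic

  two <- length(groups) == 2
  if (two) {
    a <- x[g == groups[1]]; b <- x[g == groups[2]]
    if (parametric) {
      tt <- t.test(a, b, var.equal = TRUE)
      test_used <- "Student t-test"
      statistic <- unname(tt$statistic)
      pw <- tibble::tibble(group1 = groups[1], group2 = groups[2],
                           p = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(a, b))
      test_used <- "Mann-Whitney"
      statistic <- unname(wt$statistic)
      pw <- tibble::tibble(group1 = groups[1], group2 = groups[2],
                           p = wt$p.value)
    }
    correction <- "none"
  } else {
    if (parametric) {
      fit <- aov(x ~ factor(g))
      tk <- TukeyHSD(fit)[[1]]
      cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
      pw <- tibble::tibble(group1 = vapply(cmp, `[`, "", 1),
                           group2 = vapply(cmp, `[`, "", 2),
                           p = tk[, "p adj"])
      test_used <- "one-way ANOVA + Tukey HSD"
      statistic <- unname(summary(fit)[[1]][["F value"]][1])
      correction <- "Tukey HSD"
    } else {
      pwt <- suppressWarnings(
        pairwise.wilcox.test(x, factor(g), p.adjust.method = "bonferroni"))
      m <- pwt$p.value
      pw <- tibble::as_tibble(as.data.frame(as.table(m)),
                              .name_repair = "minimal")
      names(pw) <- c("group1", "group2", "p")
      pw <- dplyr::filter(pw, !is.na(.data$p))
      pw$group1 <- as.character(pw$group1); pw$group2 <- as.character(pw$group2)
      test_used <- "pairwise Wilcoxon rank-sum + Bonferroni"
      statistic <- NA_real_
      correction <- "Bonferroni"
    }
  }

  structure(list(
    groups = groups, n = as.integer(ns[groups]),
    metric = if ("metric" %in% names(samples))
      unique(as.character(samples$metric))[1] else NA_character_,
    alpha = alpha,
    shapiro = shapiro, levene_p = levene_p,
    homoscedastic = homoscedastic, parametric = parametric,
    test = test_used, statistic = statistic,
    p_values = pw, correction = correction,
    samples = tibble::tibble(condition = g, value = x)
  ), class = "condition_test")
}

#' @export
print.condition_test <- function(x, ...) {
  cat("<condition_test>", paste(x$groups, collapse = " vs "),
      if (!is.na(x$metric)) paste0("(", x$metric, ")"), "\n")
  cat(sprintf("  gate: normal = %s (Shapiro-Wilk), homoscedastic = %s (Levene p = %.3g)\n",
              paste(x$shapiro$normal, collapse = "/"), x$homoscedastic,
              x$levene_p))
  cat(sprintf("  test: %s", x$test),
      if (!is.na(x$statistic)) sprintf(" (statistic = %.4g)", x$statistic), "\n")
  for (i in seq_len(nrow(x$p_values)))
    cat(sprintf("    %s vs %s: p = %.4g\n", x$p_values$group1[i],
                x$p_values$group2[i], x$p_values$p[i]))
  invisible(x)
}

#' Tidy a gated condition comparison
#'
#' @param x A `condition_test`.
#' @param ... Unused.
#' @return One row per pairwise comparison: `group1`, `group2`, `p`,
#'   `test`, `correction`.
#' @export
tidy.condition_test <- function(x, ...) {
  dplyr::mutate(x$p_values, test = x$test, correction = x$correction)
}

#' One-row summary of a gated condition comparison
#'
#' @param x A `condition_test`.
#' @param ... Unused.
#' @return A one-row tibble with the gate decisions, chosen test and the
#'   smallest pairwise p-value.
#' @export
glance.condition_test <- function(x, ...) {
  tibble::tibble(n_groups = length(x$groups),
                 all_normal = all(x$shapiro$normal),
                 levene_p = x$levene_p,
                 homoscedastic = x$homoscedastic,
                 parametric = x$parametric,
                 test = x$test,
                 statistic = x$statistic,
                 min_p = min(x$p_values$p))
}
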