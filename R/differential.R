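#' Rank tests behind the differential pipeline
#'
#' Thin, policy-carrying wrappers around the two-sided Wilcoxon tests used
#' throughout the package. `wilcoxon_rank_sum()` computes the two-sample
#' Mann-Whitney/rank-sum test: exact when the pooled size is at most 12
#' with no ties, otherwise the normal approximation with midrank tie
#' correction and continuity correction. `wilcoxon_signed_rank()` computes
#' the one-sample signed-rank test on paired differences (zeros dropped):
#' exact for up to 12 non-zero differences without tied magnitudes,
#' otherwise the corrected normal approximation. If every difference is
#' zero the test is inconclusive (p = 1, with a warning).
#'
#' @param x,y Numeric vectors (non-empty).
#' @param diffs Numeric vector of paired differences.
#' @param exact Override the exact-vs-approximate policy (`NULL` = policy).
#' @return A list with `statistic` and `p_value`.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)$p_value          # 0.1, exact
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value # 2/32
#' @name rank_tests
NULL

#' @rdname rank_tests
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (length(x) + length(y) <= 12) && !ties
  if (all(c(x, y) == c(x, y)[1]))
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  p <- res$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(res$statistic), p_value = min(1, p))
}

#' @rdname rank_tests
#' @export
wilcoxon_signed_rank <- function(diffs, exact = NULL) {
  if (length(diffs) == 0) abort("`diffs` must be non-empty.")
  nz <- diffs[diffs != 0]
  if (length(nz) == 0) {
    warn("All paired differences are zero; test is inconclusive.")
    return(list(statistic = 0, p_value = 1))
  }
  ties <- anyDuplicated(abs(nz)) > 0
  if (is.null(exact)) exact <- length(nz) <= 12 && !ties
  res <- suppressWarnings(stats::wilcox.test(nz, exact = exact, correct = TRUE))
  p <- res$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(res$statistic), p_value = min(1, p))
}

#' Storey q-values
#'
#' False-discovery-rate adjustment with the null-proportion estimate
#' \eqn{\hat\pi_0 = \#\{p > \lambda\} / (m (1 - \lambda))} at a fixed
#' tuning value \eqn{\lambda} (default 0.5), clipped to (0, 1]; q-values
#' are the step-up minima \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\,
#' p_{(j)} / j}. With \eqn{\hat\pi_0 = 1} this reduces exactly to the
#' Benjamini-Hochberg adjustment. When no p-value exceeds \eqn{\lambda}
#' the estimate is floored at \eqn{1/m} to keep it positive.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param lambda Tuning value in (0, 1).
#' @param pi0 Optional fixed null proportion overriding the estimate.
#' @return A list with `pi0` (list: `pi0`, `lambda`) and `q_values` (same
#'   order as the input).
#' @examples
#' storey_qvalues(c(0.6, 0.7, 0.8, 0.9))$pi0$pi0  # 1
#' @export
storey_qvalues <- function(p_values, lambda = 0.5, pi0 = NULL) {
  if (length(p_values) == 0) abort("`p_values` must be non-empty.")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    abort("All p-values must lie in [0, 1].")
  if (lambda <= 0 || lambda >= 1) abort("`lambda` must be in (0, 1).")
  m <- length(p_values)
  if (is.null(pi0)) {
    pi0 <- min(1, sum(p_values > lambda) / (m * (1 - lambda)))
    pi0 <- max(pi0, 1 / m)
  }
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  q_sorted <- pi0 * m * p_sorted / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  list(pi0 = list(pi0 = pi0, lambda = lambda), q_values = q)
}

#' Upper-quartile (Q3) abundance
#'
#' 75th percentile with linear interpolation between order statistics
#' (index `1 + 0.75 * (n - 1)`), the abundance summary used by the
#' low-abundance filter of the differential pipeline.
#'
#' @param values Non-empty numeric vector.
#' @return The 75th percentile.
#' @examples
#' q3_quantile(c(0, 0, 0, 100))  # 25
#' @export
q3_quantile <- function(values) {
  if (length(values) == 0) abort("`values` must be non-empty.")
  unname(stats::quantile(values, probs = 0.75, type = 7))
}

#' Configuration for the differential-abundance pipeline
#'
#' Thresholds of the multi-criterion selection rule: a feature is called
#' significant only if its Storey q-value is at most `q_threshold`, its
#' pseudocount-stabilised fold change is at least `fc_threshold`, and the
#' 75th percentile of its normalised counts in the enriched group reaches
#' the level-specific abundance floor (`q3_min_otu` at OTU level,
#' `q3_min_genus` at genus level, in reads at the rarefied depth).
#'
#' @param q_threshold Maximum q-value (default 0.05).
#' @param fc_threshold Minimum fold change (default 2).
#' @param q3_min_otu,q3_min_genus Q3 abundance floors (defaults 10, 100).
#' @param prevalence_min Prevalence screen fraction (default 0.10).
#' @param pseudocount Added to both group means in the fold change
#'   (default 1).
#' @param paired Use the paired signed-rank test on subject-matched
#'   samples (default FALSE).
#' @param level `"otu"` or `"genus"`; selects the Q3 floor and is recorded
#'   in the results.
#' @param lambda Storey tuning value (default 0.5).
#' @return A list of class `diff_config`.
#' @export
diff_config <- function(q_threshold = 0.05, fc_threshold = 2,
                        q3_min_otu = 10, q3_min_genus = 100,
                        prevalence_min = 0.10, pseudocount = 1,
                        paired = FALSE, level = c("otu", "genus"),
                        lambda = 0.5) {
  level <- match.arg(level)
  stopifnot(q_threshold > 0, fc_threshold >= 1, q3_min_otu > 0,
            q3_min_genus > 0, prevalence_min > 0, pseudocount > 0)
  structure(list(q_threshold = q_threshold, fc_threshold = fc_threshold,
                 q3_min_otu = q3_min_otu, q3_min_genus = q3_min_genus,
                 prevalence_min = prevalence_min, pseudocount = pseudocount,
                 paired = paired, level = level, lambda = lambda),
            class = "diff_config")
}

#' Multi-criterion differential abundance between two groups
#'
#' The full selection pipeline: counts are rarefied to the table's minimum
#' library size, screened at `config$prevalence_min` prevalence over all
#' samples, then each feature is compared between the two groups with a
#' two-sided Wilcoxon rank-sum test (or the signed-rank test on
#' subject-paired samples when `config$paired`). P-values are adjusted to
#' Storey q-values; fold change is the ratio of pseudocount-stabilised
#' group means oriented enriched-over-depleted; and the enriched group's
#' Q3 abundance must reach the level-specific floor. A feature is
#' `significant` only when all three criteria hold.
#'
#' @param table An [otu_table()], already aggregated if `config$level` is
#'   `"genus"`.
#' @param metadata Metadata tibble (`sample_id`, `group`, `subject_id`).
#' @param group_a,group_b Group labels to contrast.
#' @param config A [diff_config()].
#' @param seed Seed for the rarefaction draw.
#' @return A tibble of class `apex_diff`, one row per tested feature,
#'   sorted by q then p, with columns `feature_id`, `level`, `mean_a`,
#'   `mean_b`, `fold_change`, `direction` (`up_in_a`/`up_in_b`),
#'   `p_value`, `q_value`, `q3_value`, `passes_q3`, `significant`.
#'   Attributes carry `pi0`, the groups, and the config.
#' @export
differential_analysis <- function(table, metadata, group_a, group_b,
                                  config = diff_config(), seed = 1L) {
  metadata <- validate_metadata(metadata)
  for (g in c(group_a, group_b))
    if (!g %in% metadata$group)
      abort(sprintf("Group '%s' has no samples in the metadata.", g))
  meta <- metadata[metadata$sample_id %in% sample_ids(table), ]
  ids_a <- meta$sample_id[meta$group == group_a]
  ids_b <- meta$sample_id[meta$group == group_b]
  if (length(ids_a) < 3 || length(ids_b) < 3)
    warn("A group has fewer than 3 samples; results will be unstable.")

  table <- rarefy(table, seed = seed)
  table <- prevalence_filter(table, min_fraction = config$prevalence_min)
  ids_a <- intersect(ids_a, sample_ids(table))
  ids_b <- intersect(ids_b, sample_ids(table))
  counts_a <- table$counts[, ids_a, drop = FALSE]
  counts_b <- table$counts[, ids_b, drop = FALSE]

  if (config$paired) {
    subj_a <- meta$subject_id[match(ids_a, meta$sample_id)]
    subj_b <- meta$subject_id[match(ids_b, meta$sample_id)]
    shared <- intersect(subj_a, subj_b)
    if (length(shared) == 0) abort("No subject has samples in both groups.")
    avg_by_subject <- function(counts, subj, keep) {
      m <- t(rowsum(t(counts), group = subj) / as.vector(table(subj)[sort(unique(subj))]))
      m[, keep, drop = FALSE]
    }
    mat_a <- avg_by_subject(counts_a, subj_a, shared)
    mat_b <- avg_by_subject(counts_b, subj_b, shared)
  }

  test_feature <- function(i) {
    if (config$paired) {
      wilcoxon_signed_rank(mat_a[i, ] - mat_b[i, ])$p_value
    } else {
      wilcoxon_rank_sum(counts_a[i, ], counts_b[i, ])$p_value
    }
  }
  p <- suppressWarnings(vapply(seq_len(n_features(table)), test_feature, numeric(1)))

  st <- storey_qvalues(p, lambda = config$lambda)
  mean_a <- rowMeans(counts_a)
  mean_b <- rowMeans(counts_b)
  hi <- unname(ifelse(mean_a >= mean_b, "a", "b"))
  mean_hi <- pmax(mean_a, mean_b)
  mean_lo <- pmin(mean_a, mean_b)
  fc <- (mean_hi + config$pseudocount) / (mean_lo + config$pseudocount)
  q3 <- vapply(seq_len(n_features(table)), function(i) {
    q3_quantile(if (hi[i] == "a") counts_a[i, ] else counts_b[i, ])
  }, numeric(1))
  q3_min <- if (config$level == "genus") config$q3_min_genus else config$q3_min_otu
  res <- tibble(
    feature_id = feature_ids(table),
    level = config$level,
    mean_a = unname(mean_a),
    mean_b = unname(mean_b),
    fold_change = unname(fc),
    direction = ifelse(hi == "a", "up_in_a", "up_in_b"),
    p_value = p,
    q_value = st$q_values,
    q3_value = q3,
    passes_q3 = q3 >= q3_min,
    significant = unname(st$q_values <= config$q_threshold &
      fc >= config$fc_threshold & q3 >= q3_min)
  )
  res <- res[order(res$q_value, res$p_value), ]
  structure(res, class = c("apex_diff", class(res)),
            pi0 = st$pi0, group_a = group_a, group_b = group_b,
            config = config)
}

#' @export
print.apex_diff <- function(x, ...) {
  cat(sprintf("# Differential abundance: %s vs %s (%s level)\n",
              attr(x, "group_a"), attr(x, "group_b"), x$level[1]))
  cat(sprintf("# %d features tested, %d significant, pi0 = %.3f\n",
              nrow(x), sum(x$significant), attr(x, "pi0")$pi0))
  NextMethod()
}

#' Tidy and summarise differential results
#'
#' `tidy()` returns the per-feature results as a plain tibble; `glance()`
#' returns a one-row summary (features tested, significant calls by
#' direction, the null-proportion estimate).
#'
#' @param x An `apex_diff` result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy apex_diff
#' @export
tidy.apex_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "apex_diff")
  as_tibble(out)
}

#' @rdname tidy.apex_diff
#' @method glance apex_diff
#' @export
glance.apex_diff <- function(x, ...) {
  tibble(
    group_a = attr(x, "group_a"),
    group_b = attr(x, "group_b"),
    level = x$level[1],
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    n_up_in_a = sum(x$significant & x$direction == "up_in_a"),
    n_up_in_b = sum(x$significant & x$direction == "up_in_b"),
    pi0 = attr(x, "pi0")$pi0
  )
}
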