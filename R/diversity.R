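#' Alpha-diversity estimators
#'
#' Per-sample community richness and diversity from a vector of feature
#' counts. `observed_richness()` counts features with positive counts.
#' `chao1()` is the classic nonparametric richness estimator
#' \eqn{S_{obs} + F_1^2 / (2 F_2)} built from singleton (\eqn{F_1}) and
#' doubleton (\eqn{F_2}) counts, with the bias-corrected fallback
#' \eqn{S_{obs} + F_1 (F_1 - 1) / 2} when no doubletons exist. `shannon()`
#' is \eqn{H = -\sum p_i \ln p_i} in nats; `simpson()` defaults to the
#' Gini-Simpson index \eqn{1 - \sum p_i^2} (options: the dominance form
#' \eqn{\sum p_i^2} and the inverse form \eqn{1 / \sum p_i^2}).
#'
#' @param counts Non-negative integer vector of feature counts for one
#'   sample. `chao1`, `shannon` and `simpson` require at least one positive
#'   entry.
#' @param variant Simpson variant, one of `"gini-simpson"` (default),
#'   `"dominance"`, `"inverse"`.
#' @return A numeric scalar.
#' @examples
#' chao1(c(1, 1, 2, 3))   # 4 + 2^2/(2*1) = 6
#' shannon(c(1, 1, 1, 1)) # log(4)
#' simpson(c(1, 3))       # 1 - (0.25^2 + 0.75^2) = 0.375
#' @name alpha_diversity
NULL

check_community <- function(counts) {
  if (length(counts) == 0 || all(counts == 0))
    abort("Empty community: at least one positive count is required.")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  counts
}

#' @rdname alpha_diversity
#' @export
observed_richness <- function(counts) sum(counts > 0)

#' @rdname alpha_diversity
#' @export
chao1 <- function(counts) {
  check_community(counts)
  s_obs <- observed_richness(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' @rdname alpha_diversity
#' @export
shannon <- function(counts) {
  check_community(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' @rdname alpha_diversity
#' @export
simpson <- function(counts, variant = c("gini-simpson", "dominance", "inverse")) {
  variant <- match.arg(variant)
  check_community(counts)
  p <- counts[counts > 0] / sum(counts)
  d <- sum(p^2)
  switch(variant, "gini-simpson" = 1 - d, "dominance" = d, "inverse" = 1 / d)
}

#' Per-sample diversity profiles
#'
#' Computes observed richness, Chao1, Shannon and Simpson for every sample.
#' By default samples are first rarefied to the cohort-minimum depth so the
#' estimates are comparable across libraries; set `rarefy_depth = NULL` to
#' work on raw counts.
#'
#' @param table An [otu_table()].
#' @param rarefy_depth Depth for the rarefaction step, `NULL` to skip, or
#'   the default cohort minimum.
#' @param seed Seed for the rarefaction draw (required unless
#'   `rarefy_depth` is `NULL`).
#' @param simpson_variant Passed to [simpson()].
#' @return A tibble with columns `sample_id`, `observed_otus`, `chao1`,
#'   `shannon`, `simpson`.
#' @examples
#' m <- matrix(rpois(40, 5), 8, 5,
#'             dimnames = list(paste0("F", 1:8), paste0("S", 1:5)))
#' diversity_table(otu_table(m), rarefy_depth = NULL)
#' @export
diversity_table <- function(table, rarefy_depth = min(sample_depths(table)),
                            seed = NULL, simpson_variant = "gini-simpson") {
  if (!is.null(rarefy_depth)) {
    if (is.null(seed)) abort("`seed` is required when rarefying.")
    table <- rarefy(table, depth = rarefy_depth, seed = seed)
  }
  counts <- table$counts
  tibble(
    sample_id = colnames(counts),
    observed_otus = unname(apply(counts, 2, observed_richness)),
    chao1 = unname(apply(counts, 2, chao1)),
    shannon = unname(apply(counts, 2, shannon)),
    simpson = unname(apply(counts, 2, function(x) simpson(x, variant = simpson_variant)))
  )
}

#' Compare a diversity metric between two groups
#'
#' Two-sided Wilcoxon rank-sum comparison of a per-sample metric between
#' two groups. Groups with fewer than two samples give an inconclusive
#' p of 1 with a warning.
#'
#' @param profiles Tibble from [diversity_table()] (or any tibble with
#'   `sample_id` and the metric column).
#' @param metadata Sample metadata tibble with `sample_id` and `group`.
#' @param metric Column name of the metric to compare.
#' @param group_a,group_b Group labels.
#' @return A one-row tibble: `metric`, `group_a`, `group_b`, `statistic`,
#'   `p_value`.
#' @export
compare_groups <- function(profiles, metadata, metric, group_a, group_b) {
  metadata <- validate_metadata(metadata)
  joined <- dplyr::inner_join(profiles, metadata[, c("sample_id", "group")], by = "sample_id")
  if (!metric %in% names(joined)) abort(sprintf("Unknown metric '%s'.", metric))
  x <- joined[[metric]][joined$group == group_a]
  y <- joined[[metric]][joined$group == group_b]
  if (length(x) == 0 || length(y) == 0)
    abort("Both groups must contain at least one sample.")
  if (length(x) < 2 || length(y) < 2) {
    warn("A group has fewer than 2 samples; comparison is inconclusive.")
    return(tibble(metric = metric, group_a = group_a, group_b = group_b,
                  statistic = NA_real_, p_value = 1))
  }
  res <- wilcoxon_rank_sum(x, y)
  tibble(metric = metric, group_a = group_a, group_b = group_b,
         statistic = res$statistic, p_value = res$p_value)
}

#' Cumulative dominance curve
#'
#' Fraction of a sample's reads contained in its `k` most abundant
#' features, for `k = 1..k_max`. Once `k` exceeds the sample's richness the
#' curve is padded at 1. The value at `k = 100` is the "top-100 dominance
#' fraction" used to characterise how strongly a community is dominated by
#' few taxa.
#'
#' @param counts Non-negative count vector with at least one positive
#'   entry.
#' @param k_max Number of curve points (>= 1).
#' @return Numeric vector of length `k_max`, non-decreasing, ending at 1
#'   when `k_max >= ` richness.
#' @examples
#' dominance_curve(c(50, 30, 20), k_max = 3)  # 0.5, 0.8, 1.0
#' @export
dominance_curve <- function(counts, k_max = 100L) {
  check_community(counts)
  if (k_max < 1) abort("`k_max` must be >= 1.")
  sorted <- sort(counts[counts > 0], decreasing = TRUE)
  cum <- cumsum(sorted) / sum(sorted)
  out <- rep(1, k_max)
  k <- min(k_max, length(cum))
  out[seq_len(k)] <- cum[seq_len(k)]
  out
}

#' Group-mean dominance curves for a cohort
#'
#' @param table An [otu_table()].
#' @param metadata Metadata tibble with `sample_id`, `group`.
#' @param k_max Number of curve points.
#' @return A tibble `group`, `k`, `fraction` with the per-group mean
#'   cumulative dominance fraction at each `k`.
#' @export
dominance_summary <- function(table, metadata, k_max = 100L) {
  metadata <- validate_metadata(metadata)
  curves <- purrr::map(sample_ids(table), function(s)
    dominance_curve(table$counts[, s], k_max = k_max))
  names(curves) <- sample_ids(table)
  long <- purrr::imap_dfr(curves, function(v, s)
    tibble(sample_id = s, k = seq_len(k_max), fraction = v))
  long <- dplyr::inner_join(long, metadata[, c("sample_id", "group")], by = "sample_id")
  dplyr::summarise(dplyr::group_by(long, .data$group, .data$k),
                   fraction = mean(.data$fraction), .groups = "drop")
}
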