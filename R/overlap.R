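#' Pairwise shared/unique overlap between samples
#'
#' For every unordered pair of samples, decomposes both the richness
#' (presence/absence) and the abundance (reads) into three fractions that
#' sum to one: shared (`com_*`), unique to the first sample (`x_uni_*`),
#' and unique to the second (`y_uni_*`). The richness decomposition is
#' over the union of features present in either sample, so `com_richness`
#' is the Jaccard index. The abundance decomposition pools the two
#' samples' reads: `com_abundance` is the fraction of the pooled reads
#' falling in shared features (mode `"pooled"`, default); mode
#' `"min_relative"` instead uses the Bray-Curtis-style overlap
#' \eqn{\sum_i \min(p_{xi}, p_{yi})} of relative abundances, splitting the
#' remainder evenly between the two unique slices.
#'
#' Pairs are categorised by their samples' groups: HO+HO is `O2O`
#' (within-oral), HT+HT is `T2T` (within-tooth), HO+HT is `O2T`
#' (oral-tooth); any other combination is labelled by the two group names.
#'
#' @param table An [otu_table()] (presence is taken from raw counts;
#'   rarefy first if depth-standardised presence is wanted).
#' @param metadata Metadata tibble with `sample_id`, `group`.
#' @param samples Sample ids to include (default: all samples of the
#'   table that appear in the metadata).
#' @param abundance_mode `"pooled"` or `"min_relative"`.
#' @return A tibble, one row per unordered pair, with columns `sample_x`,
#'   `sample_y`, `category`, `com_richness`, `x_uni_richness`,
#'   `y_uni_richness`, `com_abundance`, `x_uni_abundance`,
#'   `y_uni_abundance`.
#' @export
pairwise_overlap <- function(table, metadata, samples = NULL,
                             abundance_mode = c("pooled", "min_relative")) {
  abundance_mode <- match.arg(abundance_mode)
  metadata <- validate_metadata(metadata)
  samples <- samples %||% intersect(sample_ids(table), metadata$sample_id)
  bad <- setdiff(samples, sample_ids(table))
  if (length(bad) > 0)
    abort(paste0("Sample(s) not in table: ", toString(utils::head(bad, 5))))
  bad <- setdiff(samples, metadata$sample_id)
  if (length(bad) > 0)
    abort(paste0("Sample(s) not in metadata: ", toString(utils::head(bad, 5))))
  if (length(samples) < 2) abort("At least two samples are required.")
  groups <- metadata$group[match(samples, metadata$sample_id)]
  counts <- table$counts[, samples, drop = FALSE]
  pairs <- utils::combn(seq_along(samples), 2)
  categorise <- function(g1, g2) {
    key <- paste(sort(c(g1, g2)), collapse = "+")
    switch(key, "HO+HO" = "O2O", "HT+HT" = "T2T", "HO+HT" = "O2T", key)
  }
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    x <- counts[, i]; y <- counts[, j]
    px <- x > 0; py <- y > 0
    union_n <- sum(px | py)
    shared <- px & py
    com_rich <- if (union_n > 0) sum(shared) / union_n else 0
    x_uni_rich <- if (union_n > 0) sum(px & !py) / union_n else 0
    y_uni_rich <- if (union_n > 0) sum(py & !px) / union_n else 0
    if (abundance_mode == "pooled") {
      tot <- sum(x) + sum(y)
      com_ab <- (sum(x[shared]) + sum(y[shared])) / tot
      x_uni_ab <- sum(x[px & !py]) / tot
      y_uni_ab <- sum(y[py & !px]) / tot
    } else {
      rx <- x / sum(x); ry <- y / sum(y)
      com_ab <- sum(pmin(rx, ry))
      x_uni_ab <- (1 - com_ab) / 2
      y_uni_ab <- (1 - com_ab) / 2
    }
    tibble(sample_x = samples[i], sample_y = samples[j],
           category = categorise(groups[i], groups[j]),
           com_richness = com_rich, x_uni_richness = x_uni_rich,
           y_uni_richness = y_uni_rich,
           com_abundance = com_ab, x_uni_abundance = x_uni_ab,
           y_uni_abundance = y_uni_ab)
  })
}

#' Summarise overlap records by pair category
#'
#' Per-category location summaries of the shared-richness and
#' shared-abundance fractions, plus two-sided rank-sum comparisons between
#' every pair of categories.
#'
#' @param records Tibble from [pairwise_overlap()].
#' @return A list of class `overlap_summary` with elements `by_category`
#'   (mean/median/quartiles per category and measure) and `tests`
#'   (category pair, measure, statistic, p_value).
#' @export
overlap_summary <- function(records) {
  if (length(unique(records$category)) < 2)
    warn("Fewer than two categories; no between-category tests possible.")
  long <- tidyr::pivot_longer(
    records[, c("category", "com_richness", "com_abundance")],
    cols = c("com_richness", "com_abundance"),
    names_to = "measure", values_to = "value")
  by_cat <- dplyr::summarise(
    dplyr::group_by(long, .data$category, .data$measure),
    n_pairs = dplyr::n(),
    mean = mean(.data$value),
    q1 = unname(stats::quantile(.data$value, 0.25)),
    median = stats::median(.data$value),
    q3 = unname(stats::quantile(.data$value, 0.75)),
    .groups = "drop")
  cats <- sort(unique(records$category))
  tests <- NULL
  if (length(cats) >= 2) {
    combos <- utils::combn(cats, 2)
    tests <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
      purrr::map_dfr(c("com_richness", "com_abundance"), function(m) {
        x <- records[[m]][records$category == combos[1, k]]
        y <- records[[m]][records$category == combos[2, k]]
        res <- wilcoxon_rank_sum(x, y)
        tibble(category_a = combos[1, k], category_b = combos[2, k],
               measure = m, statistic = res$statistic, p_value = res$p_value)
      })
    })
  }
  structure(list(by_category = by_cat, tests = tests), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("# Overlap summary by pair category\n")
  print(x$by_category)
  if (!is.null(x$tests)) {
    cat("# Between-category rank-sum tests\n")
    print(x$tests)
  }
  invisible(x)
}
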