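#' Parse radiographic lesion dimension strings
#'
#' Clinical tables record periapical lesion sizes as free text such as
#' "4×5 mm" or "4x3mm" (two dimensions in millimetres, "×" or "x"
#' delimiter, optional "mm" suffix). The maximum dimension classifies the
#' lesion: LSA (large surface area) when it is at least 5 mm, SSA (small)
#' otherwise.
#'
#' @param raw Character vector of lesion strings.
#' @return A tibble with columns `raw`, `dim1_mm`, `dim2_mm`, `max_mm`,
#'   `label` (`"LSA"`/`"SSA"`). Unparseable strings are an error naming
#'   the offending value.
#' @examples
#' parse_lesion(c("3×2 mm", "4x5mm"))
#' @export
parse_lesion <- function(raw) {
  pat <- "^\\s*([0-9]+(?:\\.[0-9]+)?)\\s*[x×]\\s*([0-9]+(?:\\.[0-9]+)?)\\s*(?:mm)?\\s*$"
  ok <- grepl(pat, raw, ignore.case = TRUE)
  if (any(!ok))
    abort(sprintf("Cannot parse lesion string '%s'.", raw[!ok][1]))
  d1 <- as.numeric(sub(pat, "\\1", raw, ignore.case = TRUE))
  d2 <- as.numeric(sub(pat, "\\2", raw, ignore.case = TRUE))
  mx <- pmax(d1, d2)
  tibble(raw = raw, dim1_mm = d1, dim2_mm = d2, max_mm = mx,
         label = ifelse(mx >= 5, "LSA", "SSA"))
}

#' Hierarchical subtype clustering of diseased samples
#'
#' Clusters samples (typically the untreated-disease group) on their
#' genus-level community profiles: relative abundances, a Bray-Curtis
#' dissimilarity (default), agglomerative clustering with complete
#' linkage (default), and a tree cut at `k` clusters. The result is
#' deterministic for a given table; cluster letters are assigned in order
#' of first appearance over lexicographically sorted sample ids.
#'
#' @param table An [otu_table()], normally aggregated to genus level with
#'   [aggregate_taxa()].
#' @param samples Sample ids to cluster (default: all).
#' @param k Number of clusters (default 2, labelled A and B).
#' @param distance `"bray-curtis"`, `"euclidean"` or `"jaccard"`.
#' @param linkage `"complete"`, `"average"` or `"ward"`.
#' @return A tibble `sample_id`, `cluster` (letters).
#' @export
hierarchical_subtypes <- function(table, samples = NULL, k = 2,
                                  distance = c("bray-curtis", "euclidean", "jaccard"),
                                  linkage = c("complete", "average", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  samples <- samples %||% sample_ids(table)
  if (length(samples) < k)
    abort(sprintf("Need at least %d samples to form %d clusters.", k, k))
  sub <- subset_table(table, samples = samples)
  rel <- t(relative_abundance(sub))
  d <- switch(distance,
    "bray-curtis" = vegan::vegdist(rel, method = "bray"),
    "euclidean" = stats::dist(rel),
    "jaccard" = vegan::vegdist(rel > 0, method = "jaccard"))
  method <- switch(linkage, complete = "complete", average = "average", ward = "ward.D2")
  hc <- stats::hclust(d, method = method)
  cl <- stats::cutree(hc, k = k)
  first_seen <- unique(cl[order(names(cl))])
  relabel <- stats::setNames(LETTERS[seq_len(k)], first_seen)
  tibble(sample_id = samples,
         cluster = unname(relabel[as.character(cl[samples])]))
}

#' Concordance between a 2-cluster assignment and binary clinical labels
#'
#' Accuracy is the best achievable agreement over the two possible
#' cluster-to-label mappings (so it is at least 0.5 and invariant to
#' swapping the cluster letters). Significance is assessed by a
#' label-permutation test with the standard +1 correction, or by Fisher's
#' exact test on the 2x2 cluster-by-label table.
#'
#' @param assignment Tibble (`sample_id`, `cluster`) from
#'   [hierarchical_subtypes()], or a named vector.
#' @param labels Tibble (`sample_id`, `label`), or a named vector, over
#'   the same sample set.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Seed for the permutation draw.
#' @param method `"permutation"` or `"fisher"`.
#' @return A list of class `subtype_result`: `table` (per-sample tibble
#'   with `agreement` flags under the best mapping), `accuracy`,
#'   `p_value`, `mapping` (named vector cluster -> label), `method`.
#' @export
concordance <- function(assignment, labels, n_perm = 10000L, seed = 1L,
                        method = c("permutation", "fisher")) {
  method <- match.arg(method)
  if (is.data.frame(assignment))
    assignment <- stats::setNames(assignment$cluster, assignment$sample_id)
  if (is.data.frame(labels)) {
    lab_col <- intersect(c("label", "level", "levels"), tolower(names(labels)))[1]
    if (is.na(lab_col)) abort("`labels` must have a `label` column.")
    labels <- stats::setNames(labels[[which(tolower(names(labels)) == lab_col)]],
                              labels$sample_id)
  }
  if (!setequal(names(assignment), names(labels)))
    abort("`assignment` and `labels` must cover the same sample set.")
  labels <- labels[names(assignment)]
  cl_levels <- sort(unique(assignment))
  lab_levels <- sort(unique(labels))
  if (length(cl_levels) > 2 || length(lab_levels) > 2)
    abort("Concordance is defined for two clusters and two labels.")
  cl_levels <- rep(cl_levels, length.out = 2)
  lab_levels <- rep(lab_levels, length.out = 2)
  best_acc <- function(lab) {
    m1 <- mean((assignment == cl_levels[1]) == (lab == lab_levels[1]))
    max(m1, 1 - m1)
  }
  acc <- best_acc(labels)
  n <- length(labels)
  if (method == "permutation") {
    perm_acc <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) best_acc(sample(labels)), numeric(1))
    })
    p <- (1 + sum(perm_acc >= acc - 1e-12)) / (n_perm + 1)
  } else {
    tab <- table(assignment, labels)
    p <- stats::fisher.test(tab)$p.value
  }
  m1 <- mean((assignment == cl_levels[1]) == (labels == lab_levels[1]))
  mapping <- if (m1 >= 1 - m1) {
    stats::setNames(lab_levels, cl_levels)
  } else {
    stats::setNames(rev(lab_levels), cl_levels)
  }
  per_sample <- tibble(
    sample_id = names(assignment),
    cluster = unname(assignment),
    label = unname(labels),
    agreement = unname(mapping[assignment] == labels)
  )
  structure(list(table = per_sample, accuracy = acc, p_value = p,
                 mapping = mapping, method = method),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("# Cluster-label concordance: accuracy %.3f (%s p = %.3g)\n",
              x$accuracy, x$method, x$p_value))
  cat(sprintf("# mapping: %s\n",
              paste(names(x$mapping), x$mapping, sep = " -> ", collapse = ", ")))
  invisible(x)
}

#' Tidy and summarise a concordance result
#'
#' @param x A `subtype_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-sample agreement tibble. `glance()`: one row
#'   with `accuracy`, `n`, `n_agree`, `p_value`, `method`.
#' @method tidy subtype_result
#' @export
tidy.subtype_result <- function(x, ...) x$table

#' @rdname tidy.subtype_result
#' @method glance subtype_result
#' @export
glance.subtype_result <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = nrow(x$table),
         n_agree = sum(x$table$agreement),
         p_value = x$p_value, method = x$method)
}
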