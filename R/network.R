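#' Pairwise Pearson correlations with t-test p-values
#'
#' Correlates every pair of features across samples and converts each
#' correlation to a two-sided p-value through the t transform
#' \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} with \eqn{n-2} degrees of
#' freedom. Features with zero variance across samples are excluded with
#' a warning (their correlation is undefined).
#'
#' @param abundance Numeric matrix, features x samples (e.g. rarefied
#'   counts of the significant features across the whole cohort).
#' @return A list with `r` (correlation matrix, unit diagonal) and `p`
#'   (two-sided p-value matrix, diagonal `NA`), both restricted to the
#'   retained features.
#' @export
correlation_matrix <- function(abundance) {
  if (ncol(abundance) < 3) abort("At least 3 samples are required.")
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("F", seq_len(nrow(abundance)))
  v <- apply(abundance, 1, stats::var)
  if (any(v == 0)) {
    warn(sprintf("Excluding %d zero-variance feature(s).", sum(v == 0)))
    abundance <- abundance[v > 0, , drop = FALSE]
  }
  n <- ncol(abundance)
  r <- stats::cor(t(abundance), method = "pearson")
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(r) <- 1
  diag(p) <- NA_real_
  list(r = r, p = p)
}

#' Adjust edge p-values for multiple testing
#'
#' Holm step-down (default) or Benjamini-Hochberg step-up adjustment. For
#' a symmetric p-value matrix the adjustment is computed once over the
#' strictly-upper-triangle entries and mirrored back.
#'
#' @param p Numeric vector, or symmetric matrix with `NA` diagonal.
#' @param method `"holm"` or `"bh"`.
#' @return Adjusted p-values in the same shape as the input.
#' @examples
#' adjust_pvalues(c(0.01, 0.04), method = "holm")  # 0.02, 0.04
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  method_r <- if (method == "bh") "BH" else "holm"
  if (is.matrix(p)) {
    ut <- upper.tri(p)
    adj <- p
    adj[ut] <- stats::p.adjust(p[ut], method = method_r)
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    return(adj)
  }
  stats::p.adjust(p, method = method_r)
}

#' Build a thresholded co-occurrence network
#'
#' Keeps an edge between two features when the absolute correlation
#' exceeds `r_min` and the adjusted p-value is below `alpha` (the absolute
#' value is used so that strong negative co-occurrences are kept as
#' negative edges). Isolated nodes are retained; connected components are
#' labelled and each node's k-core index (the largest k such that the
#' node survives iterative removal of all nodes of degree < k) is
#' computed.
#'
#' @param r Correlation matrix.
#' @param p_adj Adjusted p-value matrix (same shape; `NA` diagonal).
#' @param r_min Absolute-correlation threshold (default 0.6).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param directions Optional named character vector (or tibble with
#'   `feature_id`, `direction`) annotating nodes, e.g. up/down calls from
#'   a differential analysis.
#' @return A list of class `corr_network`: `graph` (igraph object),
#'   `nodes` (tibble: feature_id, direction, degree, component, k_core),
#'   `edges` (tibble: u, v, r, p_adj, sign).
#' @export
build_network <- function(r, p_adj, r_min = 0.6, alpha = 0.05, directions = NULL) {
  stopifnot(identical(dim(r), dim(p_adj)))
  ids <- rownames(r) %||% paste0("F", seq_len(nrow(r)))
  keep <- upper.tri(r) & abs(r) > r_min & !is.na(p_adj) & p_adj < alpha
  idx <- which(keep, arr.ind = TRUE)
  r_kept <- r[keep]
  edges <- tibble(
    u = ids[idx[, 1]], v = ids[idx[, 2]],
    r = r_kept, p_adj = p_adj[keep],
    sign = ifelse(r_kept > 0, "positive", "negative")
  )
  g <- igraph::graph_from_data_frame(edges[, c("u", "v")], directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  core <- igraph::coreness(g)
  nodes <- tibble(
    feature_id = ids,
    degree = unname(igraph::degree(g)[ids]),
    component = unname(comp$membership[ids]),
    k_core = unname(core[ids])
  )
  if (!is.null(directions)) {
    if (is.data.frame(directions)) {
      dirs <- stats::setNames(directions$direction, directions$feature_id)
    } else dirs <- directions
    nodes$direction <- unname(dirs[nodes$feature_id])
  } else nodes$direction <- NA_character_
  nodes <- nodes[, c("feature_id", "direction", "degree", "component", "k_core")]
  structure(list(graph = g, nodes = nodes, edges = edges), class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("# Co-occurrence network: %d nodes, %d edges (%d negative), %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "negative"),
              max(x$nodes$component)))
  cat(sprintf("# k-core range: %d - %d\n", min(x$nodes$k_core), max(x$nodes$k_core)))
  invisible(x)
}

#' k-core decomposition of a network
#'
#' Standard peeling: repeatedly remove nodes of degree < k; a node's core
#' index is the largest k at which it survives.
#'
#' @param network A `corr_network` (from [build_network()]) or an igraph
#'   object.
#' @return Named integer vector: node -> core index.
#' @export
k_core_decomposition <- function(network) {
  g <- if (inherits(network, "corr_network")) network$graph else network
  igraph::coreness(g)
}

#' End-to-end co-occurrence network from an OTU table
#'
#' Rarefies the table, restricts it to the requested features (typically
#' the significant OTUs of a differential analysis), computes Pearson
#' correlations across all samples, adjusts the edge p-values, and builds
#' the thresholded network.
#'
#' @param table An [otu_table()].
#' @param features Feature ids to correlate.
#' @param r_min,alpha Edge thresholds (defaults 0.6 and 0.05).
#' @param adjust `"holm"` or `"bh"`.
#' @param seed Seed for the rarefaction draw.
#' @param directions Optional node annotation (see [build_network()]).
#' @return A `corr_network`.
#' @export
cooccurrence_network <- function(table, features, r_min = 0.6, alpha = 0.05,
                                 adjust = c("holm", "bh"), seed = 1L,
                                 directions = NULL) {
  adjust <- match.arg(adjust)
  table <- rarefy(table, seed = seed)
  sub <- subset_table(table, features = features)
  cm <- correlation_matrix(sub$counts)
  p_adj <- adjust_pvalues(cm$p, method = adjust)
  build_network(cm$r, p_adj, r_min = r_min, alpha = alpha, directions = directions)
}

#' Tidy a co-occurrence network
#'
#' `tidy()` returns the edge list; `glance()` a one-row summary of the
#' network's size, components and k-core range.
#'
#' @param x A `corr_network`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy corr_network
#' @export
tidy.corr_network <- function(x, ...) x$edges

#' @rdname tidy.corr_network
#' @method glance corr_network
#' @export
glance.corr_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_negative_edges = sum(x$edges$sign == "negative"),
    n_components = max(x$nodes$component),
    max_k_core = max(x$nodes$k_core)
  )
}
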