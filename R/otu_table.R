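#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
TAX_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
GROUP_LEVELS <- c("HO", "HT", "NRCT", "RCT")

#' Construct an OTU count table
#'
#' The central data container of the package: a non-negative integer count
#' matrix (features in rows, samples in columns) together with an optional
#' per-feature taxonomy at the seven canonical ranks (kingdom through
#' species). All downstream stages — rarefaction, diversity, differential
#' abundance, overlap, networks, subtyping — consume this container.
#'
#' @param counts Integer matrix, features x samples, with row and column
#'   names giving feature and sample identifiers.
#' @param taxonomy Optional data frame with a `feature_id` column and any of
#'   the rank columns `kingdom`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species` (missing ranks are `NA`). Row order need not match
#'   `counts`.
#' @return An object of class `otu_table`.
#' @examples
#' m <- matrix(c(3L, 0L, 4L, 2L), 2, 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' otu_table(m)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts)) abort("`counts` must be a matrix (features x samples).")
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    abort("Duplicate feature ids in count matrix.")
  if (anyDuplicated(colnames(counts)))
    abort("Duplicate sample ids in count matrix.")
  if (length(counts) > 0) {
    if (any(!is.finite(counts)) || any(counts < 0))
      abort("Counts must be finite and non-negative.")
    if (any(counts != round(counts)))
      abort("Counts must be integers.")
  }
  storage.mode(counts) <- "integer"
  tax <- empty_taxonomy(rownames(counts))
  if (!is.null(taxonomy)) {
    taxonomy <- as_tibble(taxonomy)
    if (!"feature_id" %in% names(taxonomy))
      abort("`taxonomy` must have a `feature_id` column.")
    missing_ft <- setdiff(rownames(counts), taxonomy$feature_id)
    keep <- intersect(names(taxonomy), c("feature_id", TAX_RANKS))
    taxonomy <- taxonomy[taxonomy$feature_id %in% rownames(counts), keep]
    for (r in TAX_RANKS) if (!r %in% names(taxonomy)) taxonomy[[r]] <- NA_character_
    if (length(missing_ft) > 0)
      taxonomy <- dplyr::bind_rows(taxonomy, empty_taxonomy(missing_ft))
    tax <- taxonomy[match(rownames(counts), taxonomy$feature_id),
                    c("feature_id", TAX_RANKS)]
    for (r in TAX_RANKS) {
      v <- as.character(tax[[r]])
      v[!is.na(v) & v == ""] <- NA_character_
      tax[[r]] <- v
    }
  }
  if (nrow(counts) > 0 && any(colSums(counts) == 0))
    warn("Some samples have zero total counts.")
  structure(list(counts = counts, taxonomy = tax), class = "otu_table")
}

empty_taxonomy <- function(feature_ids) {
  tax <- tibble(feature_id = as.character(feature_ids))
  for (r in TAX_RANKS) tax[[r]] <- NA_character_
  tax
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (ncol(x$counts) > 0 && nrow(x$counts) > 0) {
    d <- colSums(x$counts)
    cat(sprintf("  sample depths: %d - %d (median %d)\n",
                min(d), max(d), as.integer(stats::median(d))))
  }
  n_tax <- sum(!is.na(x$taxonomy$kingdom))
  cat(sprintf("  taxonomy present for %d features\n", n_tax))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Number of features / samples in an OTU table
#' @param table An `otu_table`.
#' @return An integer scalar.
#' @export
n_features <- function(table) nrow(table$counts)

#' @rdname n_features
#' @export
n_samples <- function(table) ncol(table$counts)

#' Feature and sample identifiers
#' @param table An `otu_table`.
#' @return A character vector.
#' @export
feature_ids <- function(table) rownames(table$counts)

#' @rdname feature_ids
#' @export
sample_ids <- function(table) colnames(table$counts)

#' Per-sample library sizes (total read counts)
#' @param table An `otu_table`.
#' @return Named integer vector of column sums.
#' @export
sample_depths <- function(table) colSums(table$counts)

#' Subset an OTU table by feature and/or sample identifiers
#'
#' @param table An `otu_table`.
#' @param features,samples Character vectors of identifiers to keep (default:
#'   all). Unknown identifiers are an error.
#' @return An `otu_table`.
#' @export
subset_table <- function(table, features = NULL, samples = NULL) {
  f <- features %||% feature_ids(table)
  s <- samples %||% sample_ids(table)
  bad <- setdiff(f, feature_ids(table))
  if (length(bad) > 0) abort(paste0("Unknown feature id(s): ", toString(utils::head(bad, 5))))
  bad <- setdiff(s, sample_ids(table))
  if (length(bad) > 0) abort(paste0("Unknown sample id(s): ", toString(utils::head(bad, 5))))
  counts <- table$counts[f, s, drop = FALSE]
  out <- otu_table(counts, table$taxonomy[match(f, table$taxonomy$feature_id), ])
  out
}

#' Tidy a count table into long format
#'
#' @param x An `otu_table`.
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `count` plus the
#'   taxonomy ranks.
#' @method as_tibble otu_table
#' @export
as_tibble.otu_table <- function(x, ...) {
  long <- tibble(
    feature_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
  dplyr::left_join(long, x$taxonomy, by = "feature_id")
}

# ---- taxonomy lineage <-> rank columns --------------------------------------

parse_lineage <- function(lineage) {
  out <- rep(NA_character_, length(TAX_RANKS))
  names(out) <- TAX_RANKS
  if (is.na(lineage) || !nzchar(trimws(lineage))) return(out)
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  for (i in seq_along(parts)) {
    if (i > length(TAX_RANKS)) break
    nm <- sub("^[a-z]__", "", parts[i])
    out[i] <- if (nzchar(nm)) nm else NA_character_
  }
  out
}

format_lineage <- function(tax_row) {
  ranks <- unlist(tax_row[TAX_RANKS], use.names = FALSE)
  last <- max(c(0L, which(!is.na(ranks))))
  if (last == 0L) return("")
  nm <- ranks[seq_len(last)]
  nm[is.na(nm)] <- ""
  paste0(TAX_PREFIXES[seq_len(last)], nm, collapse = "; ")
}

has_taxonomy <- function(table) {
  any(!is.na(unlist(table$taxonomy[TAX_RANKS])))
}

# ---- I/O --------------------------------------------------------------------

#' Read a classic tab-separated OTU table
#'
#' Reads the classic QIIME text dialect: a tab-separated file whose first
#' column holds feature (OTU) ids, whose remaining columns hold integer
#' counts per sample, and whose optional last column `taxonomy` carries a
#' Greengenes-style lineage string (`k__Bacteria; p__Firmicutes; ...`).
#' A leading `#OTU ID` marker on the header is tolerated, as are comment
#' lines above the header.
#'
#' @param path Path to the file.
#' @return An [otu_table()].
#' @seealso [write_otu_table()]
#' @export
read_otu_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("'%s' is empty.", path))
  is_header <- function(l) !startsWith(l, "#") || grepl("^#\\s*OTU", l, ignore.case = TRUE)
  h <- which(vapply(lines, is_header, logical(1)))[1]
  if (is.na(h)) abort(sprintf("'%s' has no header row.", path))
  lines <- lines[h:length(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  n_col <- length(header)
  if (n_col < 1) abort("Malformed header row.")
  tax_col <- length(header) > 1 &&
    tolower(header[n_col]) %in% c("taxonomy", "consensus lineage", "taxon")
  samp_idx <- seq(2, length.out = n_col - 1 - tax_col)
  sample_names <- header[samp_idx]
  rows <- fields[-1]
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != n_col)
      abort(sprintf("Parse error at line %d of '%s': expected %d fields, found %d.",
                    h + i, path, n_col, length(rows[[i]])))
  }
  ids <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    abort(sprintf("Duplicate feature id '%s' in '%s'.", ids[duplicated(ids)][1], path))
  counts <- matrix(0L, nrow = length(rows), ncol = length(samp_idx),
                   dimnames = list(ids, sample_names))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][samp_idx]))
    if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
      abort(sprintf("Parse error at line %d of '%s': counts must be non-negative integers.",
                    h + i, path))
    counts[i, ] <- as.integer(v)
  }
  taxonomy <- NULL
  if (tax_col) {
    lineages <- vapply(rows, `[[`, character(1), n_col)
    ranks <- t(vapply(lineages, parse_lineage, character(length(TAX_RANKS))))
    taxonomy <- as_tibble(ranks)
    taxonomy$feature_id <- ids
  }
  otu_table(counts, taxonomy)
}

#' Write an OTU table in the classic tab-separated dialect
#'
#' Emits the same dialect accepted by [read_otu_table()], so that a
#' write/read round trip reproduces the table exactly. The taxonomy column
#' is omitted when no feature has any rank assigned.
#'
#' @param table An `otu_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_otu_table <- function(table, path) {
  with_tax <- has_taxonomy(table)
  header <- c("#OTU ID", sample_ids(table), if (with_tax) "taxonomy")
  body <- character(n_features(table))
  for (i in seq_len(n_features(table))) {
    cells <- c(feature_ids(table)[i], format(table$counts[i, ], scientific = FALSE, trim = TRUE))
    if (with_tax) cells <- c(cells, format_lineage(table$taxonomy[i, ]))
    body[i] <- paste(cells, collapse = "\t")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), body), con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with required columns `sample_id`, `group` (one of HO, HT,
#' NRCT, RCT), `subject_id`, and optional `lesion` (free text such as
#' "4x5 mm", diseased samples only) and `subtype` (A/B).
#'
#' @param path Path to the file.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_metadata(meta)
}

#' Validate a sample metadata data frame
#'
#' @param meta Data frame with at least `sample_id`, `group`, `subject_id`.
#' @return The validated metadata as a tibble.
#' @export
validate_metadata <- function(meta) {
  meta <- as_tibble(meta)
  need <- c("sample_id", "group", "subject_id")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0)
    abort(paste0("Metadata is missing column(s): ", toString(missing)))
  if (anyDuplicated(meta$sample_id)) abort("Duplicate sample_id in metadata.")
  bad <- setdiff(unique(meta$group), GROUP_LEVELS)
  if (length(bad) > 0)
    abort(paste0("Unknown group label(s): ", toString(bad),
                 " (expected ", toString(GROUP_LEVELS), ")"))
  if (!"lesion" %in% names(meta)) meta$lesion <- NA_character_
  if (!"subtype" %in% names(meta)) meta$subtype <- NA_character_
  meta
}

#' Write sample metadata
#' @param meta Metadata tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

# ---- transformations --------------------------------------------------------

#' Aggregate features at a taxonomic level
#'
#' Features sharing an identical lineage down to `level` (the full prefix
#' of rank names, not the bare name at `level`, so homonymous genera in
#' different families are kept apart) are summed per sample. Features with
#' no name at `level` are pooled into a single "unassigned" feature whose
#' taxonomy keeps the ranks on which all pooled features agree. Per-sample
#' totals are conserved.
#'
#' @param table An `otu_table`.
#' @param level One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return An `otu_table` with one feature per distinct lineage.
#' @export
aggregate_taxa <- function(table, level = c("phylum", "class", "order", "family", "genus")) {
  level <- match.arg(level)
  if (n_features(table) == 0) return(table)
  li <- match(level, TAX_RANKS)
  ranks_used <- TAX_RANKS[seq_len(li)]
  tax <- table$taxonomy
  assigned <- !is.na(tax[[level]])
  key <- rep("unassigned", n_features(table))
  if (any(assigned)) {
    mat <- as.matrix(tax[assigned, ranks_used, drop = FALSE])
    mat[is.na(mat)] <- ""
    key[assigned] <- apply(mat, 1, function(r)
      paste0(TAX_PREFIXES[seq_len(li)], r, collapse = ";"))
  }
  agg <- rowsum(table$counts, group = key, reorder = TRUE)
  storage.mode(agg) <- "integer"
  new_tax <- lapply(rownames(agg), function(k) {
    members <- tax[key == k, TAX_RANKS, drop = FALSE]
    if (k == "unassigned") {
      consensus <- vapply(TAX_RANKS[seq_len(li)], function(r) {
        v <- unique(members[[r]])
        if (length(v) == 1 && !is.na(v)) v else NA_character_
      }, character(1))
    } else {
      consensus <- unlist(members[1, seq_len(li)], use.names = FALSE)
    }
    c(consensus, rep(NA_character_, length(TAX_RANKS) - li))
  })
  new_tax <- as_tibble(do.call(rbind, new_tax), .name_repair = ~TAX_RANKS)
  new_tax$feature_id <- rownames(agg)
  otu_table(agg, new_tax)
}

#' Rarefy samples to a common depth
#'
#' Down-samples each sample's reads uniformly without replacement (one
#' multivariate-hypergeometric draw per sample) to exactly `depth` reads,
#' the normalisation used before all between-sample comparisons. Samples
#' whose library is smaller than `depth` are dropped with a warning.
#'
#' @param table An `otu_table`.
#' @param depth Target depth; defaults to the minimum library size.
#' @param seed Integer seed making the draw reproducible. Required.
#' @return An `otu_table` whose column sums all equal `depth`.
#' @export
rarefy <- function(table, depth = min(sample_depths(table)), seed) {
  if (missing(seed)) abort("`seed` is required for reproducible rarefaction.")
  depth <- as.numeric(depth)
  if (length(depth) != 1 || !is.finite(depth) || depth <= 0 || depth != round(depth))
    abort("`depth` must be a positive integer.")
  depths <- sample_depths(table)
  keep <- names(depths)[depths >= depth]
  if (length(keep) < length(depths))
    warn(sprintf("Dropping %d sample(s) with depth < %d: %s",
                 length(depths) - length(keep), depth,
                 toString(setdiff(names(depths), keep))))
  if (length(keep) == 0) abort("No sample reaches the requested depth.")
  sub <- table$counts[, keep, drop = FALSE]
  rar <- withr::with_seed(as.integer(seed), {
    # rrarefy heuristically warns when the smallest positive count exceeds
    # one; irrelevant for validated integer tables
    withCallingHandlers(
      t(vegan::rrarefy(t(sub), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  })
  storage.mode(rar) <- "integer"
  otu_table(rar, table$taxonomy)
}

#' Per-sample relative abundances
#'
#' @param table An `otu_table` with strictly positive library sizes.
#' @return A numeric matrix (features x samples) whose columns sum to 1.
#' @export
relative_abundance <- function(table) {
  depths <- sample_depths(table)
  if (any(depths == 0)) abort("Zero-depth sample(s); cannot normalise.")
  sweep(table$counts, 2, depths, "/")
}

#' Filter features by prevalence
#'
#' Retains features detected (count > 0) in at least
#' `ceiling(min_fraction * n_samples)` samples, the screen applied before
#' differential testing.
#'
#' @param table An `otu_table`.
#' @param min_fraction Minimum fraction of samples, in (0, 1]. Default 0.10.
#' @return A filtered `otu_table`.
#' @export
prevalence_filter <- function(table, min_fraction = 0.10) {
  if (min_fraction <= 0 || min_fraction > 1)
    abort("`min_fraction` must be in (0, 1].")
  need <- ceiling(min_fraction * n_samples(table))
  prev <- rowSums(table$counts > 0)
  keep <- feature_ids(table)[prev >= need]
  subset_table(table, features = keep)
}
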