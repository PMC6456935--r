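stage_seed <- function(seed, stage) {
  stages <- c("simulate", "rarefy", "diversity", "differential", "overlap",
              "network", "subtype")
  offset <- match(stage, stages)
  if (is.na(offset)) abort(sprintf("Unknown stage '%s'.", stage))
  (as.integer(seed) %% 20000000L) * 100L + offset
}

#' Run the full cohort analysis pipeline
#'
#' Orchestrates the package end to end: simulate (or load) an OTU table
#' and metadata, then per-sample diversity with group comparisons,
#' differential abundance for the disease contrast at OTU and genus
#' level, pairwise sample overlap among the healthy samples, the
#' co-occurrence network over the significant OTUs, and genus-level
#' subtype clustering of the untreated-disease samples with
#' lesion-concordance testing. Every stage writes a tab-separated file
#' into `out_dir`, and a `manifest.tsv` records the seed, parameters and
#' per-stage row counts. All randomness derives from `seed` through
#' per-stage substreams, so any stage re-runs reproducibly.
#'
#' @param out_dir Output directory (created if needed).
#' @param table,metadata An [otu_table()] and metadata tibble, or paths
#'   to files readable by [read_otu_table()] / [read_sample_metadata()].
#'   When both are `NULL` a cohort is simulated from `design`.
#' @param design A [default_design()] used when simulating.
#' @param seed Root seed for the run.
#' @param steps Stages to run, a subset of `c("diversity",
#'   "differential", "overlap", "network", "subtype")` (simulation/loading
#'   always happens first).
#' @param config A [diff_config()] for the differential stage (the genus
#'   run reuses it with `level = "genus"`).
#' @param contrast Two group labels for the differential contrast
#'   (default NRCT vs HT).
#' @param r_min,alpha Network edge thresholds.
#' @return Invisibly, a list with every stage's in-memory result plus the
#'   manifest tibble.
#' @export
run_pipeline <- function(out_dir, table = NULL, metadata = NULL,
                         design = default_design(), seed = 1L,
                         steps = c("diversity", "differential", "overlap",
                                   "network", "subtype"),
                         config = diff_config(),
                         contrast = c("NRCT", "HT"),
                         r_min = 0.6, alpha = 0.05) {
  known <- c("diversity", "differential", "overlap", "network", "subtype")
  bad <- setdiff(steps, known)
  if (length(bad) > 0) abort(paste0("Unknown step(s): ", toString(bad)))
  if ("network" %in% steps && !"differential" %in% steps)
    abort("The network stage requires the differential stage.")
  if (xor(is.null(table), is.null(metadata)))
    abort("Provide both `table` and `metadata`, or neither (to simulate).")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, contrast = paste(contrast, collapse = " vs "),
                   q_threshold = config$q_threshold,
                   fc_threshold = config$fc_threshold, r_min = r_min,
                   alpha = alpha)
  results <- list()

  if (is.null(table)) {
    cohort <- simulate_cohort(design, seed = stage_seed(seed, "simulate"))
    table <- cohort$table
    metadata <- cohort$metadata
    results$truth <- cohort$truth
    manifest$simulated <- TRUE
  } else {
    if (is.character(table)) table <- read_otu_table(table)
    if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
    metadata <- validate_metadata(metadata)
    manifest$simulated <- FALSE
  }
  write_otu_table(table, file.path(out_dir, "otu_table.tsv"))
  write_sample_metadata(metadata, file.path(out_dir, "metadata.tsv"))
  results$table <- table
  results$metadata <- metadata
  manifest$n_features <- n_features(table)
  manifest$n_samples <- n_samples(table)

  if ("diversity" %in% steps) {
    profiles <- diversity_table(table, seed = stage_seed(seed, "diversity"))
    readr::write_tsv(profiles, file.path(out_dir, "diversity.tsv"))
    groups_present <- intersect(GROUP_LEVELS, unique(metadata$group))
    comparisons <- NULL
    if (length(groups_present) >= 2) {
      combos <- utils::combn(groups_present, 2)
      comparisons <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
        purrr::map_dfr(c("observed_otus", "chao1", "shannon", "simpson"),
                       function(m) compare_groups(profiles, metadata, m,
                                                  combos[1, k], combos[2, k]))
      })
      readr::write_tsv(comparisons, file.path(out_dir, "diversity_comparisons.tsv"))
    }
    dom <- dominance_summary(table, metadata, k_max = 100L)
    readr::write_tsv(dom, file.path(out_dir, "dominance.tsv"))
    results$diversity <- profiles
    results$diversity_comparisons <- comparisons
    results$dominance <- dom
    manifest$diversity_rows <- nrow(profiles)
  }

  if ("differential" %in% steps) {
    diff_otu <- differential_analysis(table, metadata, contrast[1], contrast[2],
                                      config = config,
                                      seed = stage_seed(seed, "differential"))
    readr::write_tsv(tidy(diff_otu), file.path(out_dir, "diff_otu.tsv"))
    results$diff_otu <- diff_otu
    manifest$diff_otu_tested <- nrow(diff_otu)
    manifest$diff_otu_significant <- sum(diff_otu$significant)
    if (has_taxonomy(table)) {
      genus_tab <- aggregate_taxa(table, "genus")
      cfg_g <- config
      cfg_g$level <- "genus"
      diff_genus <- differential_analysis(genus_tab, metadata, contrast[1],
                                          contrast[2], config = cfg_g,
                                          seed = stage_seed(seed, "differential"))
      readr::write_tsv(tidy(diff_genus), file.path(out_dir, "diff_genus.tsv"))
      results$diff_genus <- diff_genus
      manifest$diff_genus_significant <- sum(diff_genus$significant)
    }
  }

  if ("overlap" %in% steps) {
    healthy <- metadata$sample_id[metadata$group %in% c("HO", "HT")]
    if (length(healthy) >= 2) {
      records <- pairwise_overlap(table, metadata, samples = healthy)
      readr::write_tsv(records, file.path(out_dir, "overlap_pairs.tsv"))
      osum <- overlap_summary(records)
      readr::write_tsv(osum$by_category, file.path(out_dir, "overlap_summary.tsv"))
      if (!is.null(osum$tests))
        readr::write_tsv(osum$tests, file.path(out_dir, "overlap_tests.tsv"))
      results$overlap <- records
      results$overlap_summary <- osum
      manifest$overlap_pairs <- nrow(records)
    }
  }

  if ("network" %in% steps) {
    sig <- results$diff_otu$feature_id[results$diff_otu$significant]
    if (length(sig) >= 2) {
      dirs <- tibble(feature_id = results$diff_otu$feature_id,
                     direction = results$diff_otu$direction)
      net <- cooccurrence_network(table, sig, r_min = r_min, alpha = alpha,
                                  seed = stage_seed(seed, "network"),
                                  directions = dirs)
      readr::write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
      readr::write_tsv(net$nodes, file.path(out_dir, "network_nodes.tsv"))
      results$network <- net
      manifest$network_nodes <- nrow(net$nodes)
      manifest$network_edges <- nrow(net$edges)
    } else {
      warn("Fewer than 2 significant features; skipping the network stage.")
    }
  }

  if ("subtype" %in% steps && has_taxonomy(table)) {
    nrct <- metadata$sample_id[metadata$group == "NRCT" & !is.na(metadata$lesion)]
    if (length(nrct) >= 2) {
      genus_tab <- aggregate_taxa(table, "genus")
      assignment <- hierarchical_subtypes(genus_tab, samples = nrct)
      lesions <- parse_lesion(metadata$lesion[match(nrct, metadata$sample_id)])
      labels <- tibble(sample_id = nrct, label = lesions$label)
      conc <- concordance(assignment, labels,
                          seed = stage_seed(seed, "subtype"))
      readr::write_tsv(tidy(conc), file.path(out_dir, "subtype.tsv"))
      readr::write_tsv(glance(conc), file.path(out_dir, "subtype_summary.tsv"))
      results$subtype <- conc
      manifest$subtype_accuracy <- conc$accuracy
    }
  }

  man <- tibble(key = names(manifest),
                value = vapply(manifest, function(v) format(v, digits = 10),
                               character(1)))
  readr::write_tsv(man, file.path(out_dir, "manifest.tsv"))
  results$manifest <- man
  invisible(results)
}
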