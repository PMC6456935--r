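#' Default design for a synthetic root-apex cohort
#'
#' Returns the design object encoding the cohort structure the simulator
#' emulates: 50 samples in four groups (9 healthy-oral HO, 10 healthy-tooth
#' HT, 23 untreated diseased NRCT, 8 failed-root-canal RCT), per-sample
#' library sizes uniform on 29,604-68,088 reads, a 5,000-OTU pool with
#' log-normal rank-abundance whose group-specific sigma makes diseased
#' communities more dominated, and three disjoint planted effect sets:
#' `n_down` OTUs abundant in healthy samples and suppressed in disease,
#' `n_up` OTUs near-absent in healthy teeth and elevated in NRCT, and
#' `n_subtype` OTUs elevated only in NRCT subtype B. NRCT samples split
#' into subtypes A (9, large-lesion-leaning) and B (14, small-lesion-
#' leaning), with lesion dimension strings drawn to agree with subtype up
#' to `lesion_mislabel_rate`. HO/HT samples from the same subject share a
#' per-subject profile effect.
#'
#' @param ... Named overrides for any design field.
#' @return A list of class `cohort_design`.
#' @examples
#' d <- default_design()
#' sum(d$group_sizes)  # 50
#' @export
default_design <- function(...) {
  design <- list(
    group_sizes = c(HO = 9L, HT = 10L, NRCT = 23L, RCT = 8L),
    depth_range = c(29604L, 68088L),
    n_features = 5000L,
    lognormal_sigma_by_group = c(HO = 2.00, HT = 2.12, NRCT = 2.70, RCT = 2.85),
    overdispersion = 300,
    n_down = 49L,
    n_up = 40L,
    n_subtype = 51L,
    down_effect = 25,
    down_residual = 0.02,
    up_effect = 40,
    up_background = 0.05,
    subtype_effect = 25,
    subtype_split = c(A = 9L, B = 14L),
    lesion_mislabel_rate = 4 / 23,
    paired_subject_effect = 0.6,
    subject_noise_sd = 0.75,
    planted_band = c(0.70, 0.97),
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(design))
  if (length(bad) > 0) abort(paste0("Unknown design field(s): ", toString(bad)))
  design[names(dots)] <- dots
  structure(design, class = "cohort_design")
}

validate_design <- function(design) {
  d <- design
  stopifnot(inherits(d, "cohort_design"))
  if (!setequal(names(d$group_sizes), GROUP_LEVELS) || any(d$group_sizes <= 0))
    abort("`group_sizes` must be positive counts named HO, HT, NRCT, RCT.")
  if (length(d$depth_range) != 2 || d$depth_range[1] > d$depth_range[2] || d$depth_range[1] <= 0)
    abort("`depth_range` must be a positive increasing pair.")
  if (d$n_features <= 0) abort("`n_features` must be positive.")
  if (d$n_down < 0 || d$n_up < 0 || d$n_subtype < 0)
    abort("Planted set sizes must be non-negative.")
  if (d$n_down + d$n_up + d$n_subtype > d$n_features)
    abort("Planted sets exceed the feature pool.")
  if (!setequal(names(d$subtype_split), c("A", "B")) ||
      sum(d$subtype_split) != d$group_sizes[["NRCT"]])
    abort("`subtype_split` must be counts named A, B summing to the NRCT group size.")
  if (d$lesion_mislabel_rate < 0 || d$lesion_mislabel_rate > 1)
    abort("`lesion_mislabel_rate` must be in [0, 1].")
  if (!(is.infinite(d$overdispersion) || d$overdispersion > 0))
    abort("`overdispersion` must be positive (Inf allowed).")
  if (d$paired_subject_effect < 0 || d$paired_subject_effect > 1)
    abort("`paired_subject_effect` must be a correlation in [0, 1].")
  invisible(d)
}

# Simple oral-flora-flavoured taxonomy pool for simulated OTUs. Planted
# features each get a private genus so that planted structure survives
# genus-level aggregation, as the key taxa in real cohorts are distinct
# genera.
simulate_taxonomy <- function(feature_names, planted_ids) {
  n <- length(feature_names)
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Actinobacteria",
             "Fusobacteria", "Spirochaetes", "Synergistetes", "TM7",
             "Tenericutes", "Acidobacteria", "Cyanobacteria", "Chloroflexi")
  n_bg_genera <- 200L
  genus_phylum <- sample(phyla, n_bg_genera, replace = TRUE,
                         prob = c(8, 7, 6, 4, 3, 2, 2, 1, 1, 1, 1, 1))
  bg_genera <- sprintf("Genus%03d", seq_len(n_bg_genera))
  genus_of <- sample(seq_len(n_bg_genera), n, replace = TRUE,
                     prob = 1 / seq_len(n_bg_genera))
  genus <- bg_genera[genus_of]
  phylum <- genus_phylum[genus_of]
  if (length(planted_ids) > 0) {
    idx <- match(planted_ids, feature_names)
    genus[idx] <- sprintf("KeyGenus%03d", seq_along(idx))
    phylum[idx] <- sample(phyla[1:6], length(idx), replace = TRUE)
  }
  tibble(
    feature_id = feature_names,
    kingdom = "Bacteria",
    phylum = phylum,
    class = paste0(phylum, "_c"),
    order = paste0(phylum, "_o"),
    family = paste0(genus, "_f"),
    genus = genus,
    species = NA_character_
  )
}

lesion_string <- function(label) {
  # mixed "x"/"×" delimiters and optional space before "mm", as seen in
  # clinical tables
  if (label == "LSA") {
    a <- sample(5:8, 1)
    b <- sample(2:7, 1)
  } else {
    a <- sample(2:4, 1)
    b <- sample(2:4, 1)
  }
  dims <- sample(c(a, b))
  sep <- sample(c("×", "x"), 1)
  mm <- sample(c(" mm", "mm"), 1)
  paste0(dims[1], sep, dims[2], mm)
}

#' Simulate a synthetic 16S cohort with planted effects
#'
#' Draws an OTU table, sample metadata, and the planted ground truth from
#' the generative model described in `vignette("apexbiome-methods")`:
#' a shared standard-normal score per OTU sets the rank-abundance backbone;
#' each group's expected profile is `exp(sigma_g * z)` (larger sigma =
#' stronger dominance) times multiplicative planted effects; each sample
#' perturbs its group profile by a Dirichlet draw (plus a shared per-subject
#' effect for paired HO/HT samples) and is sequenced multinomially at a
#' depth uniform on the design's depth range.
#'
#' @param design A [default_design()] object (possibly with overrides).
#' @param seed Integer seed; defaults to the design's seed. The same seed
#'   reproduces the cohort exactly.
#' @return A list with elements `table` (an [otu_table()] with simulated
#'   taxonomy), `metadata` (tibble: sample_id, group, subject_id, lesion,
#'   subtype), and `truth` (list: `down_ids`, `up_ids`, `subtype_ids`,
#'   `subtype_assignment`, `lesion_labels`).
#' @examples
#' cohort <- simulate_cohort(default_design(n_features = 300), seed = 7)
#' cohort$table
#' @export
simulate_cohort <- function(design = default_design(), seed = design$seed) {
  validate_design(design)
  d <- design
  withr::with_seed(as.integer(seed), {
    n <- d$n_features
    feature_names <- sprintf("OTU%05d", seq_len(n))
    z <- stats::rnorm(n)

    # planted features come from the mid-to-high abundance band: the
    # multi-criterion selection rule is designed to discard low-abundance
    # candidates, so detectable planted effects must sit above it
    band <- stats::quantile(z, d$planted_band)
    eligible <- which(z >= band[1] & z <= band[2])
    n_planted <- d$n_down + d$n_up + d$n_subtype
    if (length(eligible) < n_planted)
      abort("Planted band too narrow for the requested planted sets.")
    planted <- sample(eligible, n_planted)
    down_idx <- planted[seq_len(d$n_down)]
    up_idx <- planted[d$n_down + seq_len(d$n_up)]
    sub_idx <- planted[d$n_down + d$n_up + seq_len(d$n_subtype)]

    taxonomy <- simulate_taxonomy(feature_names, feature_names[planted])

    # group-level expected profiles (before per-sample noise)
    profile_for <- function(group, subtype = NA) {
      w <- exp(d$lognormal_sigma_by_group[[group]] * z)
      if (group %in% c("HO", "HT")) {
        w[down_idx] <- w[down_idx] * d$down_effect
        w[up_idx] <- w[up_idx] * d$up_background
      } else {
        w[down_idx] <- w[down_idx] * d$down_residual
        w[up_idx] <- w[up_idx] * if (group == "NRCT") d$up_effect else d$up_background
      }
      if (identical(subtype, "B")) w[sub_idx] <- w[sub_idx] * d$subtype_effect
      w / sum(w)
    }

    # sample sheet with subject pairing: HO subjects each also contribute
    # one HT tooth; one subject contributes a second HT tooth
    n_ho <- d$group_sizes[["HO"]]; n_ht <- d$group_sizes[["HT"]]
    n_pair <- min(n_ho, n_ht)
    ho_subj <- sprintf("P%02d", seq_len(n_ho))
    ht_subj <- c(sprintf("P%02d", seq_len(n_pair)),
                 if (n_ht > n_pair) sprintf("P%02d", rep(seq_len(n_pair), length.out = n_ht - n_pair)))
    meta <- dplyr::bind_rows(
      tibble(sample_id = sprintf("O_H_%02d", seq_len(n_ho)), group = "HO", subject_id = ho_subj),
      tibble(sample_id = sprintf("T_H_%02d", seq_len(n_ht)), group = "HT", subject_id = ht_subj),
      tibble(sample_id = sprintf("T_D_None_%02d", seq_len(d$group_sizes[["NRCT"]])),
             group = "NRCT", subject_id = sprintf("N%02d", seq_len(d$group_sizes[["NRCT"]]))),
      tibble(sample_id = sprintf("T_D_RCT_%02d", seq_len(d$group_sizes[["RCT"]])),
             group = "RCT", subject_id = sprintf("R%02d", seq_len(d$group_sizes[["RCT"]])))
    )

    # NRCT subtype assignment and lesion labels
    nrct_ids <- meta$sample_id[meta$group == "NRCT"]
    subtype <- sample(rep(c("A", "B"), times = d$subtype_split))
    names(subtype) <- nrct_ids
    true_label <- ifelse(subtype == "A", "LSA", "SSA")
    n_flip <- round(d$lesion_mislabel_rate * length(true_label))
    if (n_flip > 0) {
      flip <- sample(seq_along(true_label), n_flip)
      true_label[flip] <- ifelse(true_label[flip] == "LSA", "SSA", "LSA")
    }
    meta$subtype <- NA_character_
    meta$subtype[match(nrct_ids, meta$sample_id)] <- subtype
    meta$lesion <- NA_character_
    meta$lesion[match(nrct_ids, meta$sample_id)] <-
      vapply(true_label, lesion_string, character(1))
    rct_ids <- meta$sample_id[meta$group == "RCT"]
    meta$lesion[match(rct_ids, meta$sample_id)] <-
      vapply(sample(c("LSA", "SSA"), length(rct_ids), replace = TRUE),
             lesion_string, character(1))

    # healthy samples carry a log-normal per-sample perturbation split into
    # a component shared within subject and an independent remainder, so
    # `paired_subject_effect` sets the within-subject profile correlation
    # without changing each sample's total variability
    rho <- d$paired_subject_effect
    healthy_subjects <- unique(c(ho_subj, ht_subj))
    subj_eff <- matrix(stats::rnorm(n * length(healthy_subjects)),
                       nrow = n, ncol = length(healthy_subjects),
                       dimnames = list(NULL, healthy_subjects))

    counts <- matrix(0L, nrow = n, ncol = nrow(meta),
                     dimnames = list(feature_names, meta$sample_id))
    depths <- sample(seq(d$depth_range[1], d$depth_range[2]), nrow(meta), replace = TRUE)
    for (j in seq_len(nrow(meta))) {
      g <- meta$group[j]
      p <- profile_for(g, subtype = meta$subtype[j])
      if (g %in% c("HO", "HT")) {
        e <- d$subject_noise_sd *
          (rho * subj_eff[, meta$subject_id[j]] +
             sqrt(1 - rho^2) * stats::rnorm(n))
        p <- p * exp(e)
        p <- p / sum(p)
      }
      if (is.finite(d$overdispersion)) {
        gam <- stats::rgamma(n, shape = d$overdispersion * p)
        tot <- sum(gam)
        p <- if (tot > 0) gam / tot else p
      }
      counts[, j] <- stats::rmultinom(1, size = depths[j], prob = p)[, 1]
    }

    truth <- list(
      down_ids = feature_names[down_idx],
      up_ids = feature_names[up_idx],
      subtype_ids = feature_names[sub_idx],
      subtype_assignment = tibble(sample_id = nrct_ids, subtype = unname(subtype)),
      lesion_labels = tibble(sample_id = nrct_ids, label = unname(true_label))
    )
    list(table = otu_table(counts, taxonomy), metadata = validate_metadata(meta), truth = truth)
  })
}
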