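overlap_fixture <- function() {
  counts <- matrix(
    c(10L, 40L, 50L, 0L,
      0L, 30L, 30L, 40L),
    nrow = 4,
    dimnames = list(c("a", "b", "c", "d"), c("X", "Y"))
  )
  meta <- tibble::tibble(sample_id = c("X", "Y"), group = c("HO", "HT"),
                         subject_id = c("p1", "p2"))
  list(table = otu_table(counts), meta = meta)
}

test_that("worked example decomposes richness and abundance correctly", {
  fx <- overlap_fixture()
  rec <- pairwise_overlap(fx$table, fx$meta)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$com_richness, 2 / 4)
  expect_equal(rec$com_abundance, (40 + 50 + 30 + 30) / 200)
  expect_equal(rec$x_uni_abundance, 10 / 200)
  expect_equal(rec$y_uni_abundance, 40 / 200)
  expect_equal(rec$category, "O2T")
})

test_that("identical and disjoint samples give extreme overlaps", {
  same <- otu_table(matrix(c(3L, 5L, 3L, 5L), 2, 2,
                           dimnames = list(c("a", "b"), c("S1", "S2"))))
  meta <- tibble::tibble(sample_id = c("S1", "S2"), group = c("HO", "HO"),
                         subject_id = c("p", "q"))
  rec <- pairwise_overlap(same, meta)
  expect_equal(rec$com_richness, 1)
  expect_equal(rec$com_abundance, 1)
  expect_equal(rec$x_uni_richness + rec$y_uni_richness, 0)
  expect_equal(rec$category, "O2O")

  disj <- otu_table(matrix(c(3L, 0L, 0L, 5L), 2, 2,
                           dimnames = list(c("a", "b"), c("S1", "S2"))))
  rec2 <- pairwise_overlap(disj, meta)
  expect_equal(rec2$com_richness, 0)
  expect_equal(rec2$com_abundance, 0)
})

test_that("decompositions sum to one and match the Jaccard index", {
  tab <- random_table(n_feat = 40, n_samp = 8, seed = 12, lambda = 2)
  meta <- tibble::tibble(sample_id = sample_ids(tab),
                         group = rep(c("HO", "HT"), 4),
                         subject_id = sample_ids(tab))
  rec <- pairwise_overlap(tab, meta)
  expect_equal(nrow(rec), choose(8, 2))
  expect_equal(rec$com_richness + rec$x_uni_richness + rec$y_uni_richness,
               rep(1, nrow(rec)), tolerance = 1e-12)
  expect_equal(rec$com_abundance + rec$x_uni_abundance + rec$y_uni_abundance,
               rep(1, nrow(rec)), tolerance = 1e-12)
  # com_richness is the Jaccard index of the presence sets
  jac <- function(x, y) {
    px <- tab$counts[, x] > 0; py <- tab$counts[, y] > 0
    sum(px & py) / sum(px | py)
  }
  expect_equal(rec$com_richness,
               mapply(jac, rec$sample_x, rec$sample_y, USE.NAMES = FALSE))
  # min-relative mode still partitions
  rec2 <- pairwise_overlap(tab, meta, abundance_mode = "min_relative")
  expect_equal(rec2$com_abundance + rec2$x_uni_abundance + rec2$y_uni_abundance,
               rep(1, nrow(rec2)), tolerance = 1e-12)
})

test_that("restricting to the paired subjects yields the expected pair counts", {
  co <- small_cohort(seed = 6)
  meta <- co$metadata
  paired_subj <- intersect(meta$subject_id[meta$group == "HO"],
                           meta$subject_id[meta$group == "HT"])[1:8]
  keep <- meta$sample_id[meta$subject_id %in% paired_subj &
                           meta$group %in% c("HO", "HT")]
  keep <- setdiff(keep, meta$sample_id[duplicated(paste(meta$subject_id, meta$group))])
  rec <- pairwise_overlap(co$table, meta, samples = keep)
  expect_equal(sum(rec$category == "O2T"), 8 * 8)
  expect_equal(sum(rec$category == "O2O"), choose(8, 2))
  expect_equal(sum(rec$category == "T2T"), choose(8, 2))
})

test_that("overlap summary reports categories and rank-sum contrasts", {
  co <- small_cohort(seed = 6)
  healthy <- co$metadata$sample_id[co$metadata$group %in% c("HO", "HT")]
  rec <- pairwise_overlap(co$table, co$metadata, samples = healthy)
  os <- overlap_summary(rec)
  expect_setequal(unique(os$by_category$category), c("O2O", "T2T", "O2T"))
  expect_equal(nrow(os$tests), choose(3, 2) * 2)
  expect_true(all(os$tests$p_value > 0 & os$tests$p_value <= 1))
})

test_that("stronger subject pairing raises oral-tooth overlap", {
  med <- function(eff) {
    vals <- purrr::map_dbl(1:3, function(s) {
      co <- simulate_cohort(default_design(paired_subject_effect = eff), seed = s)
      healthy <- co$metadata$sample_id[co$metadata$group %in% c("HO", "HT")]
      rec <- pairwise_overlap(co$table, co$metadata, samples = healthy)
      stats::median(rec$com_richness[rec$category == "O2T"])
    })
    mean(vals)
  }
  expect_gt(med(0.9), med(0))
})
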