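test_that("constructor validates counts and ids", {
  m <- matrix(c(1L, 2L, 3L, 4L), 2, 2)
  expect_s3_class(otu_table(m), "otu_table")
  expect_error(otu_table(matrix(c(-3, 1, 2, 0), 2, 2)), "non-negative")
  expect_error(otu_table(matrix(c(1.5, 1, 2, 0), 2, 2)), "integers")
  bad <- matrix(1:4, 2, 2, dimnames = list(c("A", "A"), c("S1", "S2")))
  expect_error(otu_table(bad), "Duplicate feature")
})

test_that("write/read round-trips tables exactly, with and without taxonomy", {
  tab <- tiny_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, path)
  back <- read_otu_table(path)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$taxonomy, tab$taxonomy)

  bare <- random_table(seed = 42)
  write_otu_table(bare, path)
  back2 <- read_otu_table(path)
  expect_identical(back2$counts, bare$counts)
  # no taxonomy -> taxonomy column omitted
  expect_false(grepl("taxonomy", readLines(path, n = 1)))

  # random round-trip property
  for (s in 1:5) {
    t0 <- random_table(n_feat = 11, n_samp = 4, seed = s)
    write_otu_table(t0, path)
    expect_identical(read_otu_table(path)$counts, t0$counts)
  }
})

test_that("reader handles the classic dialect and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# Constructed from biom file",
    "#OTU ID\tS1\tS2\ttaxonomy",
    "OTU1\t3\t0\tk__Bacteria; p__Firmicutes",
    "OTU2\t1\t2\tk__Bacteria"
  ), path)
  tab <- read_otu_table(path)
  expect_equal(sample_ids(tab), c("S1", "S2"))
  expect_equal(tab$taxonomy$phylum, c("Firmicutes", NA))
  expect_equal(unname(tab$counts["OTU1", "S1"]), 3L)

  writeLines(c("#OTU ID\tS1\tS2", "OTU1\t-3\t1"), path)
  expect_error(read_otu_table(path), "non-negative integers")
  writeLines(c("#OTU ID\tS1\tS2", "OTU1\t1"), path)
  expect_error(read_otu_table(path), "expected 3 fields")
  writeLines(c("#OTU ID\tS1", "OTU1\t1", "OTU1\t2"), path)
  expect_error(read_otu_table(path), "Duplicate")
})

test_that("zero-feature table round-trips to an empty table", {
  empty <- otu_table(matrix(integer(0), 0, 2,
                            dimnames = list(NULL, c("S1", "S2"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(empty, path)
  expect_equal(n_features(read_otu_table(path)), 0)
})

test_that("taxonomic aggregation sums lineage groups and conserves depth", {
  tab <- tiny_table()
  gen <- aggregate_taxa(tab, "genus")
  # OTU1 + OTU2 share the Streptococcus lineage
  strep <- gen$counts[gen$taxonomy$feature_id[which(gen$taxonomy$genus == "Streptococcus")], ]
  expect_equal(unname(strep), unname(tab$counts["OTU1", ] + tab$counts["OTU2", ]))
  # OTU4 has no genus -> pooled into the unassigned bucket
  expect_true("unassigned" %in% feature_ids(gen))
  expect_equal(unname(gen$counts["unassigned", ]), unname(tab$counts["OTU4", ]))
  # depth conservation at every level
  for (lv in c("phylum", "class", "order", "family", "genus")) {
    agg <- aggregate_taxa(tab, lv)
    expect_equal(colSums(agg$counts), colSums(tab$counts))
  }
})

test_that("aggregation keys on the full lineage, not the bare name", {
  counts <- matrix(c(2L, 3L), 2, 1, dimnames = list(c("A", "B"), "S1"))
  tax <- tibble::tibble(
    feature_id = c("A", "B"), kingdom = "Bacteria",
    phylum = c("P1", "P2"), class = c("C1", "C2"), order = c("O1", "O2"),
    family = c("F1", "F2"), genus = c("SameName", "SameName"),
    species = NA_character_
  )
  agg <- aggregate_taxa(otu_table(counts, tax), "genus")
  expect_equal(n_features(agg), 2)  # homonymous genera stay apart
})

test_that("rarefaction hits the target depth exactly and is reproducible", {
  tab <- random_table(n_feat = 30, n_samp = 5, seed = 3, lambda = 50)
  rar <- rarefy(tab, depth = 100, seed = 7)
  expect_true(all(colSums(rar$counts) == 100))
  rar2 <- rarefy(tab, depth = 100, seed = 7)
  expect_identical(rar$counts, rar2$counts)
  # depth equal to a sample's total leaves it unchanged
  d <- min(sample_depths(tab))
  rar3 <- rarefy(tab, depth = d, seed = 1)
  low <- names(which(sample_depths(tab) == d))
  expect_equal(rar3$counts[, low], tab$counts[, low])
  expect_error(rarefy(tab, depth = 0, seed = 1), "positive")
  expect_warning(rarefy(tab, depth = max(sample_depths(tab)), seed = 1), "Dropping")
})

test_that("rarefaction matches the hypergeometric expectation", {
  # community [2, 3], depth 3: feature 1 count ~ Hypergeometric(5; 2; 3)
  tab <- otu_table(matrix(c(2L, 3L), 2, 1, dimnames = list(c("A", "B"), "S1")))
  draws <- vapply(1:1000, function(s) rarefy(tab, depth = 3, seed = s)$counts["A", 1],
                  integer(1))
  m <- 3 * 2 / 5
  v <- 3 * (2 / 5) * (3 / 5) * (5 - 3) / (5 - 1)
  expect_lt(abs(mean(draws) - m), 3 * sqrt(v / 1000))
  # support respected
  expect_true(all(draws %in% 0:2))
})

test_that("relative abundance normalises columns to one", {
  tab <- tiny_table()
  rel <- relative_abundance(tab)
  expect_equal(unname(colSums(rel)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(rel[, "S1"]), c(5, 1, 0, 7) / 13)
  # scaling a sample's counts leaves fractions unchanged
  scaled <- tab$counts
  scaled[, 1] <- scaled[, 1] * 10L
  expect_equal(relative_abundance(otu_table(scaled))[, 1], rel[, 1])
})

test_that("prevalence filter applies the ceiling threshold and is idempotent", {
  withr::with_seed(9, {
    counts <- matrix(0L, 3, 50,
                     dimnames = list(c("rare", "edge", "common"),
                                     sprintf("S%02d", 1:50)))
    counts["rare", sample(50, 4)] <- 1L
    counts["edge", sample(50, 5)] <- 1L
    counts["common", ] <- 2L
    tab <- suppressWarnings(otu_table(counts))
  })
  filt <- suppressWarnings(prevalence_filter(tab, 0.10))
  expect_setequal(feature_ids(filt), c("edge", "common"))
  twice <- suppressWarnings(prevalence_filter(filt, 0.10))
  expect_identical(twice$counts, filt$counts)
  # epsilon threshold keeps anything present at least once
  all_kept <- suppressWarnings(prevalence_filter(tab, 1e-9))
  expect_equal(n_features(all_kept), 3)
})

test_that("metadata validation enforces groups and uniqueness", {
  meta <- tibble::tibble(sample_id = c("a", "b"), group = c("HO", "XX"),
                         subject_id = c("s1", "s2"))
  expect_error(validate_metadata(meta), "Unknown group")
  meta$group <- c("HO", "HT")
  expect_s3_class(validate_metadata(meta), "tbl_df")
  expect_error(validate_metadata(meta[c(1, 1), ]), "Duplicate")
})
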