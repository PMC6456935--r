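test_that("rank-sum test matches enumeration oracles at small n", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 4, 6), c(6, 4, 2))$p_value, 1)

  withr::with_seed(21, {
    for (i in 1:25) {
      nx <- sample(2:5, 1); ny <- sample(2:5, 1)
      v <- sample(100, nx + ny)  # distinct values, no ties
      x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
      expect_equal(wilcoxon_rank_sum(x, y)$p_value, rank_sum_oracle(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("signed-rank test matches enumeration oracles", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value, 2 / 32)
  expect_equal(wilcoxon_signed_rank(c(-2, -1, 1, 2))$p_value, 1)
  expect_warning(res <- wilcoxon_signed_rank(c(0, 0)), "zero")
  expect_equal(res$p_value, 1)

  withr::with_seed(33, {
    for (i in 1:20) {
      n <- sample(3:8, 1)
      d <- sample(100, n) * sample(c(-1, 1), n, replace = TRUE)
      expect_equal(wilcoxon_signed_rank(d)$p_value, signed_rank_oracle(d),
                   tolerance = 1e-12)
      # sign flip invariance
      expect_equal(wilcoxon_signed_rank(-d)$p_value, wilcoxon_signed_rank(d)$p_value)
    }
  })
})

test_that("normal approximation stays close to the exact rank-sum p", {
  splits <- utils::combn(10, 5)
  worst <- 0
  for (k in seq_len(ncol(splits))) {
    x <- splits[, k]
    y <- setdiff(1:10, x)
    pe <- wilcoxon_rank_sum(x, y, exact = TRUE)$p_value
    pa <- wilcoxon_rank_sum(x, y, exact = FALSE)$p_value
    worst <- max(worst, abs(pe - pa))
  }
  expect_lt(worst, 0.02)
})

test_that("Storey q-values reproduce the hand example and the BH identity", {
  st <- storey_qvalues(c(0.6, 0.7, 0.8, 0.9), lambda = 0.5)
  expect_equal(st$pi0$pi0, 1)

  withr::with_seed(7, {
    p <- c(runif(40)^2, runif(40))
    st1 <- storey_qvalues(p, pi0 = 1)
    expect_equal(st1$q_values, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    st2 <- storey_qvalues(p)
    # q monotone in p
    ord <- order(p)
    expect_true(all(diff(st2$q_values[ord]) >= -1e-12))
    expect_true(all(st2$q_values <= 1 & st2$q_values >= 0))
    expect_true(st2$pi0$pi0 > 0 && st2$pi0$pi0 <= 1)
  })

  expect_equal(length(unique(storey_qvalues(rep(0.2, 5))$q_values)), 1)
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Q3 quantile interpolates between order statistics", {
  expect_equal(q3_quantile(c(0, 0, 0, 100)), 25)
  expect_equal(q3_quantile(rep(0, 6)), 0)
  expect_equal(q3_quantile(rep(3.5, 4)), 3.5)
  expect_error(q3_quantile(numeric(0)), "non-empty")
})

test_that("differential pipeline applies the three-criterion rule", {
  co <- small_cohort(seed = 2)
  res <- differential_analysis(co$table, co$metadata, "NRCT", "HT", seed = 5)
  expect_s3_class(res, "apex_diff")
  # the selection rule is the conjunction of its three criteria
  cfg <- attr(res, "config")
  expect_equal(res$significant,
               res$q_value <= cfg$q_threshold &
                 res$fold_change >= cfg$fc_threshold & res$passes_q3)
  # q monotone in p within the analysis
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  # sorted by q then p
  expect_true(!is.unsorted(res$q_value))
})

test_that("features below the prevalence screen never reach the output", {
  counts <- rbind(
    absent = rep(0L, 12),
    common = rep(5L, 12),
    matrix(rpois(10 * 12, 6), 10, 12,
           dimnames = list(sprintf("f%02d", 1:10), NULL))
  )
  colnames(counts) <- sprintf("S%02d", 1:12)
  counts["absent", 1] <- 1L  # present in 1/12 samples, below the 10% ceiling? 1 >= ceiling(1.2) is FALSE
  meta <- tibble::tibble(sample_id = colnames(counts),
                         group = rep(c("NRCT", "HT"), each = 6),
                         subject_id = colnames(counts))
  res <- differential_analysis(otu_table(counts), meta, "NRCT", "HT", seed = 1)
  expect_false("absent" %in% res$feature_id)
  expect_true("common" %in% res$feature_id)
})

test_that("swapping the contrast flips directions but not the calls", {
  co <- small_cohort(seed = 3)
  r1 <- differential_analysis(co$table, co$metadata, "NRCT", "HT", seed = 5)
  r2 <- differential_analysis(co$table, co$metadata, "HT", "NRCT", seed = 5)
  m <- match(r1$feature_id, r2$feature_id)
  expect_equal(r1$p_value, r2$p_value[m])
  expect_equal(r1$q_value, r2$q_value[m])
  expect_equal(r1$fold_change, r2$fold_change[m])
  expect_equal(r1$significant, r2$significant[m])
  untied <- r1$mean_a != r1$mean_b  # direction is arbitrary at exactly tied means
  flipped <- ifelse(r2$direction[m] == "up_in_a", "up_in_b", "up_in_a")
  expect_equal(r1$direction[untied], flipped[untied])
})

test_that("paired mode runs on subject-matched healthy samples", {
  co <- small_cohort(seed = 4)
  cfg <- diff_config(paired = TRUE)
  res <- suppressWarnings(
    differential_analysis(co$table, co$metadata, "HT", "HO", config = cfg, seed = 5))
  expect_s3_class(res, "apex_diff")
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_error(
    differential_analysis(co$table, co$metadata, "NRCT", "ZZZ", config = cfg, seed = 5),
    "no samples")
})

test_that("tidy and glance summarise a differential result", {
  co <- small_cohort(seed = 2)
  res <- differential_analysis(co$table, co$metadata, "NRCT", "HT", seed = 5)
  td <- tidy(res)
  expect_false(inherits(td, "apex_diff"))
  gl <- glance(res)
  expect_equal(gl$n_tested, nrow(res))
  expect_equal(gl$n_significant, sum(res$significant))
  expect_equal(gl$n_up_in_a + gl$n_up_in_b, gl$n_significant)
})
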