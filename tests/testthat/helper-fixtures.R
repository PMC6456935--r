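# Shared fixtures and independent oracles.

# small deterministic table with taxonomy
tiny_table <- function() {
  counts <- matrix(
    c(5L, 0L, 3L,
      1L, 2L, 0L,
      0L, 4L, 2L,
      7L, 1L, 1L),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("OTU1", "OTU2", "OTU3", "OTU4"), c("S1", "S2", "S3"))
  )
  tax <- tibble::tibble(
    feature_id = c("OTU1", "OTU2", "OTU3", "OTU4"),
    kingdom = "Bacteria",
    phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes", "Firmicutes"),
    class = c("Bacilli", "Bacilli", "Bacteroidia", "Clostridia"),
    order = c("Lactobacillales", "Lactobacillales", "Bacteroidales", "Clostridiales"),
    family = c("Streptococcaceae", "Streptococcaceae", "Prevotellaceae", NA),
    genus = c("Streptococcus", "Streptococcus", "Prevotella", NA),
    species = NA_character_
  )
  otu_table(counts, tax)
}

random_table <- function(n_feat = 20, n_samp = 6, seed = 1, lambda = 8) {
  withr::with_seed(seed, {
    counts <- matrix(stats::rpois(n_feat * n_samp, lambda), n_feat, n_samp,
                     dimnames = list(sprintf("F%03d", seq_len(n_feat)),
                                     sprintf("S%02d", seq_len(n_samp))))
    otu_table(counts)
  })
}

# exact two-sided rank-sum p by enumeration over all rank splits (no ties)
rank_sum_oracle <- function(x, y) {
  n <- length(x) + length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  splits <- utils::combn(n, length(x))
  us <- apply(splits, 2, function(ix) sum(ix) - length(x) * (length(x) + 1) / 2)
  pl <- mean(us <= u_obs)
  pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# exact two-sided signed-rank p by enumeration over all sign patterns
signed_rank_oracle <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  pl <- mean(vs <= v_obs)
  pu <- mean(vs >= v_obs)
  min(1, 2 * min(pl, pu))
}

# brute-force k-core: for each k, prune nodes of degree < k on an adjacency
# matrix until stable; a node's core index is the largest k it survives
k_core_oracle <- function(adj) {
  n <- nrow(adj)
  core <- integer(n)
  for (k in 0:n) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- rowSums(adj[, alive, drop = FALSE]) * alive
      drop <- alive & deg < k
      if (!any(drop)) break
      alive[drop] <- FALSE
    }
    core[alive] <- k
    if (!any(alive)) break
  }
  core
}

small_cohort <- function(seed = 1, ...) {
  simulate_cohort(default_design(n_features = 800, ...), seed = seed)
}
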