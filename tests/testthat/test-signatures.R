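# 10-tumor fixture: gene gH mutated in all 5 of subtype "1", none of "2";
# gene gN mutated at the same rate everywhere.
make_tiny_cohort <- function() {
  ids <- sprintf("t%02d", 1:10)
  M <- matrix(0, 10, 3, dimnames = list(ids, c("gH", "gN", "gZ")))
  M[1:5, "gH"] <- 1
  M[c(1, 2, 6, 7), "gN"] <- 1
  M[10, "gZ"] <- 1
  part <- as_partition(stats::setNames(rep(c("1", "2"), each = 5), ids))
  list(M = M, part = part)
}

test_that("all-vs-none enrichment gives the exact hypergeometric tail", {
  tc <- make_tiny_cohort()
  res <- fisher_gene_test(tc$M, tc$part, "gH", "1")
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(sum(res$table), 10)
  expect_equal(res$odds_direction, "enriched")
  # rate-matched gene is null
  null <- fisher_gene_test(tc$M, tc$part, "gN", "1")
  expect_gt(null$p_value, 0.5)
})

test_that("fisher p-values equal exhaustive fixed-margin enumeration", {
  set.seed(70)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    ids <- sprintf("t%02d", seq_len(n))
    M <- matrix(rbinom(n * 2, 1, 0.4), n, 2,
                dimnames = list(ids, c("g1", "g2")))
    n_in <- sample(2:(n - 2), 1)
    part <- as_partition(stats::setNames(
      sample(rep(c("A", "B"), c(n_in, n - n_in))), ids))
    for (g in colnames(M)) {
      if (sum(M[, g]) == 0) next
      res <- fisher_gene_test(M, part, g, "A")
      a <- sum(M[, g] == 1 & unclass(part)[ids] == "A")
      oracle <- brute_fisher_greater(a, sum(M[, g]), n_in, n)
      expect_equal(res$p_value, oracle, tolerance = 1e-10)
    }
  }
})

test_that("bulk signature p-values match the per-gene exact test", {
  co <- simulate_cohort(sim_config(n_genes = 40, n_tumors = 40,
                                   drivers_per_subtype = 4,
                                   background_rate = 0.05, seed = 8))
  sig <- gene_signature(co$mutations, co$truth_labels, "1",
                        top_n = Inf, p_threshold = 1.01)
  for (g in sig$gene[1:5]) {
    expect_equal(sig$p_value[sig$gene == g],
                 fisher_gene_test(co$mutations, co$truth_labels, g,
                                  "1")$p_value,
                 tolerance = 1e-12)
  }
})

test_that("signatures are sorted, thresholded, truncated and order-invariant", {
  tc <- make_tiny_cohort()
  sig <- gene_signature(tc$M, tc$part, "1")
  expect_equal(sig$gene, "gH")         # only the enriched gene passes 0.05
  expect_true(all(sig$p_value < 0.05))
  top1 <- gene_signature(tc$M, tc$part, "1", top_n = 1, p_threshold = 1.01)
  expect_equal(nrow(top1), 1L)
  expect_equal(top1$gene, "gH")
  # empty signature when nothing is differential
  sig2 <- gene_signature(tc$M, tc$part, "2")
  expect_equal(nrow(sig2), 0L)
  # permuting tumor order changes nothing
  perm <- sample(nrow(tc$M))
  sig3 <- gene_signature(tc$M[perm, , drop = FALSE], tc$part, "1",
                         top_n = Inf, p_threshold = 1.01)
  sig0 <- gene_signature(tc$M, tc$part, "1", top_n = Inf, p_threshold = 1.01)
  expect_equal(sig3$p_value, sig0$p_value)
})

test_that("only membership of the target subtype matters", {
  tc <- make_tiny_cohort()
  relab <- unclass(tc$part)
  relab[relab == "2"] <- sample(c("2", "3"), sum(relab == "2"), replace = TRUE)
  p1 <- gene_signature(tc$M, tc$part, "1", top_n = Inf, p_threshold = 1.01)
  p2 <- gene_signature(tc$M, as_partition(relab), "1",
                       top_n = Inf, p_threshold = 1.01)
  expect_equal(p1$p_value, p2$p_value)
})

test_that("planted drivers are recovered and the null is controlled", {
  co <- simulate_cohort(sim_config(seed = 5))
  sigs <- all_signatures(co$mutations, co$truth_labels)
  for (s in names(sigs)) {
    recall <- mean(co$truth_drivers[[s]] %in% sigs[[s]]$gene)
    expect_gte(recall, 0.9)
  }
  # under shuffled labels the sparse cohort's false-positive fraction
  # never exceeds the nominal level (the exact test is conservative here)
  set.seed(71)
  fr <- replicate(10, {
    perm <- as_partition(stats::setNames(sample(unclass(co$truth_labels)),
                                         names(co$truth_labels)))
    sig <- gene_signature(co$mutations, perm, "1", top_n = Inf,
                          p_threshold = 1.01)
    mean(sig$p_value < 0.05)
  })
  expect_lte(mean(fr), 0.07)
})

test_that("type-I error is near nominal when mutation counts are moderate", {
  set.seed(72)
  n <- 240; g <- 300
  M <- matrix(rbinom(n * g, 1, 0.3), n, g,
              dimnames = list(sprintf("t%03d", 1:n), sprintf("g%03d", 1:g)))
  labs <- stats::setNames(as.character(rep(1:4, each = 60)), rownames(M))
  fr <- replicate(50, {
    perm <- as_partition(stats::setNames(sample(labs), names(labs)))
    sig <- gene_signature(M, perm, "1", top_n = Inf, p_threshold = 1.01)
    mean(sig$p_value < 0.05)
  })
  expect_gte(mean(fr), 0.03)
  expect_lte(mean(fr), 0.07)
})

test_that("BH correction is exposed and shrinks the signature", {
  co <- simulate_cohort(sim_config(n_genes = 60, n_tumors = 60,
                                   drivers_per_subtype = 5, seed = 9))
  raw <- gene_signature(co$mutations, co$truth_labels, "1")
  adj <- gene_signature(co$mutations, co$truth_labels, "1",
                        correction = "BH")
  expect_true(nrow(adj) <= nrow(raw))
  expect_true("p_adjusted" %in% names(adj))
})
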