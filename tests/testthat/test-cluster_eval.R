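test_that("contingency counts shared tumors", {
  wp <- worked_partitions()
  g <- contingency(wp$P, wp$C)
  expect_equal(unname(g$v), matrix(c(2, 1, 0, 1), 2))
  # nested example: P = {a,b},{c} vs C = {a,b,c}
  P <- as_partition(stats::setNames(c("1", "1", "2"), c("a", "b", "c")))
  C <- as_partition(stats::setNames(c("x", "x", "x"), c("a", "b", "c")))
  g2 <- contingency(P, C)
  expect_equal(unname(g2$v), matrix(c(2, 1), 2))
  res <- ppv_sn_acc(g2)
  expect_equal(res$PPV, 2 / 3)
  expect_equal(res$SN, 1)
  expect_equal(res$ACC, sqrt(2 / 3))
  expect_equal(ppv_sn_acc(g2, geometric = FALSE)$ACC, 2 / 3)
})

test_that("identical partitions score perfectly on every metric", {
  set.seed(30)
  P <- random_partition(12, 3)
  relabeled <- as_partition(stats::setNames(
    paste0("cluster_", unclass(P)), names(P)))
  g <- contingency(P, relabeled)
  res <- ppv_sn_acc(g)
  expect_equal(c(res$PPV, res$SN, res$ACC), c(1, 1, 1))
  expect_equal(mmr(P, relabeled, 0.5), 1)
  expect_equal(plus_metrics(P, relabeled, 0.5)$F_plus, 1)
  expect_equal(as.numeric(aumf(P, relabeled)), 2)
})

test_that("neighborhood affinity matches its closed form", {
  expect_equal(na_affinity(c("a", "b"), c("a", "b")), 1)
  expect_equal(na_affinity(c("a", "b", "c", "d"), c("a", "b")), 0.5)
  expect_equal(na_affinity(c("a"), c("b")), 0)
})

test_that("worked matching example reproduces the hand-derived values", {
  wp <- worked_partitions()
  g <- contingency(wp$P, wp$C)
  na_mat <- unname(g$v^2 / outer(g$row_sizes, g$col_sizes))
  expect_equal(na_mat, matrix(c(2 / 3, 1 / 6, 0, 1 / 2), 2), tolerance = 1e-12)
  expect_equal(mmr(wp$P, wp$C, 0.2), 7 / 12)
  # at 0.6 only the (p1, c1) edge (affinity 2/3) survives
  expect_equal(mmr(wp$P, wp$C, 0.6), (2 / 3) / 2)
  # above every affinity no edge qualifies
  expect_equal(mmr(wp$P, wp$C, 0.7), 0)
  pm2 <- plus_metrics(wp$P, wp$C, 0.2)
  expect_equal(pm2$F_plus, 1)
  pm6 <- plus_metrics(wp$P, wp$C, 0.6)
  expect_equal(c(pm6$Np_plus, pm6$Nc_plus), c(1L, 1L))
  expect_equal(pm6$F_plus, 0.5)
})

test_that("matching metrics equal exhaustive enumeration on random instances", {
  set.seed(40)
  for (i in 1:50) {
    n <- sample(6:12, 1)
    P <- random_partition(n, sample(2:5, 1))
    C <- random_partition(n, sample(2:5, 1))
    theta <- sample(c(0, 0.1, 0.25, 0.5, 0.75), 1)
    oracle <- brute_mmr_fplus(P, C, theta)
    expect_equal(mmr(P, C, theta), oracle$mmr, tolerance = 1e-12)
    expect_equal(plus_metrics(P, C, theta)$F_plus, oracle$f_plus,
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to relabeling and non-increasing in theta", {
  set.seed(41)
  P <- random_partition(20, 4)
  C <- random_partition(20, 3)
  C2 <- as_partition(stats::setNames(paste0("z", unclass(C)), names(C)))
  thetas <- seq(0, 1, by = 0.1)
  m1 <- vapply(thetas, function(th) mmr(P, C, th), 0)
  m2 <- vapply(thetas, function(th) mmr(P, C2, th), 0)
  f1 <- vapply(thetas, function(th) plus_metrics(P, C, th)$F_plus, 0)
  expect_equal(m1, m2)
  expect_true(all(diff(m1) <= 1e-12))
  expect_true(all(diff(f1) <= 1e-12))
  # ACC^2 = PPV * SN exactly
  res <- ppv_sn_acc(contingency(P, C))
  expect_equal(res$ACC^2, res$PPV * res$SN, tolerance = 1e-12)
})

test_that("AUMF is stable under grid refinement and bounded in [0, 2]", {
  # one reference cluster vs fully shattered discovered clusters
  P <- as_partition(stats::setNames(rep("1", 6), letters[1:6]))
  C <- as_partition(stats::setNames(as.character(1:6), letters[1:6]))
  coarse <- as.numeric(aumf(P, C))
  fine <- as.numeric(aumf(P, C, seq(0, 1, by = 0.001)))
  # the curve is a step function, so the coarse trapezoid can be off by at
  # most half a grid cell times the jump height at each discontinuity
  curve <- attr(aumf(P, C, seq(0, 1, by = 0.001)), "curve")
  jump <- max(abs(diff(curve$MMR + curve$F_plus)))
  expect_lt(abs(coarse - fine), 0.05 * jump / 2 + 1e-9)
  set.seed(42)
  for (i in 1:10) {
    a <- as.numeric(aumf(random_partition(15, 4), random_partition(15, 3)))
    expect_gte(a, 0)
    expect_lte(a, 2)
  }
})

test_that("silhouette matches the brute-force pairwise loop", {
  # 1D worked case {0,1} vs {10,11}: mean of (9.5/10.5, 8.5/9.5) twice
  X <- matrix(c(0, 1, 10, 11), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  lab <- stats::setNames(c("1", "1", "2", "2"), rownames(X))
  expected <- mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5))
  expect_equal(silhouette_score(X, lab), expected, tolerance = 1e-12)

  set.seed(50)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    X <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(sprintf("t%03d", 1:n), NULL))
    C <- random_partition(n, sample(2:4, 1), ids = rownames(X))
    expect_equal(silhouette_score(X, C),
                 brute_silhouette(X, unclass(C)[rownames(X)]),
                 tolerance = 1e-10)
  }
})

test_that("silhouette agrees with the classical reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(51)
  X <- matrix(rnorm(120), 40, 3, dimnames = list(sprintf("t%02d", 1:40), NULL))
  lab <- sample(1:3, 40, replace = TRUE)
  ours <- silhouette_score(X, stats::setNames(as.character(lab), rownames(X)))
  ref <- mean(cluster::silhouette(lab, stats::dist(X))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("silhouette stays within [-1, 1] and handles no separation", {
  set.seed(52)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    X <- matrix(rnorm(n * 2), n, 2,
                dimnames = list(sprintf("t%03d", 1:n), NULL))
    s <- silhouette_score(X, random_partition(n, sample(2:4, 1),
                                              ids = rownames(X)))
    expect_gte(s, -1)
    expect_lte(s, 1)
  }
  # both clusters are the same two-point cloud: no separation
  X <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1), 4, 2,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  s <- silhouette_score(X, stats::setNames(c("1", "1", "2", "2"),
                                           rownames(X)))
  expect_lte(s, 0)
})

test_that("select_k returns the reference size for a self-reproducing runner", {
  set.seed(60)
  ref <- random_partition(30, 3)
  runner <- function(X, k) {
    if (k == 3) ref else random_partition(30, k, ids = names(ref))
  }
  X <- matrix(rnorm(60), 30, 2, dimnames = list(names(ref), NULL))
  sel <- select_k(X, ref, 2:5, runner = runner)
  expect_equal(sel$best_k, 3L)
  # singleton range returns that k
  sel1 <- select_k(X, ref, 3, runner = runner)
  expect_equal(sel1$best_k, 3L)
  # failing k is skipped with a warning
  runner2 <- function(X, k) if (k == 2) stop("boom") else runner(X, k)
  expect_warning(sel2 <- select_k(X, ref, 2:4, runner = runner2), "failed")
  expect_equal(sel2$best_k, 3L)
})
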