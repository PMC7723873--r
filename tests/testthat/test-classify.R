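test_that("confusion-based metrics reproduce hand-computed examples", {
  counts <- data.frame(class = c("c1", "c2"),
                       TP = c(3, 4), TN = c(4, 3), FP = c(1, 2), FN = c(2, 1))
  m <- multiclass_metrics(counts)
  expect_equal(m$precision, 0.7)
  expect_equal(m$recall, 0.7)
  expect_equal(m$f_measure, 0.7)
  expect_equal(m$accuracy, 0.7)

  # perfect predictions
  truth <- rep(c("a", "b", "c"), each = 4)
  perfect <- multiclass_metrics(confusion_counts(truth, truth))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f_measure = 1))
  # all-wrong predictions degrade to zero by convention
  wrong <- multiclass_metrics(confusion_counts(c("a", "b"), c("b", "a")))
  expect_equal(wrong$precision, 0)
  expect_equal(wrong$f_measure, 0)
})

test_that("confusion rows always sum to the sample count", {
  set.seed(80)
  truth <- sample(letters[1:4], 30, replace = TRUE)
  pred <- sample(letters[1:4], 30, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  expect_true(all(cc$TP + cc$TN + cc$FP + cc$FN == 30))
})

test_that("micro-averaged precision equals recall equals per-sample accuracy", {
  set.seed(81)
  for (i in 1:20) {
    truth <- sample(letters[1:4], 40, replace = TRUE)
    pred <- sample(letters[1:4], 40, replace = TRUE)
    m <- multiclass_metrics(confusion_counts(truth, pred))
    expect_equal(m$precision, m$recall, tolerance = 1e-12)
    expect_equal(m$precision, mean(truth == pred), tolerance = 1e-12)
  }
})

test_that("ROC areas match the rank-sum oracle and the worked example", {
  # 4 samples, class-1 scores (0.9, 0.8, 0.3, 0.1), truth (1,0,1,0)
  scores <- cbind(c1 = c(0.9, 0.8, 0.3, 0.1),
                  c2 = c(0.1, 0.2, 0.7, 0.9))
  truth <- c("c1", "c2", "c1", "c2")
  roc <- roc_auc(scores, truth)
  expect_equal(unname(roc$auc_per_class["c1"]), 0.75)

  # one-hot scores are perfect
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  colnames(onehot) <- c("a", "b", "c")
  roc2 <- roc_auc(onehot, c("a", "b", "c", "a"))
  expect_equal(unname(roc2$auc_per_class), rep(1, 3))
  expect_equal(roc2$auc_micro, 1)
  expect_equal(roc2$auc_macro, 1)

  set.seed(82)
  for (i in 1:15) {
    n <- sample(10:50, 1)
    sc <- cbind(a = runif(n), b = runif(n))
    tr <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(tr)) < 2) next
    roc3 <- roc_auc(sc, tr)
    expect_equal(unname(roc3$auc_per_class["a"]),
                 brute_auc(sc[, "a"], tr == "a"), tolerance = 1e-10)
    expect_equal(unname(roc3$auc_per_class["b"]),
                 brute_auc(sc[, "b"], tr == "b"), tolerance = 1e-10)
  }
})

test_that("per-class areas agree with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  sc <- cbind(a = runif(60), b = runif(60))
  tr <- sample(c("a", "b"), 60, replace = TRUE)
  roc <- roc_auc(sc, tr)
  ref <- as.numeric(pROC::auc(pROC::roc(tr == "a", sc[, "a"], quiet = TRUE,
                                        direction = "<")))
  expect_equal(unname(roc$auc_per_class["a"]), ref, tolerance = 1e-10)
})

test_that("random scores sit at chance level", {
  set.seed(84)
  n <- 2000
  sc <- cbind(a = runif(n), b = runif(n))
  tr <- sample(c("a", "b"), n, replace = TRUE)
  roc <- roc_auc(sc, tr)
  expect_lt(abs(roc$auc_macro - 0.5), 0.03)
  expect_lt(abs(roc$auc_micro - 0.5), 0.03)
})

test_that("metrics are invariant to class-label renaming", {
  set.seed(85)
  truth <- sample(c("a", "b", "c"), 30, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 30, replace = TRUE)
  m1 <- multiclass_metrics(confusion_counts(truth, pred))
  ren <- c(a = "x", b = "y", c = "z")
  m2 <- multiclass_metrics(confusion_counts(ren[truth], ren[pred]))
  expect_equal(m1, m2)
})

test_that("cross-validation is stratified, seeded and errors on tiny classes", {
  co <- simulate_cohort(sim_config(n_genes = 60, n_tumors = 60,
                                   drivers_per_subtype = 5, seed = 12))
  X <- propagate(co$mutations, co$network)$matrix
  cfg <- cv_config(repeats = 1, seed = 3, classifier = "knn")
  r1 <- cross_validate(X, co$truth_labels, cfg)
  r2 <- cross_validate(X, co$truth_labels, cfg)
  expect_equal(r1$per_repeat, r2$per_repeat)
  expect_gte(r1$accuracy, 0.9)   # separable cohort

  tiny <- as_partition(stats::setNames(
    c(rep("big", 55), rep("small", 5)), rownames(X)))
  expect_error(cross_validate(X, tiny, cv_config(folds = 10)),
               "small")
})

test_that("every classifier runs and beats chance on a separable cohort", {
  co <- simulate_cohort(sim_config(n_genes = 60, n_tumors = 60,
                                   drivers_per_subtype = 5, seed = 13))
  X <- propagate(co$mutations, co$network)$matrix
  for (cl in c("svm", "mlp", "knn", "naive_bayes")) {
    r <- cross_validate(X, co$truth_labels,
                        cv_config(repeats = 1, seed = 4, classifier = cl))
    expect_gte(r$auc_macro, 0.8)
  }
})

test_that("a label-determining feature dominates the importance table", {
  set.seed(86)
  n <- 80
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(sprintf("t%03d", 1:n), sprintf("g%02d", 1:10)))
  lab <- rep(c("A", "B"), each = n / 2)
  X[, "g01"] <- ifelse(lab == "A", 1, -1) + rnorm(n, sd = 0.05)
  part <- as_partition(stats::setNames(lab, rownames(X)))
  imp <- feature_importance(X, part, seed = 5)
  expect_equal(imp$gene[1], "g01")
  expect_true(imp$selected[1])
  expect_true(all(imp$importance[imp$gene != "g01"] < imp$importance[1]))
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  # an impossible threshold empties the selection
  imp2 <- feature_importance(X, part, threshold = 1.0, seed = 5)
  expect_false(any(imp2$selected))
})
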