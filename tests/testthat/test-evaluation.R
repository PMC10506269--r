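test_that("top_k_accuracy: closed cases, exclusion rule, brute-force oracle", {
  y <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(top_k_accuracy(matrix(c(0.9, 0.05, 0.05), 1, 3), y, 1), 1.0)
  # k = C always hits any labelled sample
  set.seed(41)
  sc <- rmat(20, 4); yy <- matrix(rbinom(80, 1, 0.4), 20, 4)
  yy[rowSums(yy) == 0, 1] <- 1
  expect_equal(top_k_accuracy(sc, yy, 4), 1.0)
  # anti-correlated scores with a single label miss at k = 1
  y1 <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  s1 <- 1 - y1
  expect_equal(top_k_accuracy(s1, y1, 1), 0.0)

  # unlabeled samples leave the denominator, with a warning
  y2 <- rbind(c(1, 0), c(0, 0))
  s2 <- rbind(c(0.9, 0.1), c(0.9, 0.1))
  expect_warning(acc <- top_k_accuracy(s2, y2, 1), "no true label")
  expect_equal(acc, 1.0)

  for (r in 1:100) {
    n <- sample(5:50, 1)
    sc <- rmat(n, 12)
    yy <- matrix(rbinom(n * 12, 1, 0.25), n, 12)
    if (all(rowSums(yy) == 0)) yy[1, 1] <- 1
    k <- sample(1:12, 1)
    expect_equal(suppressWarnings(top_k_accuracy(sc, yy, k)),
                 oracle_topk(sc, yy, k))
  }
  expect_error(top_k_accuracy(sc, yy, 13), "k must")
})

test_that("roc_auc: tie convention, pairwise oracle, invariances", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.7, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(42)
  for (r in 1:100) {
    n <- sample(6:30, 1)
    sc <- round(rnorm(n), 1)           # induce ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    a <- roc_auc(sc, lb)
    expect_equal(a, oracle_auc(sc, lb), tolerance = 1e-12)
    # monotone transform invariance
    expect_equal(roc_auc(exp(sc), lb), a, tolerance = 1e-12)
  }
  # complement identity in the tie-free case
  sc <- rnorm(25); lb <- rbinom(25, 1, 0.5); lb[1:2] <- c(0, 1)
  expect_equal(roc_auc(sc, lb) + roc_auc(-sc, lb), 1, tolerance = 1e-12)
})

test_that("average_precision: closed forms and enumeration oracle", {
  expect_equal(average_precision(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1.0)
  m <- 8
  sc <- seq(m, 1); lb <- c(rep(0, m - 1), 1)   # single positive ranked last
  expect_equal(average_precision(sc, lb), 1 / m)
  expect_error(average_precision(1:3, c(0, 0, 0)), "without positives")

  set.seed(43)
  for (r in 1:100) {
    n <- sample(5:40, 1)
    sc <- rnorm(n); lb <- rbinom(n, 1, 0.4)
    if (sum(lb) == 0) lb[1] <- 1
    expect_equal(average_precision(sc, lb), oracle_ap(sc, lb), tolerance = 1e-12)
  }
})

test_that("AP equals prevalence in expectation under random scores", {
  set.seed(44)
  n <- 400; prev <- 0.3
  lb <- rbinom(n, 1, prev)
  aps <- replicate(50, average_precision(runif(n), lb))
  expect_lt(abs(mean(aps) - mean(lb)), 0.05)
})

test_that("build_report aggregates per-class metrics with NA flagging", {
  set.seed(45)
  y <- matrix(rbinom(60, 1, 0.4), 20, 3)
  y[rowSums(y) == 0, 2] <- 1
  rep1 <- build_report(y, label_matrix(y, class_names = c("a", "b", "c")))
  expect_equal(unname(rep1$per_class_auc), rep(1, 3))
  expect_equal(rep1$top1_accuracy, 1.0)
  expect_equal(rep1$macro_ap, 1.0)

  # single-class column is flagged, not silently dropped
  y2 <- cbind(y[, 1:2], 0)
  y2[1, 3] <- 0
  sc <- rmat(20, 3)
  rep2 <- build_report(sc, label_matrix(y2))
  expect_true(is.na(rep2$per_class_auc[3]))
  expect_identical(rep2$undefined_classes, "class3")
  expect_false(is.na(rep2$macro_auc))

  # label-shuffled scores: macro AUC near chance
  set.seed(46)
  n <- 2000
  yy <- matrix(rbinom(n * 3, 1, 0.4), n, 3)
  rep3 <- build_report(matrix(runif(n * 3), n, 3), label_matrix(yy))
  expect_lt(abs(rep3$macro_auc - 0.5), 0.05)

  # report round trip is lossless
  d <- file.path(tempdir(), "rep_out")
  write_report(rep1, d)
  rep1b <- read_report(d)
  expect_identical(rep1b$per_class_auc, rep1$per_class_auc)
  expect_identical(rep1b$top1_accuracy, rep1$top1_accuracy)
  expect_true(file.exists(file.path(d, "metrics.tsv")))
  expect_true(file.exists(file.path(d, "roc_a.tsv")))
})

test_that("top-1 is never above top-3 and curve axes are monotone", {
  set.seed(47)
  sc <- rmat(50, 5); y <- matrix(rbinom(250, 1, 0.3), 50, 5)
  y[rowSums(y) == 0, 1] <- 1
  rp <- build_report(sc, label_matrix(y))
  expect_lte(rp$top1_accuracy, rp$top3_accuracy)
  for (cl in rp$class_names) {
    roc <- rp$roc_points[[cl]]
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
    pr <- rp$pr_points[[cl]]
    expect_true(all(diff(pr$recall) >= 0))
  }
})
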