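test_that("LOOCV reaches accuracy 1 when features encode the labels", {
  fs <- make_fset(cbind(c(1, 1, 0, 0)), c("walk", "walk", "idle", "idle"))
  res <- loocv(fs, classifier_spec("knn", k = 1))
  expect_equal(res$accuracy, 1)
  expect_equal(res$n_folds, 4)
  expect_length(res$skipped, 0)
})

test_that("LOOCV runs exactly one fold per trial on an 80-trial subject", {
  set.seed(50)
  X <- rbind(matrix(rnorm(40 * 3, 1), 40, 3), matrix(rnorm(40 * 3, -1), 40, 3))
  fs <- make_fset(X, rep(c("walk", "idle"), each = 40))
  res <- loocv(fs, classifier_spec("lda"))
  expect_equal(res$n_folds, 80)
  expect_true(all(!is.na(res$predictions)))
  expect_equal(sum(res$confusion), 80)
})

test_that("LOOCV fold-by-fold predictions match a hand-enumerated 1-NN run", {
  # six points on a line: walk {0, 1, 8.5}, idle {10, 11, 12}.
  # Nearest other point: 0->1 (walk), 1->0 (walk), 8.5->10 (idle, wrong),
  # 10->11 (idle), 11->10 (idle), 12->11 (idle): accuracy 5/6.
  fs <- make_fset(cbind(c(0, 1, 8.5, 10, 11, 12)),
                  c("walk", "walk", "walk", "idle", "idle", "idle"))
  res <- loocv(fs, classifier_spec("knn", k = 1))
  expect_equal(res$predictions,
               c("walk", "walk", "idle", "idle", "idle", "idle"))
  expect_equal(res$accuracy, 5 / 6)
})

test_that("LOOCV accuracy is invariant to trial ordering", {
  set.seed(51)
  X <- rbind(matrix(rnorm(12 * 4, 1.2), 12, 4),
             matrix(rnorm(12 * 4, -1.2), 12, 4))
  fs <- make_fset(X, rep(c("walk", "idle"), each = 12))
  perm <- sample(24)
  fp <- make_fset(X[perm, ], fs$y[perm])
  for (cl in list(classifier_spec("lda"), classifier_spec("knn"),
                  classifier_spec("cdsrc", sparsity = 4))) {
    expect_equal(loocv(fs, cl)$accuracy, loocv(fp, cl)$accuracy,
                 label = cl$name)
  }
})

test_that("summaries are mean +/- sample sd across subjects", {
  cells <- data.frame(subject = 1:2, classifier = "cdsrc",
                      accuracy = c(0.8, 0.9))
  s <- summarize_accuracy(cells, by = "classifier")
  expect_equal(s$mean_accuracy, 0.85)
  expect_equal(s$sd_accuracy, 0.0707, tolerance = 1e-3)
  cells2 <- data.frame(subject = 1:3, classifier = "knn", accuracy = 0.7)
  expect_equal(summarize_accuracy(cells2, by = "classifier")$sd_accuracy, 0)
  # random grid against a direct split-apply oracle
  set.seed(52)
  grid <- expand.grid(subject = 1:6, classifier = c("a", "b"),
                      features = c("M", "MPR"))
  grid$accuracy <- runif(nrow(grid))
  s <- summarize_accuracy(grid, by = c("classifier", "features"))
  for (i in seq_len(nrow(s))) {
    v <- grid$accuracy[grid$classifier == s$classifier[i] &
                         grid$features == s$features[i]]
    expect_equal(s$mean_accuracy[i], mean(v))
    expect_equal(s$sd_accuracy[i], sd(v))
  }
})

test_that("a uniform +0.1 shift over 15 subjects is detected by Wilcoxon", {
  set.seed(53)
  base <- runif(15, 0.6, 0.9)
  acc <- cbind(cdsrc = base + 0.1, svm = base)
  rep <- compare_classifiers(acc)
  expect_lt(rep$wilcoxon$p[1], 0.05)
  expect_true(rep$wilcoxon$significant[1])
  # exact enumeration oracle on the same differences
  expect_lt(oracle_wilcoxon_exact(acc[, 1] - acc[, 2]), 0.05)
})

test_that("Friedman statistic matches the rank-sum formula on a small matrix", {
  m <- matrix(c(0.9, 0.8, 0.7,
                0.85, 0.75, 0.65,
                0.95, 0.7, 0.6,
                0.8, 0.78, 0.5), 4, 3, byrow = TRUE)
  colnames(m) <- c("cdsrc", "svm", "knn")
  rep <- compare_classifiers(m)
  expect_equal(rep$friedman_stat, oracle_friedman_stat(m), tolerance = 1e-10)
  expect_true(all(rep$normality_p > 0 | is.na(rep$normality_p)))
})

test_that("degenerate comparisons are reported, not errored", {
  m <- matrix(rep(c(0.8, 0.8, 0.7), each = 5), 5, 3)
  colnames(m) <- c("cdsrc", "svm", "knn")
  rep <- compare_classifiers(m)
  expect_true(is.na(rep$wilcoxon$p[rep$wilcoxon$comparison == "cdsrc vs svm"]))
  expect_match(rep$wilcoxon$note[1], "zero")
  # identical columns: Friedman statistic includes a 0-difference pair
  m2 <- matrix(runif(10), 5, 2, dimnames = list(NULL, c("cdsrc", "svm")))
  m2[, 2] <- m2[, 1]
  expect_equal(compare_classifiers(m2)$friedman_stat, 0)
})

test_that("Holm correction flag adjusts pairwise p values", {
  set.seed(54)
  base <- runif(12, 0.5, 0.8)
  acc <- cbind(cdsrc = base + 0.08, svm = base, knn = base - 0.01)
  raw <- compare_classifiers(acc)
  hol <- compare_classifiers(acc, holm = TRUE)
  expect_true(all(hol$wilcoxon$p >= raw$wilcoxon$p - 1e-12))
})
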