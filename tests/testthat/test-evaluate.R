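test_that("the stratified split reproduces the 180/30/90 study layout", {
  labels <- rep(c("normal", "slight", "total"), each = 100)
  sp <- stratified_split(labels, seed = 3)
  expect_length(sp$train, 180L)
  expect_length(sp$val, 30L)
  expect_length(sp$test, 90L)
  expect_length(intersect(sp$train, c(sp$val, sp$test)), 0L)
  expect_setequal(c(sp$train, sp$val, sp$test), seq_along(labels))
  for (lev in unique(labels)) {
    expect_identical(sum(labels[sp$train] == lev), 60L)
    expect_identical(sum(labels[sp$val] == lev), 10L)
    expect_identical(sum(labels[sp$test] == lev), 30L)
  }
  expect_identical(stratified_split(labels, seed = 3), sp)
  expect_error(stratified_split(c("normal", "slight", "total"), 1),
               "too small")
})

test_that("the confusion matrix counts truth by prediction", {
  truth <- rep(c("normal", "slight", "total"), times = c(4, 3, 2))
  cm <- confusion_matrix(truth, truth)
  expect_equal(unname(diag(cm)), c(4, 3, 2))
  expect_identical(sum(cm) - sum(diag(cm)), 0L)
  pred <- c("slight", truth[-1])
  cm2 <- confusion_matrix(truth, pred)
  expect_equal(unname(rowSums(cm2)), c(4, 3, 2))
  expect_equal(sum(diag(cm2)) / sum(cm2), mean(truth == pred),
               tolerance = 1e-12)
  expect_error(confusion_matrix(truth, rep("weird", 9),
                                levels = unique(truth)), "outside")
})

test_that("uniform random predictions put about two thirds off-diagonal", {
  set.seed(8)
  n <- 9000
  truth <- sample(c("normal", "slight", "total"), n, replace = TRUE)
  pred <- sample(c("normal", "slight", "total"), n, replace = TRUE)
  cm <- confusion_matrix(truth, pred)
  off <- 1 - sum(diag(cm)) / n
  expect_lt(abs(off - 2 / 3), 0.02)
})

test_that("run_experiment produces a coherent, reproducible report", {
  tab <- sim_feature_table("laboratory", 10, 21)
  tab <- tab[c("sample_id", "label", "environment",
               grep("_F2$", names(tab), value = TRUE))]
  rep1 <- run_experiment(tab, models = c("svm", "knn"),
                         conditions = c("raw", "discretized"),
                         n_repeats = 2, seed = 77)
  rep2 <- run_experiment(tab, models = c("svm", "knn"),
                         conditions = c("raw", "discretized"),
                         n_repeats = 2, seed = 77)
  expect_identical(rep1$cells, rep2$cells)
  for (key in names(rep1$cells)) {
    cell <- rep1$cells[[key]]
    expect_length(cell$test_acc, 2L)
    expect_gte(cell$mean, min(cell$test_acc))
    expect_lte(cell$mean, max(cell$test_acc))
    expect_equal(unname(rowSums(cell$confusion)), c(3, 3, 3))
  }
  expect_length(rep1$deltas, 2L)
  md <- report_markdown(rep1)
  expect_length(md, 4L)
  expect_match(md[3], "^\\| SVM \\|")
})

test_that("label-shuffled data scores at chance", {
  tab <- sim_feature_table("laboratory", 10, 21)
  set.seed(1)
  tab$label <- sample(tab$label)
  rep <- run_experiment(tab, models = "svm", conditions = "raw",
                        n_repeats = 3, seed = 5)
  expect_lt(abs(rep$cells$svm.raw$mean - 1 / 3), 0.17)
})
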