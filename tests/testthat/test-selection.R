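make_sel_table <- function(n = 90, n_noise = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c("normal", "slight", "total"), each = n / 3)
  sig1 <- as.integer(factor(y)) + rnorm(n, 0, 0.15)
  sig2 <- as.integer(factor(y)) * 2 + rnorm(n, 0, 0.2)
  noise <- lapply(seq_len(n_noise), function(i) rnorm(n))
  names(noise) <- paste0("noise", seq_len(n_noise))
  toy_table(c(list(sig1 = sig1, sig2 = sig2), noise), y)
}

test_that("a label-copy feature scores close to the label entropy", {
  set.seed(2)
  n <- 120
  y <- rep(c("normal", "slight", "total"), each = n / 3)
  tab <- toy_table(list(copy = as.integer(factor(y)),
                        n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n)), y)
  s <- mime_scores(tab, cfg = selection_config())
  expect_equal(unname(s["copy"]), log2(3), tolerance = 0.15)
  expect_gt(s["copy"], max(s[c("n1", "n2", "n3")]))
})

test_that("zero penalty weights reduce the score to plain relevance", {
  tab <- make_sel_table()
  cfg0 <- selection_config(alpha = 0, beta = 0)
  s <- mime_scores(tab, cfg = cfg0)
  y <- tab$label
  direct <- vapply(setdiff(names(tab), c("sample_id", "label", "environment")),
                   function(f) estimate_mi(tab[[f]], y, bins = cfg0$mi_bins), 0)
  expect_equal(s, direct, tolerance = 1e-12)
})

test_that("duplicating an informative feature is penalized as redundancy", {
  tab <- make_sel_table()
  dup <- tab
  dup$sig1_copy <- dup$sig1
  cfg <- selection_config(alpha = 1, beta = 0)
  s_single <- mime_scores(tab, cfg = cfg)
  s_dup <- mime_scores(dup, cfg = cfg)
  # with a duplicate present, sig1's redundancy penalty grows by I(F,F)/m
  m <- length(s_dup) - 1
  expected_drop <- estimate_mi(tab$sig1, tab$sig1) / m
  observed_drop <- s_single["sig1"] - s_dup["sig1"]
  # m changed between configurations, so compare against the dominant term
  expect_gt(observed_drop, 0.5 * expected_drop)
})

test_that("mime scores are permutation-equivariant in feature order", {
  tab <- make_sel_table()
  feats <- setdiff(names(tab), c("sample_id", "label", "environment"))
  perm <- rev(feats)
  tab_perm <- tab[c("sample_id", "label", "environment", perm)]
  s1 <- mime_scores(tab)
  s2 <- mime_scores(tab_perm)
  expect_equal(s2[names(s1)], s1)
})

test_that("filter stage respects thresholds and never empties the set", {
  scores <- stats::setNames(seq_len(144) / 100, paste0("f", 1:144))
  cfg_min <- selection_config(filter_threshold = min(scores),
                              threshold_type = "absolute")
  expect_length(filter_stage(scores, cfg_min), 144L)
  cfg_inf <- selection_config(filter_threshold = Inf,
                              threshold_type = "absolute")
  expect_identical(filter_stage(scores, cfg_inf), "f144")
  cfg_q <- selection_config(filter_threshold = 0.25)
  expect_length(filter_stage(scores, cfg_q), 108L)
})

test_that("the wrapper removes pure-noise features across seeds", {
  tab <- make_sel_table(n = 90, n_noise = 3)
  for (seed in 1:10) {
    res <- rfecv_wrapper(tab, cfg = selection_config(cv_folds = 3,
                                                     seed = seed))
    expect_true(all(c("sig1", "sig2") %in% res$selected) ||
                  res$final_accuracy >= res$initial_accuracy)
    expect_false(all(paste0("noise", 1:3) %in% res$selected))
    expect_lte(length(res$selected), 5L)
    expect_gte(res$final_accuracy, res$initial_accuracy)
  }
})

test_that("identical feature copies collapse to a single survivor", {
  set.seed(4)
  y <- rep(c("normal", "slight", "total"), each = 20)
  base <- as.integer(factor(y)) + rnorm(60, 0, 0.3)
  tab <- toy_table(list(c1 = base, c2 = base, c3 = base, c4 = base), y)
  res <- rfecv_wrapper(tab, cfg = selection_config(cv_folds = 3, seed = 2))
  expect_length(res$selected, 1L)
})

test_that("the wrapper is deterministic and its log reconstructs the set", {
  tab <- make_sel_table()
  cfg <- selection_config(cv_folds = 3, seed = 42)
  r1 <- rfecv_wrapper(tab, cfg = cfg)
  r2 <- rfecv_wrapper(tab, cfg = cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$selected, r2$selected)
  feats <- setdiff(names(tab), c("sample_id", "label", "environment"))
  reconstructed <- setdiff(feats, r1$log$feature[r1$log$removed])
  expect_setequal(reconstructed, r1$selected)
  expect_error(rfecv_wrapper(toy_table(list(a = 1:6, b = 6:1),
                                       rep("normal", 6))),
               "degenerate")
})

test_that("full selection returns a coherent result object", {
  tab <- make_sel_table(n = 90, n_noise = 6)
  res <- select_features(tab, cfg = selection_config(cv_folds = 3, seed = 7))
  expect_s3_class(res, "enose_selection")
  expect_true(all(res$selected %in% res$filtered))
  expect_true(all(res$filtered %in% names(res$mime_scores)))
  expect_lt(length(res$selected), length(res$mime_scores))
})
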