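range_table <- function(ranges, n_per_class = 10, seed = 1) {
  # samples spanning each class's [lo, hi] exactly
  set.seed(seed)
  vals <- unlist(lapply(ranges, function(r)
    c(r[1], r[2], runif(n_per_class - 2, r[1], r[2]))))
  toy_table(list(f = vals),
            rep(names(ranges), each = n_per_class))
}

test_that("disjoint, identical, and partially overlapping class ranges segment as drawn", {
  # three disjoint ranges -> 3 pure + 2 gap segments
  tab <- range_table(list(normal = c(0, 1), slight = c(2, 3), total = c(4, 5)))
  m <- fit_discretizer(tab)
  expect_identical(m$model$f$K, 5L)
  expect_equal(m$model$f$breakpoints, c(1, 2, 3, 4))
  # interior points of the three class regions carry distinct odd tags;
  # gap interiors carry the even tags
  probes <- discretize_transform(
    m, toy_table(list(f = c(0.5, 1.5, 2.5, 3.5, 4.5)), rep("normal", 5)))$f
  expect_identical(probes, 1:5)

  # identical ranges -> one segment
  tab2 <- range_table(list(normal = c(0, 1), slight = c(0, 1),
                           total = c(0, 1)))
  m2 <- fit_discretizer(tab2)
  expect_identical(m2$model$f$K, 1L)
  expect_true(all(discretize_transform(m2, tab2)$f == 1L))

  # partial overlap: [0,2] and [1,3] -> pure A, overlap, pure B
  tab3 <- range_table(list(normal = c(0, 2), slight = c(1, 3)))
  m3 <- fit_discretizer(tab3)
  expect_identical(m3$model$f$K, 3L)
  expect_equal(m3$model$f$breakpoints, c(1, 2))
  tg <- discretize_transform(m3, toy_table(list(f = c(0.5, 1.5, 2.5)),
                                           rep("normal", 3)))$f
  expect_identical(tg, c(1L, 2L, 3L))
})

test_that("transform clips outside the fitted range and respects boundaries", {
  tab <- range_table(list(normal = c(0, 2), slight = c(1, 3)))
  m <- fit_discretizer(tab)
  out <- discretize_transform(m, toy_table(list(f = c(-100, 100, 1, 2)),
                                           rep("slight", 4)))$f
  expect_identical(out[1], 1L)      # far below -> first segment
  expect_identical(out[2], 3L)      # far above -> last segment
  expect_identical(out[3], 2L)      # breakpoint belongs to right segment
  expect_identical(out[4], 3L)
  expect_error(discretize_transform(m, toy_table(list(zz = 1), "slight")),
               "do not match")
})

test_that("tags agree with a linear-scan assigner and are monotone", {
  set.seed(9)
  for (i in 1:100) {
    y <- rep(c("normal", "slight", "total"), each = 8)
    tab <- toy_table(list(f = rnorm(24)), y)
    m <- fit_discretizer(tab)
    v <- sort(rnorm(30, 0, 2))
    tags <- discretize_transform(m, toy_table(list(f = v),
                                              rep("normal", 30)))$f
    oracle <- vapply(v, brute_assign, 1L, m$model$f$breakpoints)
    expect_identical(tags, oracle)
    expect_true(all(diff(tags) >= 0)) # monotone in the value
  }
})

test_that("one-hot encoding is exact and invertible", {
  y <- rep(c("normal", "slight", "total"), each = 5)
  set.seed(2)
  tab <- toy_table(list(a = rnorm(15), b = rnorm(15)), y)
  m <- fit_discretizer(tab)
  tagged <- discretize_transform(m, tab)
  enc <- one_hot_encode(tagged, m)
  feats <- setdiff(names(enc), c("sample_id", "label", "environment"))
  expect_length(feats, m$model$a$K + m$model$b$K)
  em <- as.matrix(enc[feats])
  expect_true(all(rowSums(em) == 2)) # one 1 per original feature
  # argmax decodes the tags
  a_block <- em[, grepl("^a_seg", colnames(em)), drop = FALSE]
  expect_identical(max.col(a_block), as.integer(tagged$a))
  # a fixed tag maps to the expected unit vector
  idx <- which(tagged$a == 2L)[1]
  if (!is.na(idx)) expect_identical(unname(a_block[idx, 2]), 1L)
  expect_error(one_hot_encode(within(tagged, a <- a + 100L), m),
               "out of range")
})

test_that("fitting requires data and class diversity", {
  empty <- data.frame(sample_id = character(0), label = character(0),
                      environment = character(0), f = numeric(0))
  expect_error(fit_discretizer(empty), "empty")
  expect_error(fit_discretizer(toy_table(list(a = 1:4), rep("normal", 4))),
               "2 classes")
})
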