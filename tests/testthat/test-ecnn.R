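small_cfg <- function(epochs = 150, seed = 1)
  train_config(learning_rate = 0.01, epochs = epochs, seed = seed)

test_that("the hyperparameter grids enumerate 144 base and 15 meta groups", {
  grid <- base_cnn_grid()
  expect_length(grid, 144L)
  expect_length(unique(vapply(grid, function(s)
    paste(s$k1, s$c1, s$k2, s$c2), "")), 144L)
  expect_setequal(unique(vapply(grid, `[[`, 0, "k1")), c(3, 5, 7, 9))
  expect_setequal(unique(vapply(grid, `[[`, 0, "c2")), c(32, 64, 128))
  expect_length(meta_cnn_grid(), 15L)
})

test_that("neighbor specs are the nearest grid points around the optimum", {
  opt <- list(k1 = 5, c1 = 64, k2 = 3, c2 = 128)
  ns <- neighbor_specs(opt, 10)
  expect_length(ns, 10L)
  expect_identical(ns[[1L]], opt)
  ids <- vapply(ns, function(s) paste(s$k1, s$c1, s$k2, s$c2), "")
  expect_length(unique(ids), 10L)
  # every returned spec differs from the optimum by at most 2 grid steps
  ax <- list(c(3, 5, 7, 9), c(8, 16, 32, 64), c(3, 5, 7), c(32, 64, 128))
  d <- vapply(ns, function(s) {
    co <- c(match(s$k1, ax[[1]]), match(s$c1, ax[[2]]),
            match(s$k2, ax[[3]]), match(s$c2, ax[[4]]))
    oo <- c(match(opt$k1, ax[[1]]), match(opt$c1, ax[[2]]),
            match(opt$k2, ax[[3]]), match(opt$c2, ax[[4]]))
    sum(abs(co - oo))
  }, 0)
  expect_true(all(d <= 2))
  expect_identical(neighbor_specs(opt, 1), list(opt))
  expect_error(neighbor_specs(list(k1 = 4, c1 = 64, k2 = 3, c2 = 128), 10),
               "does not lie in the grid")
})

test_that("infeasible specs are rejected before training", {
  toy <- toy_separable(n = 30, width = 10)
  expect_error(train_base(list(k1 = 9, c1 = 8, k2 = 3, c2 = 32),
                          toy$x, toy$y, small_cfg()), "infeasible")
  # narrow inputs shrink the feasible neighborhood instead of failing
  ns <- neighbor_specs(list(k1 = 3, c1 = 8, k2 = 3, c2 = 32), 5,
                       input_width = 9)
  for (s in ns) {
    l1 <- (9 - s$k1) %/% 2 + 1
    expect_gte((l1 - s$k2) %/% 2 + 1, 1)
  }
})

test_that("a base network fits a separable toy set and is deterministic", {
  toy <- toy_separable(n = 21, width = 20)
  fit <- train_base(list(k1 = 3, c1 = 16, k2 = 3, c2 = 32), toy$x, toy$y,
                    train_config(epochs = 300, seed = 2))
  expect_equal(mean(predict(fit, toy$x, type = "class") == toy$y), 1)
  probs <- predict(fit, toy$x, type = "prob")
  expect_equal(rowSums(probs), rep(1, nrow(toy$x)), tolerance = 1e-6)
  # bitwise-identical loss trajectory under the same seed
  f1 <- train_base(list(k1 = 3, c1 = 16, k2 = 3, c2 = 32), toy$x, toy$y,
                   small_cfg(epochs = 40, seed = 9))
  f2 <- train_base(list(k1 = 3, c1 = 16, k2 = 3, c2 = 32), toy$x, toy$y,
                   small_cfg(epochs = 40, seed = 9))
  expect_identical(f1$losses, f2$losses)
  expect_error(predict(fit, toy$x[, 1:10]), "width")
})

test_that("an untrained network predicts at chance on balanced data", {
  # features independent of the balanced labels: accuracy must sit at 1/3
  # regardless of what the random-weight network computes
  set.seed(3)
  x <- matrix(rnorm(300 * 20), 300, 20)
  y <- factor(rep(c("a", "b", "c"), 100))
  fit <- train_base(list(k1 = 3, c1 = 16, k2 = 3, c2 = 32), x, y,
                    train_config(epochs = 0, seed = 5))
  acc <- mean(predict(fit, x, type = "class") == y)
  expect_lt(abs(acc - 1 / 3), 0.1)
})

test_that("grid search scores every grid point and breaks ties by size", {
  toy <- toy_separable(n = 45, width = 20, seed = 4)
  idx <- rep(c(TRUE, FALSE), length.out = 45)
  grid <- list(list(k1 = 3, c1 = 32, k2 = 3, c2 = 64),  # larger
               list(k1 = 3, c1 = 8, k2 = 3, c2 = 32))   # smaller
  gs <- grid_search(toy$x[idx, ], toy$y[idx], toy$x[!idx, ], toy$y[!idx],
                    grid = grid, cfg = small_cfg(epochs = 200))
  expect_identical(nrow(gs$leaderboard), 2L)
  # both reach ceiling on a separable toy; the smaller spec must win
  if (length(unique(gs$leaderboard$val_accuracy)) == 1L)
    expect_identical(gs$optimal, grid[[2L]])
  expect_error(grid_search(toy$x, toy$y, toy$x, toy$y, grid = list()),
               "empty grid")
})

test_that("the ensemble trains, predicts coherently, and fuses its bases", {
  toy <- toy_separable(n = 45, width = 20, seed = 6)
  cfg <- ecnn_config(optimal_spec = list(k1 = 3, c1 = 16, k2 = 3, c2 = 32),
                     train_cfg = small_cfg(epochs = 150), seed = 11)
  fit <- train_ensemble(toy$x, toy$y, cfg)
  expect_length(fit$bases, 10L)
  probs <- predict(fit, toy$x, type = "prob")
  expect_identical(dim(probs), c(45L, 3L))
  expect_equal(rowSums(probs), rep(1, 45), tolerance = 1e-6)
  expect_equal(mean(predict(fit, toy$x, type = "class") == toy$y), 1)
  # permuting samples permutes predictions identically
  perm <- sample(45)
  expect_identical(predict(fit, toy$x[perm, ], type = "class"),
                   predict(fit, toy$x, type = "class")[perm])
  expect_error(predict(fit, toy$x[, 1:5]), "width")
  expect_error(train_ensemble(toy$x, factor(rep("a", 45))), "2 classes")
})
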