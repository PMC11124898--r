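#' Stratified train/validation/test split
#'
#' Splits sample indices 60/10/30% per class (the study's 180/30/90 layout
#' for 300 samples), deterministically by seed. Class counts that do not
#' divide exactly assign the remainder to train, then test, then validation.
#'
#' @param labels class labels.
#' @param seed integer seed.
#' @param proportions named numeric vector summing to 1.
#' @return List with integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
stratified_split <- function(labels, seed = 1,
                             proportions = c(train = 0.6, val = 0.1,
                                             test = 0.3)) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9)
  train <- val <- test <- integer(0)
  with_seed(seed, {
    for (lev in unique(labels)) {
      idx <- sample(which(labels == lev))
      n <- length(idx)
      n_tr <- floor(n * proportions["train"])
      n_te <- floor(n * proportions["test"])
      n_va <- floor(n * proportions["val"])
      left <- n - n_tr - n_te - n_va
      add <- rep(c("train", "test", "val"), length.out = left)
      n_tr <- n_tr + sum(add == "train")
      n_te <- n_te + sum(add == "test")
      n_va <- n_va + sum(add == "val")
      if (min(n_tr, n_te, n_va) < 1L)
        stop("class ", lev, " too small (", n,
             " samples) for a stratified split")
      train <- c(train, idx[seq_len(n_tr)])
      val <- c(val, idx[n_tr + seq_len(n_va)])
      test <- c(test, idx[n_tr + n_va + seq_len(n_te)])
    }
  })
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Confusion matrix
#'
#' Rows are truth, columns predictions; the trace over the total is the
#' accuracy.
#'
#' @param truth,predicted equal-length label vectors.
#' @param levels label levels fixing the matrix layout.
#' @return Integer matrix of counts.
#' @export
confusion_matrix <- function(truth, predicted,
                             levels = sort(unique(c(as.character(truth),
                                                    as.character(predicted))))) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  truth <- factor(as.character(truth), levels = levels)
  predicted <- factor(as.character(predicted), levels = levels)
  if (anyNA(truth) || anyNA(predicted)) stop("label outside provided levels")
  as.matrix(table(truth = truth, predicted = predicted))
}

# Train one classifier and return test predictions plus training accuracy.
fit_and_predict <- function(model, x_tr, y_tr, x_te, seed, ecnn_cfg,
                            train_cfg) {
  y_tr <- factor(y_tr)
  switch(model,
    svm = {
      fit <- e1071::svm(x_tr, y_tr, kernel = "radial", cost = 1,
                        scale = FALSE)
      list(test = stats::predict(fit, x_te),
           train = stats::predict(fit, x_tr))
    },
    lr = {
      df <- data.frame(y = y_tr, x_tr, check.names = TRUE)
      fit <- nnet::multinom(y ~ ., df, trace = FALSE, decay = 0.01,
                            maxit = 200, MaxNWts = 1e5)
      te <- data.frame(x_te, check.names = TRUE)
      colnames(te) <- colnames(df)[-1]
      tr <- data.frame(x_tr, check.names = TRUE)
      colnames(tr) <- colnames(df)[-1]
      list(test = stats::predict(fit, te), train = stats::predict(fit, tr))
    },
    knn = list(test = class::knn(x_tr, x_te, y_tr, k = 5),
               train = class::knn(x_tr, x_tr, y_tr, k = 5)),
    cnn = {
      cfg <- train_cfg
      cfg$seed <- substream_seed(seed, "single-cnn")
      fit <- train_base(ecnn_cfg$optimal_spec, x_tr, y_tr, cfg)
      list(test = predict(fit, x_te, type = "class"),
           train = predict(fit, x_tr, type = "class"))
    },
    ecnn = {
      cfg <- ecnn_cfg
      cfg$train_cfg <- train_cfg
      cfg$seed <- substream_seed(seed, "ecnn")
      fit <- train_ensemble(x_tr, y_tr, cfg)
      list(test = predict(fit, x_te, type = "class"),
           train = predict(fit, x_tr, type = "class"),
           fit = fit)
    },
    stop("unknown model: ", model)
  )
}

#' Repeated-split evaluation of the classifier suite
#'
#' Reproduces the study protocol on a feature table: for each repeat, a
#' stratified 60/10/30 split is drawn, the min-max normalizer is fitted on
#' the training split and applied with clipping everywhere, and each model is
#' trained and scored on the test split — once on the raw features and (when
#' the "discretized" condition is on) once on the class-overlap one-hot
#' encoding fitted on the training split. Reports per-cell run accuracies,
#' mean, sd, the best run's confusion matrix, and the discretization delta
#' per model.
#'
#' @param table feature table (typically restricted to selected features).
#' @param models subset of \code{c("svm", "lr", "knn", "cnn", "ecnn")}.
#' @param conditions subset of \code{c("raw", "discretized")}.
#' @param n_repeats repeated seeded splits (default 5).
#' @param seed root seed; repeat r uses a derived substream.
#' @param ecnn_cfg an \code{\link{ecnn_config}} for the CNN models.
#' @param train_cfg a \code{\link{train_config}} for the CNN models.
#' @return An \code{enose_report}: nested results, deltas, seeds.
#' @export
run_experiment <- function(table,
                           models = c("svm", "lr", "knn", "cnn", "ecnn"),
                           conditions = c("raw", "discretized"),
                           n_repeats = 5, seed = 1,
                           ecnn_cfg = ecnn_config(),
                           train_cfg = train_config()) {
  models <- match.arg(models, several.ok = TRUE)
  conditions <- match.arg(conditions, several.ok = TRUE)
  labels <- factor(table$label)
  cells <- list()
  base_accs <- list()
  for (r in seq_len(n_repeats)) {
    rseed <- substream_seed(seed, paste0("repeat-", r))
    split <- stratified_split(as.character(labels), rseed)
    norm <- fit_normalizer(table[split$train, ])
    normed <- suppressWarnings(apply_normalizer(table, norm))
    for (cond in conditions) {
      if (cond == "raw") {
        feats <- as.matrix(normed[feature_columns(normed)])
      } else {
        disc <- fit_discretizer(normed[split$train, ])
        enc <- one_hot_encode(discretize_transform(disc, normed), disc)
        feats <- as.matrix(enc[feature_columns(enc)])
      }
      x_tr <- feats[split$train, , drop = FALSE]
      x_te <- feats[split$test, , drop = FALSE]
      x_va <- feats[split$val, , drop = FALSE]
      y_tr <- labels[split$train]; y_te <- labels[split$test]
      y_va <- labels[split$val]
      for (model in models) {
        key <- paste(model, cond, sep = ".")
        res <- tryCatch(
          # local RNG per cell: some baselines (knn tie-breaks) consume RNG
          with_seed(substream_seed(rseed, paste0("fit-", model)),
                    fit_and_predict(model, x_tr, y_tr, x_te, rseed, ecnn_cfg,
                                    train_cfg)),
          error = function(e) e)
        if (inherits(res, "error")) {
          cells[[key]]$errors <- c(cells[[key]]$errors, conditionMessage(res))
          next
        }
        acc <- mean(as.character(res$test) == as.character(y_te))
        cells[[key]]$test_acc <- c(cells[[key]]$test_acc, acc)
        cells[[key]]$train_acc <- c(cells[[key]]$train_acc,
          mean(as.character(res$train) == as.character(y_tr)))
        cells[[key]]$seeds <- c(cells[[key]]$seeds, rseed)
        if (is.null(cells[[key]]$best_acc) || acc > cells[[key]]$best_acc) {
          cells[[key]]$best_acc <- acc
          cells[[key]]$confusion <- confusion_matrix(y_te, res$test,
                                                     levels = levels(labels))
        }
        if (model == "ecnn" && !is.null(res$fit)) {
          ba_te <- vapply(res$fit$bases, function(b)
            mean(predict(b, x_te, type = "class") == y_te), 0)
          ba_va <- vapply(res$fit$bases, function(b)
            mean(predict(b, x_va, type = "class") == y_va), 0)
          base_accs[[cond]]$test <- rbind(base_accs[[cond]]$test, ba_te)
          base_accs[[cond]]$val <- rbind(base_accs[[cond]]$val, ba_va)
        }
      }
    }
  }
  summarise_cell <- function(cell) {
    if (is.null(cell$test_acc)) return(cell)
    cell$mean <- mean(cell$test_acc)
    cell$sd <- stats::sd(cell$test_acc)
    cell
  }
  cells <- lapply(cells, summarise_cell)
  deltas <- sapply(models, function(m) {
    a <- cells[[paste0(m, ".raw")]]$mean
    b <- cells[[paste0(m, ".discretized")]]$mean
    if (is.null(a) || is.null(b)) NA_real_ else b - a
  })
  structure(list(cells = cells, deltas = deltas, base_accs = base_accs,
                 models = models, conditions = conditions,
                 n_repeats = n_repeats, seed = seed),
            class = "enose_report")
}

#' @export
print.enose_report <- function(x, digits = 2, ...) {
  cat("E-nose evaluation (", x$n_repeats, "repeats )\n")
  fmt <- function(cell) {
    if (is.null(cell$mean)) return("failed")
    sprintf("%.*f +/- %.*f", digits, 100 * cell$mean, digits,
            100 * (cell$sd %||% 0))
  }
  for (m in x$models) {
    line <- sprintf("  %-5s", m)
    for (cond in x$conditions)
      line <- paste0(line, sprintf(" | %-11s %s", cond,
                                   fmt(x$cells[[paste(m, cond, sep = ".")]])))
    if (!is.na(x$deltas[m]))
      line <- paste0(line, sprintf(" | delta %+.*f", digits,
                                   100 * x$deltas[m]))
    cat(line, "\n")
  }
  invisible(x)
}

#' Markdown accuracy table of a report
#'
#' Renders the report as a Markdown table in the layout of the study's
#' accuracy tables (training and test accuracy per condition, delta column).
#'
#' @param report an \code{enose_report}.
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  hdr <- c(
    "| Model | Train acc (raw) | Test acc (raw) | Train acc (disc) | Test acc (disc) | delta |",
    "|---|---|---|---|---|---|")
  pct <- function(v) if (is.null(v)) "-" else
    sprintf("%.2f ± %.2f", 100 * mean(v), 100 * stats::sd(v))
  rows <- vapply(report$models, function(m) {
    raw <- report$cells[[paste0(m, ".raw")]]
    disc <- report$cells[[paste0(m, ".discretized")]]
    sprintf("| %s | %s | %s | %s | %s | %s |", toupper(m),
            pct(raw$train_acc), pct(raw$test_acc),
            pct(disc$train_acc), pct(disc$test_acc),
            if (is.na(report$deltas[m])) "-" else
              sprintf("%+.2f", 100 * report$deltas[m]))
  }, "")
  c(hdr, rows)
}
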