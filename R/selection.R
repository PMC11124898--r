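#' Configuration of the two-stage feature selection
#'
#' @param alpha weight of the pairwise-redundancy penalty (>= 0).
#' @param beta weight of the class-conditional-redundancy penalty (>= 0).
#' @param mi_bins equal-frequency bin count for the MI estimators.
#' @param filter_threshold filter cutoff; a quantile of the score
#'   distribution when \code{threshold_type = "quantile"} (default lower
#'   quartile), an absolute score otherwise.
#' @param threshold_type "quantile" or "absolute".
#' @param cv_folds folds of the wrapper's cross-validation (>= 2).
#' @param svc_kernel,svc_cost kernel and regularization weight of the
#'   support-vector classifier driving the wrapper.
#' @param min_features floor below which the wrapper stops deleting (default
#'   1, the pure procedure). When cross-validated accuracy saturates, ties
#'   favouring deletion prune aggressively; pipelines feeding a convolutional
#'   model set a floor so the selected vector keeps a usable width.
#' @param seed seed for the wrapper's random feature order and fold draw.
#' @return An \code{enose_selcfg} list.
#' @export
selection_config <- function(alpha = 1, beta = 1, mi_bins = 8,
                             filter_threshold = 0.25,
                             threshold_type = c("quantile", "absolute"),
                             cv_folds = 5, svc_kernel = "radial",
                             svc_cost = 1, min_features = 1, seed = 1) {
  threshold_type <- match.arg(threshold_type)
  stopifnot(alpha >= 0, beta >= 0, mi_bins >= 2, cv_folds >= 2,
            min_features >= 1)
  structure(list(alpha = alpha, beta = beta, mi_bins = mi_bins,
                 filter_threshold = filter_threshold,
                 threshold_type = threshold_type, cv_folds = cv_folds,
                 svc_kernel = svc_kernel, svc_cost = svc_cost,
                 min_features = min_features, seed = seed),
            class = "enose_selcfg")
}

#' Mixed-mutual-information (MIME) feature scores
#'
#' Scores each feature by its mutual information with the class label,
#' penalized by its average pairwise mutual information and average
#' class-conditional mutual information with the other features:
#' \deqn{score(F_i) = I(F_i, y) - \alpha \frac{1}{m}\sum_{j \ne i} I(F_i, F_j)
#'   - \beta \frac{1}{m}\sum_{j \ne i} I(F_i, F_j \mid y)}
#' with \eqn{m} the number of other features. High-scoring features are
#' informative about the class and non-redundant given the rest.
#'
#' @param table feature table (metadata + numeric feature columns).
#' @param labels class labels (defaults to the table's \code{label} column).
#' @param cfg an \code{\link{selection_config}}.
#' @return Named numeric score vector over the feature columns.
#' @export
mime_scores <- function(table, labels = table$label, cfg = selection_config()) {
  feats <- feature_columns(table)
  if (length(feats) < 2L) stop("need at least 2 features")
  codes <- vapply(table[feats], as_codes, integer(nrow(table)),
                  bins = cfg$mi_bins)
  y <- as.integer(factor(labels))
  p <- length(feats)
  rel <- vapply(seq_len(p), function(i) mi_codes(codes[, i], y), 0)
  red <- matrix(0, p, p)
  cred <- matrix(0, p, p)
  levs <- sort(unique(y))
  idx_by_class <- lapply(levs, function(l) which(y == l))
  w <- lengths(idx_by_class) / length(y)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      red[i, j] <- red[j, i] <- mi_codes(codes[, i], codes[, j])
      cm <- 0
      for (k in seq_along(levs)) {
        idx <- idx_by_class[[k]]
        if (length(idx) >= 2L)
          cm <- cm + w[k] * mi_codes(codes[idx, i], codes[idx, j])
      }
      cred[i, j] <- cred[j, i] <- cm
    }
  }
  m <- p - 1L
  scores <- rel - cfg$alpha * rowSums(red) / m - cfg$beta * rowSums(cred) / m
  names(scores) <- feats
  scores
}

#' Filter stage of the selection
#'
#' Keeps features whose score reaches the threshold (a score-distribution
#' quantile by default). Never empties the set: if nothing clears the
#' threshold the single best-scoring feature is kept.
#'
#' @param scores named score vector from \code{\link{mime_scores}}.
#' @param cfg an \code{\link{selection_config}}.
#' @return Character vector of surviving feature names.
#' @export
filter_stage <- function(scores, cfg = selection_config()) {
  thr <- if (cfg$threshold_type == "quantile")
    stats::quantile(scores, cfg$filter_threshold, names = FALSE)
  else cfg$filter_threshold
  keep <- names(scores)[scores >= thr]
  if (length(keep) == 0L) keep <- names(which.max(scores))
  keep
}

# Stratified fold assignment, deterministic by seed.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lev in unique(labels)) {
      idx <- sample(which(labels == lev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

svc_cv_accuracy <- function(x, y, folds, cfg) {
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                      kernel = cfg$svc_kernel, cost = cfg$svc_cost,
                      scale = FALSE)
    mean(stats::predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
  }, 0)
  mean(accs)
}

#' Recursive feature elimination wrapped around a cross-validated SVM
#'
#' Iteratively proposes removing one not-yet-tested feature, chosen uniformly
#' at random (seeded), and evaluates mean cross-validated accuracy of a
#' support-vector classifier without it. If accuracy does not decrease
#' relative to the incumbent, the feature is permanently deleted (ties favour
#' deletion — smaller models) and all remaining features become candidates
#' again; otherwise the feature is marked tested. Terminates when every
#' remaining feature has been tested since the last deletion. Cross-validation
#' folds are drawn once and held fixed so evaluations are comparable.
#'
#' @param table feature table restricted to the filter-stage survivors.
#' @param labels class labels.
#' @param cfg an \code{\link{selection_config}}.
#' @return List with \code{selected} (feature names), \code{initial_accuracy},
#'   \code{final_accuracy} and \code{log} (data.frame of every decision).
#' @export
rfecv_wrapper <- function(table, labels = table$label,
                          cfg = selection_config()) {
  feats <- feature_columns(table)
  if (length(feats) < 2L) stop("need at least 2 surviving features")
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("labels are degenerate (single class)")
  x <- as.matrix(table[feats])
  folds <- stratified_folds(as.character(y), cfg$cv_folds,
                            substream_seed(cfg$seed, "rfecv-folds"))
  current <- feats
  incumbent <- svc_cv_accuracy(x[, current, drop = FALSE], y, folds, cfg)
  initial <- incumbent
  untested <- current
  log <- list()
  it <- 0L
  rng_seed <- substream_seed(cfg$seed, "rfecv-order")
  min_feat <- max(1L, cfg$min_features %||% 1L)
  with_seed(rng_seed, {
    while (length(untested) > 0L && length(current) > min_feat) {
      it <- it + 1L
      f <- untested[sample.int(length(untested), 1L)]
      candidate <- setdiff(current, f)
      acc <- svc_cv_accuracy(x[, candidate, drop = FALSE], y, folds, cfg)
      removed <- acc >= incumbent
      log[[it]] <- data.frame(iteration = it, feature = f,
                              cv_accuracy = acc, removed = removed,
                              n_remaining = length(current) - removed,
                              stringsAsFactors = FALSE)
      if (removed) {
        current <- candidate
        incumbent <- acc
        untested <- current # a deletion resets the tested set
      } else {
        untested <- setdiff(untested, f)
      }
    }
  })
  list(selected = current, initial_accuracy = initial,
       final_accuracy = incumbent,
       log = do.call(rbind, log) %||% data.frame())
}

#' Two-stage MIME-(SVM-RFECV) feature selection
#'
#' Filter stage: score every feature by \code{\link{mime_scores}} and keep
#' those above the threshold. Wrapper stage: \code{\link{rfecv_wrapper}} on
#' the survivors.
#'
#' @param table feature table.
#' @param labels class labels.
#' @param cfg an \code{\link{selection_config}}.
#' @return An \code{enose_selection}: \code{selected}, \code{mime_scores},
#'   \code{filtered} (filter survivors), \code{wrapper_log}, accuracies.
#' @export
select_features <- function(table, labels = table$label,
                            cfg = selection_config()) {
  scores <- mime_scores(table, labels, cfg)
  survivors <- filter_stage(scores, cfg)
  wrap <- rfecv_wrapper(table[c(intersect(META_COLS, names(table)), survivors)],
                        labels, cfg)
  structure(list(selected = wrap$selected, mime_scores = scores,
                 filtered = survivors, wrapper_log = wrap$log,
                 initial_accuracy = wrap$initial_accuracy,
                 final_accuracy = wrap$final_accuracy),
            class = "enose_selection")
}

#' @export
print.enose_selection <- function(x, ...) {
  cat("MIME-(SVM-RFECV) selection:", length(x$selected), "of",
      length(x$mime_scores), "features kept\n",
      " filter survivors:", length(x$filtered), "\n",
      sprintf("  wrapper cv accuracy: %.3f -> %.3f\n",
              x$initial_accuracy, x$final_accuracy))
  invisible(x)
}
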