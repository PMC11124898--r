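#' Hyperparameter grid of the base networks
#'
#' Two convolutional layers, both stride 2: kernel sizes {3,5,7,9} x kernel
#' counts {8,16,32,64} for the first layer and {3,5,7} x {32,64,128} for the
#' second — 144 hyperparameter groups in total.
#'
#' @return List of 144 spec lists \code{(k1, c1, k2, c2)} in lexicographic
#'   order of \code{(k1, c1, k2, c2)}.
#' @export
base_cnn_grid <- function() {
  g <- expand.grid(c2 = c(32, 64, 128), k2 = c(3, 5, 7),
                   c1 = c(8, 16, 32, 64), k1 = c(3, 5, 7, 9))
  g <- g[order(g$k1, g$c1, g$k2, g$c2), ]
  lapply(seq_len(nrow(g)), function(i)
    list(k1 = g$k1[i], c1 = g$c1[i], k2 = g$k2[i], c2 = g$c2[i]))
}

#' Hyperparameter grid of the meta network
#'
#' One convolutional layer (kernel sizes {3,5,7}, kernel counts
#' {4,8,16,32,64}) and one dense layer to the class scores — 15 groups.
#'
#' @return List of 15 spec lists \code{(k, c)}.
#' @export
meta_cnn_grid <- function() {
  g <- expand.grid(c = c(4, 8, 16, 32, 64), k = c(3, 5, 7))
  g <- g[order(g$k, g$c), ]
  lapply(seq_len(nrow(g)), function(i) list(k = g$k[i], c = g$c[i]))
}

spec_id <- function(spec) paste(unlist(spec), collapse = "-")

spec_feasible <- function(spec, input_width) {
  !inherits(try(build_layers(spec, input_width), silent = TRUE), "try-error")
}

spec_params <- function(spec, input_width, hidden = 200L, classes = 3L) {
  count_params(build_layers(spec, input_width, hidden, classes))
}

#' Train a base network
#'
#' Validates that the spec's receptive field fits the input width after
#' striding (infeasible specs are rejected before training) and trains a
#' two-conv-layer network with a (n, 200), (200, classes) dense head.
#'
#' @param spec base spec \code{list(k1, c1, k2, c2)}.
#' @param x numeric training matrix (samples x features).
#' @param y class labels.
#' @param cfg a \code{\link{train_config}}.
#' @return An \code{enose_cnn}.
#' @export
train_base <- function(spec, x, y, cfg = train_config()) {
  build_layers(spec, ncol(x)) # errors early on infeasible specs
  train_cnn(spec, x, y, cfg)
}

#' Grid search over base-network hyperparameters
#'
#' Trains one network per grid point on the training set, scores validation
#' accuracy, and returns the best spec. Ties are broken by smaller parameter
#' count, then lexicographic spec order. Specs infeasible for the input width
#' stay in the leaderboard with NA accuracy.
#'
#' @param train_x,train_y training set.
#' @param val_x,val_y validation set.
#' @param grid list of specs (default the full 144-point grid).
#' @param cfg a \code{\link{train_config}}; each spec trains from a seed
#'   derived from it.
#' @return List with \code{optimal} (spec) and \code{leaderboard}
#'   (data.frame with one row per grid point).
#' @export
grid_search <- function(train_x, train_y, val_x, val_y,
                        grid = base_cnn_grid(), cfg = train_config()) {
  if (length(grid) == 0L) stop("empty grid")
  rows <- lapply(grid, function(spec) {
    feas <- spec_feasible(spec, ncol(train_x))
    acc <- NA_real_; np <- NA_real_
    if (feas) {
      scfg <- cfg
      scfg$seed <- substream_seed(cfg$seed, paste0("grid-", spec_id(spec)))
      fit <- train_cnn(spec, train_x, train_y, scfg)
      acc <- mean(predict(fit, val_x, type = "class") == val_y)
      np <- spec_params(spec, ncol(train_x))
    }
    data.frame(k1 = spec$k1, c1 = spec$c1, k2 = spec$k2, c2 = spec$c2,
               feasible = feas, n_params = np, val_accuracy = acc)
  })
  lb <- do.call(rbind, rows)
  ok <- which(lb$feasible)
  if (length(ok) == 0L) stop("no feasible spec for this input width")
  ord <- ok[order(-lb$val_accuracy[ok], lb$n_params[ok],
                  lb$k1[ok], lb$c1[ok], lb$k2[ok], lb$c2[ok])]
  list(optimal = grid[[ord[1L]]], leaderboard = lb)
}

#' Neighbourhood of a spec in the hyperparameter grid
#'
#' Returns the spec itself plus the grid points nearest to it under L1
#' distance on grid-index coordinates (kernel-size index and kernel-count
#' index of both layers), the way a diverse set of base classifiers is picked
#' around the grid-search optimum. Deterministic tie-break by lexicographic
#' spec order.
#'
#' @param optimal a base spec present in the grid.
#' @param count how many specs to return (default 10).
#' @param input_width if given, infeasible specs for this width are skipped.
#' @return List of \code{count} distinct specs, the first being
#'   \code{optimal}.
#' @export
neighbor_specs <- function(optimal, count = 10, input_width = NULL) {
  grid <- base_cnn_grid()
  ax <- list(k1 = c(3, 5, 7, 9), c1 = c(8, 16, 32, 64),
             k2 = c(3, 5, 7), c2 = c(32, 64, 128))
  coord <- function(s) c(match(s$k1, ax$k1), match(s$c1, ax$c1),
                         match(s$k2, ax$k2), match(s$c2, ax$c2))
  oc <- coord(optimal)
  if (anyNA(oc)) stop("optimal spec does not lie in the grid")
  if (!is.null(input_width))
    grid <- Filter(function(s) spec_feasible(s, input_width), grid)
  if (length(grid) < count) stop("grid too small for count = ", count)
  d <- vapply(grid, function(s) sum(abs(coord(s) - oc)), 0)
  key <- vapply(grid, function(s)
    sprintf("%02d%03d%02d%03d", s$k1, s$c1, s$k2, s$c2), "")
  grid[order(d, key)][seq_len(count)]
}

#' Ensemble configuration
#'
#' @param optimal_spec grid-search optimum the base classifiers are centred
#'   on; default (5,64)/(3,128).
#' @param meta_spec meta-network spec; default (3,16).
#' @param n_base number of base classifiers (default 10).
#' @param train_cfg a \code{\link{train_config}} shared by all networks.
#' @param meta_folds folds used to build out-of-fold base outputs for the
#'   meta learner (default 5).
#' @param meta_epochs training epochs of the meta network (default 300; its
#'   30-wide input makes it cheap even when base training is scaled down).
#' @param stacking "insample" (default) trains the meta network on the
#'   trained bases' own training-set outputs, the way the stacked ensemble is
#'   described; "oof" uses out-of-fold base outputs instead, which avoids
#'   in-sample optimism in principle but at small training sizes feeds the
#'   meta learner probabilities distribution-shifted away from what the
#'   refit bases emit at prediction time.
#' @param seed root seed of the ensemble.
#' @return An \code{enose_ecnncfg} list.
#' @export
ecnn_config <- function(optimal_spec = list(k1 = 5, c1 = 64, k2 = 3, c2 = 128),
                        meta_spec = list(k = 3, c = 16),
                        n_base = 10, train_cfg = train_config(),
                        meta_folds = 5, meta_epochs = 300,
                        stacking = c("insample", "oof"),
                        seed = 1) {
  stacking <- match.arg(stacking)
  structure(list(optimal_spec = optimal_spec, meta_spec = meta_spec,
                 n_base = n_base, train_cfg = train_cfg,
                 meta_folds = meta_folds, meta_epochs = meta_epochs,
                 stacking = stacking, seed = seed),
            class = "enose_ecnncfg")
}

base_prob_matrix <- function(bases, x) {
  do.call(cbind, lapply(bases, function(b) predict(b, x, type = "prob")))
}

#' Train the ensemble convolutional network
#'
#' Selects \code{n_base} diverse base specs around the optimal hyperparameter
#' group (\code{\link{neighbor_specs}}), builds the meta training matrix from
#' out-of-fold base class probabilities (stratified folds within the training
#' set, concatenated to a \code{3 * n_base}-long score vector per sample),
#' trains the meta network on it, and refits the bases on the full training
#' set.
#'
#' @param x numeric training matrix.
#' @param y class labels (>= 2 classes present).
#' @param cfg an \code{\link{ecnn_config}}.
#' @return An \code{enose_ecnn} with the fitted base networks and meta
#'   network.
#' @export
train_ensemble <- function(x, y, cfg = ecnn_config()) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("need at least 2 classes present")
  specs <- neighbor_specs(cfg$optimal_spec, cfg$n_base, ncol(x))
  tcfg <- cfg$train_cfg
  n <- nrow(x)
  if (cfg$stacking == "oof") {
    folds <- stratified_folds(as.character(y), cfg$meta_folds,
                              substream_seed(cfg$seed, "stack-folds"))
    if (min(table(y, folds)) < 1L)
      stop("fold too small to cover every class")
    meta_x <- matrix(0, n, 3L * cfg$n_base)
    for (f in sort(unique(folds))) {
      hold <- folds == f
      for (b in seq_along(specs)) {
        bcfg <- tcfg
        bcfg$seed <- substream_seed(cfg$seed, sprintf("oof-%d-%d", f, b))
        fit <- train_cnn(specs[[b]], x[!hold, , drop = FALSE], y[!hold], bcfg)
        meta_x[hold, (b - 1L) * 3L + 1:3] <-
          predict(fit, x[hold, , drop = FALSE], type = "prob")
      }
    }
  }
  bases <- lapply(seq_along(specs), function(b) {
    bcfg <- tcfg
    bcfg$seed <- substream_seed(cfg$seed, paste0("base-", b))
    train_cnn(specs[[b]], x, y, bcfg)
  })
  if (cfg$stacking == "insample") meta_x <- base_prob_matrix(bases, x)
  mcfg <- tcfg
  mcfg$epochs <- as.integer(cfg$meta_epochs %||% tcfg$epochs)
  mcfg$seed <- substream_seed(cfg$seed, "meta")
  meta <- train_cnn(cfg$meta_spec, meta_x, y, mcfg)
  structure(list(bases = bases, meta = meta, specs = specs,
                 levels = levels(y), input_width = ncol(x), cfg = cfg),
            class = "enose_ecnn")
}

#' Predict from a trained ensemble
#'
#' Base class probabilities are concatenated into one score vector per sample
#' and fused by the meta network.
#'
#' @param object an \code{enose_ecnn}.
#' @param x numeric matrix with the training input width.
#' @param type "prob" or "class".
#' @param ... unused.
#' @return Probability matrix (rows sum to 1) or factor of labels.
#' @export
predict.enose_ecnn <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (ncol(x) != object$input_width)
    stop("input width ", ncol(x), " does not match training width ",
         object$input_width)
  meta_x <- base_prob_matrix(object$bases, x)
  probs <- predict(object$meta, meta_x, type = "prob")
  if (type == "prob") return(probs)
  factor(object$levels[max.col(probs, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.enose_ecnn <- function(x, ...) {
  cat("Ensemble CNN:", length(x$bases), "base networks, meta spec (",
      x$meta$spec$k, ",", x$meta$spec$c, "), input width",
      x$input_width, "\n")
  invisible(x)
}
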