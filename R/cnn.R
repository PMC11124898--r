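# Minimal 1-D convolutional network engine: valid convolutions with stride,
# ReLU, dense layers, softmax cross-entropy, full-batch gradient descent with
# momentum. Convolutions are realised as im2col gathers followed by one BLAS
# matrix product, which is fast at the problem sizes of a sensor array
# (input widths of tens to a few hundred points, batches of tens to hundreds
# of samples).

conv_out_len <- function(w, k, stride = 2L) {
  if (w < k) return(-1L)
  (w - k) %/% stride + 1L
}

# Gather sliding windows: X array (N, W, C) -> matrix (N*L, k*C), rows
# ordered sample-fastest within each output position.
im2col <- function(X, k, stride, L) {
  d <- dim(X)
  starts <- (seq_len(L) - 1L) * stride
  idx <- as.vector(outer(seq_len(k), starts, `+`)) # k*L positions
  Xs <- X[, idx, , drop = FALSE]                   # N x (k*L) x C
  dim(Xs) <- c(d[1], k, L, d[3])
  Xs <- aperm(Xs, c(1, 3, 2, 4))                   # N x L x k x C
  dim(Xs) <- c(d[1] * L, k * d[3])
  Xs
}

conv_forward <- function(X, Wm, b, k, stride, L) {
  N <- dim(X)[1]
  P <- im2col(X, k, stride, L)
  Z <- P %*% Wm
  Z <- Z + rep(b, each = nrow(Z))
  dim(Z) <- c(N, L, length(b))
  list(Z = Z, P = P)
}

conv_backward <- function(dZ, P, Wm, k, stride, in_dim) {
  N <- in_dim[1]; W_in <- in_dim[2]; C_in <- in_dim[3]
  L <- dim(dZ)[2]; C_out <- dim(dZ)[3]
  dZm <- dZ; dim(dZm) <- c(N * L, C_out)
  dW <- crossprod(P, dZm)
  db <- colSums(dZm)
  dP <- dZm %*% t(Wm)                 # (N*L) x (k*C_in)
  dim(dP) <- c(N, L, k, C_in)
  dX <- array(0, c(N, W_in, C_in))
  starts <- (seq_len(L) - 1L) * stride
  for (kk in seq_len(k)) {
    cols <- starts + kk
    dX[, cols, ] <- dX[, cols, ] + dP[, , kk, ]
  }
  list(dX = dX, dW = dW, db = db)
}

# Build the layer graph of a network spec for a given input width.
# Base spec: list(k1, c1, k2, c2); meta spec: list(k, c).
build_layers <- function(spec, input_width, hidden = 200L, classes = 3L) {
  if (!is.null(spec$k1)) {
    L1 <- conv_out_len(input_width, spec$k1)
    L2 <- if (L1 > 0) conv_out_len(L1, spec$k2) else -1L
    if (L2 < 1L)
      stop(sprintf(
        "spec (%d,%d)/(%d,%d) infeasible for input width %d after striding",
        spec$k1, spec$c1, spec$k2, spec$c2, input_width))
    list(
      list(type = "conv", k = spec$k1, cin = 1L, cout = spec$c1,
           win = input_width, lout = L1, relu = TRUE),
      list(type = "conv", k = spec$k2, cin = spec$c1, cout = spec$c2,
           win = L1, lout = L2, relu = TRUE),
      list(type = "dense", nin = L2 * spec$c2, nout = hidden, relu = TRUE),
      list(type = "dense", nin = hidden, nout = classes, relu = FALSE)
    )
  } else {
    L1 <- conv_out_len(input_width, spec$k)
    if (L1 < 1L)
      stop(sprintf("meta spec (%d,%d) infeasible for input width %d",
                   spec$k, spec$c, input_width))
    list(
      list(type = "conv", k = spec$k, cin = 1L, cout = spec$c,
           win = input_width, lout = L1, relu = TRUE),
      list(type = "dense", nin = L1 * spec$c, nout = classes, relu = FALSE)
    )
  }
}

count_params <- function(layers) {
  sum(vapply(layers, function(l) {
    if (l$type == "conv") l$k * l$cin * l$cout + l$cout
    else l$nin * l$nout + l$nout
  }, 0))
}

# Gaussian initialization, scaled by fan-in.
init_params <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "conv") {
      fan <- l$k * l$cin
      list(W = matrix(stats::rnorm(fan * l$cout, 0, sqrt(2 / fan)),
                      fan, l$cout),
           b = numeric(l$cout))
    } else {
      list(W = matrix(stats::rnorm(l$nin * l$nout, 0, sqrt(2 / l$nin)),
                      l$nin, l$nout),
           b = numeric(l$nout))
    }
  })
}

net_forward <- function(layers, params, X, keep_cache = FALSE) {
  N <- nrow(X)
  A <- array(X, c(N, ncol(X), 1L))
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]; p <- params[[i]]
    if (l$type == "conv") {
      cf <- conv_forward(A, p$W, p$b, l$k, 2L, l$lout)
      Z <- cf$Z
      if (keep_cache) caches[[i]] <- list(P = cf$P, Z = Z, in_dim = dim(A))
      A <- if (l$relu) pmax(Z, 0) else Z
    } else {
      if (length(dim(A)) == 3L) dim(A) <- c(N, prod(dim(A)[-1]))
      Z <- A %*% p$W + rep(p$b, each = N)
      if (keep_cache) caches[[i]] <- list(Ain = A, Z = Z)
      A <- if (l$relu) pmax(Z, 0) else Z
    }
  }
  list(logits = A, caches = caches)
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

net_backward <- function(layers, params, caches, dlogits) {
  grads <- vector("list", length(layers))
  dA <- dlogits
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; p <- params[[i]]; cc <- caches[[i]]
    if (l$type == "dense") {
      dZ <- if (l$relu) dA * (cc$Z > 0) else dA
      grads[[i]] <- list(W = crossprod(cc$Ain, dZ), b = colSums(dZ))
      dA <- dZ %*% t(p$W)
    } else {
      if (is.matrix(dA)) dim(dA) <- c(dim(cc$Z))
      dZ <- if (l$relu) dA * (cc$Z > 0) else dA
      cb <- conv_backward(dZ, cc$P, p$W, l$k, 2L, cc$in_dim)
      grads[[i]] <- list(W = cb$dW, b = cb$db)
      dA <- cb$dX
    }
  }
  grads
}

#' Training configuration of the convolutional networks
#'
#' Full-batch gradient descent with momentum. \code{decay} is the momentum
#' coefficient by default; setting \code{decay_mode = "lr_decay"} instead
#' multiplies the learning rate by \code{decay} each epoch (an alternative
#' reading of "decay"; it shrinks the step to nothing over hundreds of epochs
#' and is kept only for comparison runs).
#'
#' @param learning_rate step size (default 0.001).
#' @param decay momentum coefficient (default 0.9).
#' @param epochs training epochs (default 300; 0 leaves the network at its
#'   random initialization).
#' @param decay_mode "momentum" or "lr_decay".
#' @param seed seed of the Gaussian initialization.
#' @return An \code{enose_traincfg} list.
#' @export
train_config <- function(learning_rate = 0.001, decay = 0.9, epochs = 300,
                         decay_mode = c("momentum", "lr_decay"), seed = 1) {
  decay_mode <- match.arg(decay_mode)
  stopifnot(learning_rate > 0, epochs >= 0)
  structure(list(learning_rate = learning_rate, decay = decay,
                 epochs = as.integer(epochs), decay_mode = decay_mode,
                 seed = seed),
            class = "enose_traincfg")
}

# Train a network on a numeric matrix x (samples x width) and factor y.
train_cnn <- function(spec, x, y, cfg = train_config(), hidden = 200L) {
  y <- factor(y)
  layers <- build_layers(spec, ncol(x), hidden = hidden,
                         classes = nlevels(y))
  params <- with_seed(substream_seed(cfg$seed, "cnn-init"),
                      init_params(layers))
  vel <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  onehot <- matrix(0, nrow(x), nlevels(y))
  onehot[cbind(seq_len(nrow(x)), as.integer(y))] <- 1
  losses <- numeric(cfg$epochs)
  lr <- cfg$learning_rate
  for (ep in seq_len(cfg$epochs)) {
    fw <- net_forward(layers, params, x, keep_cache = TRUE)
    probs <- softmax(fw$logits)
    losses[ep] <- -mean(log(pmax(probs[onehot == 1], 1e-12)))
    dlogits <- (probs - onehot) / nrow(x)
    grads <- net_backward(layers, params, fw$caches, dlogits)
    if (cfg$decay_mode == "lr_decay") {
      step <- lr * cfg$decay^(ep - 1)
      for (i in seq_along(params)) {
        params[[i]]$W <- params[[i]]$W - step * grads[[i]]$W
        params[[i]]$b <- params[[i]]$b - step * grads[[i]]$b
      }
    } else {
      for (i in seq_along(params)) {
        vel[[i]]$W <- cfg$decay * vel[[i]]$W - lr * grads[[i]]$W
        vel[[i]]$b <- cfg$decay * vel[[i]]$b - lr * grads[[i]]$b
        params[[i]]$W <- params[[i]]$W + vel[[i]]$W
        params[[i]]$b <- params[[i]]$b + vel[[i]]$b
      }
    }
  }
  structure(list(spec = spec, layers = layers, params = params,
                 levels = levels(y), input_width = ncol(x),
                 losses = losses, cfg = cfg),
            class = "enose_cnn")
}

#' Predict from a trained convolutional network
#'
#' @param object an \code{enose_cnn}.
#' @param x numeric matrix (samples x input width).
#' @param type "prob" for the softmax score matrix, "class" for labels.
#' @param ... unused.
#' @return Probability matrix (rows sum to 1) or factor of labels.
#' @export
predict.enose_cnn <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (ncol(x) != object$input_width)
    stop("input width ", ncol(x), " does not match training width ",
         object$input_width)
  probs <- softmax(net_forward(object$layers, object$params, x)$logits)
  colnames(probs) <- object$levels
  if (type == "prob") return(probs)
  factor(object$levels[max.col(probs, ties.method = "first")],
         levels = object$levels)
}
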