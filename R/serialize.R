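# Model checkpoints as self-describing JSON: the spec of every network plus
# its weight matrices at full (17 significant digit) precision, so predictions
# from a reloaded model are bit-identical.

cnn_to_list <- function(fit) {
  list(type = "cnn", spec = fit$spec, levels = fit$levels,
       input_width = fit$input_width,
       params = lapply(fit$params, function(p)
         list(W = p$W, b = p$b)))
}

as_mat <- function(W) {
  if (is.matrix(W)) return(W)
  do.call(rbind, lapply(W, function(r) as.numeric(unlist(r))))
}

cnn_from_list <- function(obj) {
  params <- lapply(obj$params, function(p)
    list(W = as_mat(p$W), b = as.numeric(unlist(p$b))))
  spec <- lapply(obj$spec, as.numeric)
  levels <- as.character(unlist(obj$levels))
  layers <- build_layers(spec, as.integer(obj$input_width),
                         classes = length(levels))
  structure(list(spec = spec, layers = layers, params = params,
                 levels = levels,
                 input_width = as.integer(obj$input_width),
                 losses = numeric(0), cfg = NULL),
            class = "enose_cnn")
}

#' Save a trained model to JSON
#'
#' Serializes a base network (\code{enose_cnn}) or ensemble
#' (\code{enose_ecnn}) to a self-describing JSON checkpoint: network specs
#' plus weights at full precision. A reloaded model predicts identically.
#'
#' @param model an \code{enose_cnn} or \code{enose_ecnn}.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  obj <- if (inherits(model, "enose_ecnn")) {
    list(type = "ecnn", levels = model$levels,
         input_width = model$input_width,
         bases = lapply(model$bases, cnn_to_list),
         meta = cnn_to_list(model$meta))
  } else if (inherits(model, "enose_cnn")) {
    cnn_to_list(model)
  } else stop("not a trained enose model")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by \code{\link{write_model}}
#'
#' @param path JSON checkpoint.
#' @return An \code{enose_cnn} or \code{enose_ecnn}.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(obj$type, "cnn")) return(cnn_from_list(obj))
  if (!identical(obj$type, "ecnn")) stop("unrecognized checkpoint: ", path)
  bases <- lapply(obj$bases, cnn_from_list)
  structure(list(bases = bases, meta = cnn_from_list(obj$meta),
                 specs = lapply(bases, `[[`, "spec"),
                 levels = as.character(unlist(obj$levels)),
                 input_width = as.integer(obj$input_width), cfg = NULL),
            class = "enose_ecnn")
}
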