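#' @keywords internal
"_PACKAGE"

#' Derive a named sub-seed from one root seed
#'
#' All stage-level randomness in the package flows from one root seed through
#' named substreams, so a single integer reproduces a full experiment. The
#' derived seed is deterministic in (seed, stage) and stays inside the 32-bit
#' integer range.
#'
#' @param seed root integer seed.
#' @param stage substream name, e.g. "simulate", "selection", "repeat-3".
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the RNG with \code{seed}, evaluates \code{expr}, and restores the
#' caller's RNG state afterwards, so seeded computations do not perturb the
#' surrounding random stream.
#'
#' @param seed integer seed for the local stream.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

CLASS_LABELS <- c("normal", "slight", "total")

check_class_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || !label %in% CLASS_LABELS)
    stop("unknown class label: ", paste(label, collapse = ","),
         " (expected one of ", paste(CLASS_LABELS, collapse = ", "), ")")
  label
}
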