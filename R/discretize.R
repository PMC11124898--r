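#' Fit a supervised class-overlap discretizer
#'
#' For every feature, computes each class's value range on the fitting data
#' and splits the feature's global range at every class-range endpoint lying
#' strictly inside it. The resulting segments separate pure regions (covered
#' by a single class range) from overlap regions (covered by several), and
#' gaps between disjoint class ranges keep their own segment. Segment tags
#' are the left-to-right indices 1..K.
#'
#' With three classes of disjoint ranges [0,1], [2,3], [4,5] this yields five
#' segments (three pure, two gaps); two classes [0,2] and [1,3] yield three
#' (pure, overlap, pure); identical ranges collapse to a single segment.
#'
#' @param table feature table (fit on training data only; the scheme can be
#'   fitted on all samples for fidelity runs, but that leaks test ranges).
#' @param labels class labels.
#' @return An \code{enose_discretizer}: per feature, the sorted breakpoints,
#'   segment count \code{K}, global range, and the class ranges used.
#' @export
fit_discretizer <- function(table, labels = table$label) {
  feats <- feature_columns(table)
  if (length(feats) == 0L || nrow(table) == 0L) stop("empty table")
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2L) stop("need at least 2 classes present")
  per_feature <- lapply(feats, function(f) {
    v <- table[[f]]
    ranges <- t(vapply(levels(y), function(l) {
      vv <- v[y == l]
      c(lo = min(vv), hi = max(vv))
    }, c(lo = 0, hi = 0)))
    glo <- min(ranges[, "lo"]); ghi <- max(ranges[, "hi"])
    ends <- sort(unique(as.vector(ranges)))
    breakpoints <- ends[ends > glo & ends < ghi]
    list(breakpoints = breakpoints, K = length(breakpoints) + 1L,
         global = c(glo, ghi), class_ranges = ranges)
  })
  names(per_feature) <- feats
  structure(list(features = feats, model = per_feature),
            class = "enose_discretizer")
}

#' Map feature values to segment tags
#'
#' Values are assigned the tag of the segment containing them, under the
#' half-open convention [b_k, b_{k+1}) with the last segment closed; values
#' outside the fitted global range are clipped into the first/last segment.
#' The mapping is monotone non-decreasing in the value.
#'
#' @param model an \code{enose_discretizer}.
#' @param table feature table with the fitted feature columns.
#' @return The table with feature columns replaced by integer tags.
#' @export
discretize_transform <- function(model, table) {
  stopifnot(inherits(model, "enose_discretizer"))
  feats <- feature_columns(table)
  if (!setequal(feats, model$features))
    stop("feature names do not match the fitted discretizer")
  for (f in model$features) {
    bp <- model$model[[f]]$breakpoints
    # tag = 1 + number of breakpoints <= value (half-open [b, b') segments);
    # values beyond the global range clip into the end segments automatically
    table[[f]] <- findInterval(table[[f]], bp) + 1L
  }
  table
}

#' One-hot encode a tagged table
#'
#' Each discretized feature with K segments expands to K binary columns
#' ("<feature>_seg<k>") with a single 1 at its tag position, so the encoded
#' row length is the sum of segment counts. With
#' \code{uniform_width = TRUE} every feature instead occupies
#' \code{max(K)} columns (trailing columns always zero), giving the encoding
#' a regular per-feature block structure. The padding columns are inert for
#' distance- and kernel-based models, but the regular grid matters to the
#' 1-D convolutional models, whose shared kernels otherwise straddle
#' misaligned blocks.
#'
#' @param tagged table produced by \code{\link{discretize_transform}}.
#' @param model the fitted \code{enose_discretizer}.
#' @param uniform_width pad every feature's block to the maximum segment
#'   count (default FALSE).
#' @return Feature table of one-hot blocks.
#' @export
one_hot_encode <- function(tagged, model, uniform_width = FALSE) {
  stopifnot(inherits(model, "enose_discretizer"))
  kmax <- max(vapply(model$model, `[[`, 0L, "K"))
  blocks <- lapply(model$features, function(f) {
    K <- model$model[[f]]$K
    tags <- tagged[[f]]
    if (any(tags < 1L | tags > K)) stop("tag out of range for ", f)
    width <- if (uniform_width) kmax else K
    m <- matrix(0L, nrow = length(tags), ncol = width,
                dimnames = list(NULL, paste0(f, "_seg", seq_len(width))))
    m[cbind(seq_along(tags), tags)] <- 1L
    m
  })
  meta <- tagged[intersect(META_COLS, names(tagged))]
  out <- cbind(meta, as.data.frame(do.call(cbind, blocks),
                                   check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Mean inter-class range-overlap fraction
#'
#' For each feature, the fraction of its global range covered by at least one
#' pairwise intersection of class ranges; averaged over features. This is the
#' quantity the discretizer segments on, and the statistic by which a noisy
#' storage environment shows wider class overlap than a laboratory one.
#'
#' @param table feature table.
#' @param labels class labels.
#' @return Mean overlap fraction in [0, 1].
#' @export
class_overlap_fraction <- function(table, labels = table$label) {
  model <- fit_discretizer(table, labels)
  fr <- vapply(model$model, function(m) {
    glo <- m$global[1]; ghi <- m$global[2]
    if (ghi <= glo) return(0)
    r <- m$class_ranges
    segs <- c(glo, m$breakpoints, ghi)
    mid <- (segs[-length(segs)] + segs[-1]) / 2
    len <- diff(segs)
    covered <- vapply(mid, function(x)
      sum(r[, "lo"] <= x & x <= r[, "hi"]) >= 2, TRUE)
    sum(len[covered]) / (ghi - glo)
  }, 0)
  mean(fr)
}
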