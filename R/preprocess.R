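# Metadata columns carried through feature tables.
META_COLS <- c("sample_id", "label", "environment")

feature_columns <- function(table) setdiff(names(table), META_COLS)

#' Baseline-correct a raw record to relative-conductivity responses
#'
#' Converts raw resistances to the dimensionless response
#' \eqn{x_t(i) = R_{air}(i) / R_S(i, t) = G(i,t) / G_0(i)}, where
#' \eqn{R_{air}(i)} is the arithmetic mean of sensor i's resistance over the
#' 60 s clean-air pre-clean window and \eqn{R_S(i,t)} its resistance at time
#' t in the sample gas. Expressing the signal relative to clean air cancels
#' part of the sensors' long-term drift.
#'
#' @param record an \code{enose_record}.
#' @return An \code{enose_response}: list with \code{sample_id},
#'   \code{class_label}, \code{environment} and \code{x}, a 12 x 180 matrix
#'   of responses.
#' @export
baseline_correct <- function(record) {
  stopifnot(inherits(record, "enose_record"))
  if (ncol(record$preclean) < 1L)
    stop("record ", record$sample_id, ": empty pre-clean window")
  if (any(record$preclean <= 0) || any(record$resistance <= 0))
    stop("record ", record$sample_id,
         ": non-positive resistance, rejecting record")
  r_air <- rowMeans(record$preclean)
  x <- r_air / record$resistance
  structure(list(sample_id = record$sample_id,
                 class_label = record$class_label,
                 environment = record$environment,
                 r_air = r_air, x = x),
            class = "enose_response")
}

#' Fit a min-max feature normalizer
#'
#' Records the column-wise minimum and maximum of the fitting set (training
#' data only, to avoid leaking test information into the scaling).
#'
#' @param table a feature table (data.frame with metadata columns
#'   \code{sample_id}, \code{label}, \code{environment} plus numeric feature
#'   columns).
#' @return An \code{enose_normalizer} with per-feature \code{f_min},
#'   \code{f_max}; degenerate columns (max == min) are flagged.
#' @export
fit_normalizer <- function(table) {
  feats <- feature_columns(table)
  if (nrow(table) < 2L || length(feats) == 0L)
    stop("need at least 2 samples and 1 feature to fit a normalizer")
  m <- as.matrix(table[feats])
  f_min <- apply(m, 2, min)
  f_max <- apply(m, 2, max)
  degenerate <- f_max <= f_min
  if (any(degenerate))
    warning("degenerate (constant) feature columns: ",
            paste(feats[degenerate], collapse = ", "))
  structure(list(features = feats, f_min = f_min, f_max = f_max,
                 degenerate = degenerate),
            class = "enose_normalizer")
}

#' Apply a fitted min-max normalizer
#'
#' Maps each feature to \eqn{(F - F_{min}) / (F_{max} - F_{min})}. Values of
#' the fitting set land in [0, 1]; out-of-range values (new data) are clipped
#' to [0, 1]; degenerate columns map to 0.
#'
#' @param table a feature table with the columns the stats were fitted on.
#' @param stats an \code{enose_normalizer}.
#' @return The table with normalized feature columns.
#' @export
apply_normalizer <- function(table, stats) {
  stopifnot(inherits(stats, "enose_normalizer"))
  feats <- feature_columns(table)
  if (!setequal(feats, stats$features))
    stop("feature columns do not match the fitted normalizer")
  for (f in stats$features) {
    rng <- stats$f_max[f] - stats$f_min[f]
    table[[f]] <- if (rng <= 0) rep(0, nrow(table)) else
      pmin(1, pmax(0, (table[[f]] - stats$f_min[f]) / rng))
  }
  table
}
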