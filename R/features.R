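#' First-peak index of a response curve
#'
#' Returns the earliest index within the injection window at which the series
#' attains its maximum over that window (ties broken by the earliest index;
#' a flat series therefore returns 1). Indices are 1-based positions in the
#' recorded series, whose first point is the first second of injection.
#'
#' @param x numeric response series.
#' @param t_b last index of the injection window (default 90, i.e. 90 s at
#'   1 Hz).
#' @return Integer index \code{T_a} with \code{1 <= T_a <= t_b}.
#' @export
detect_first_peak <- function(x, t_b = INJECT_LEN) {
  if (length(x) == 0L) stop("empty series")
  t_b <- min(as.integer(t_b), length(x))
  w <- x[seq_len(t_b)]
  which.max(w) # earliest index attaining the max
}

#' Curve features of one sensor's response
#'
#' Computes the 12 per-sensor features used by the pipeline, 7 in the time
#' domain and 5 in the frequency domain, from the baseline-corrected response
#' \code{x}:
#' \itemize{
#' \item F1 mean response over the whole record;
#' \item F2 maximum response;
#' \item F3 area (sum) over the injection window;
#' \item F4 mean over the stable window \code{[T_a, T_b]}, where \code{T_a}
#'   is the first-peak index and \code{T_b} the end of injection;
#' \item F5 maximum first difference (1 s sampling, forward differences);
#' \item F6 mean first difference;
#' \item F7 maximum second difference;
#' \item F8..F12 the five largest one-sided magnitude-spectrum amplitudes of
#'   the discrete Fourier transform (length-180 transform, DC bin excluded,
#'   unnormalized, sorted descending).
#' }
#'
#' @param x numeric response series (length 180 at 1 Hz by default).
#' @param t_b last index of the injection window (default 90).
#' @return Named numeric vector \code{F1..F12}.
#' @export
#' @examples
#' extract_sensor_features(rep(1, 180))
extract_sensor_features <- function(x, t_b = INJECT_LEN) {
  if (anyNA(x)) stop("series contains NA")
  n <- length(x)
  t_b <- min(as.integer(t_b), n)
  t_a <- detect_first_peak(x, t_b)
  d1 <- diff(x)       # delta t = 1 s
  d2 <- diff(x, differences = 2)
  spec <- Mod(stats::fft(x))[2:(n %/% 2 + 1)] # one-sided, DC excluded
  top5 <- sort(spec, decreasing = TRUE)[1:5]
  c(F1 = mean(x),
    F2 = max(x),
    F3 = sum(x[seq_len(t_b)]),
    F4 = mean(x[t_a:t_b]),
    F5 = if (length(d1)) max(d1) else 0,
    F6 = if (length(d1)) mean(d1) else 0,
    F7 = if (length(d2)) max(d2) else 0,
    F8 = top5[1], F9 = top5[2], F10 = top5[3], F11 = top5[4], F12 = top5[5])
}

#' Feature table of a dataset
#'
#' Applies \code{\link{extract_sensor_features}} to every sensor of every
#' baseline-corrected record, yielding one row per sample with 12 x 12 = 144
#' named feature columns ("S1_F1" .. "S12_F12") plus the metadata columns.
#'
#' @param responses list of \code{enose_response} objects (or
#'   \code{enose_record}s, which are baseline-corrected on the fly).
#' @param t_b injection-window end index.
#' @return A data.frame feature table.
#' @export
extract_features <- function(responses, t_b = INJECT_LEN) {
  stopifnot(length(responses) >= 1L)
  responses <- lapply(responses, function(r) {
    if (inherits(r, "enose_record")) baseline_correct(r) else r
  })
  shapes <- vapply(responses, function(r) paste(dim(r$x), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent response shapes: ", paste(unique(shapes), collapse = ", "))
  sensors <- rownames(responses[[1L]]$x)
  rows <- lapply(responses, function(r) {
    v <- unlist(lapply(sensors, function(s) extract_sensor_features(r$x[s, ], t_b)))
    names(v) <- as.vector(t(outer(sensors, paste0("F", 1:12), paste, sep = "_")))
    v
  })
  m <- do.call(rbind, rows)
  out <- data.frame(
    sample_id = vapply(responses, `[[`, "", "sample_id"),
    label = vapply(responses, `[[`, "", "class_label"),
    environment = vapply(responses, `[[`, "", "environment"),
    m, stringsAsFactors = FALSE, check.names = FALSE
  )
  rownames(out) <- NULL
  out
}
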