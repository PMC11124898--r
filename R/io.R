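#' Write records to long-format CSV
#'
#' Writes two UTF-8 CSV files: \code{records.csv} with columns
#' \code{sample_id,label,environment,sensor,t,resistance} — pre-clean
#' clean-air points at \code{t = -60..-1}, recorded points at
#' \code{t = 0..179} — and the companion \code{baseline.csv} with
#' \code{sample_id,sensor,mean_preclean_resistance}.
#'
#' @param records list of \code{enose_record}s.
#' @param dir output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_records <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(records, function(r) {
    sensors <- rownames(r$resistance)
    rbind(
      data.frame(sample_id = r$sample_id, label = r$class_label,
                 environment = r$environment,
                 sensor = rep(sensors, each = ncol(r$preclean)),
                 t = rep(seq_len(ncol(r$preclean)) - ncol(r$preclean) - 1L,
                         times = length(sensors)),
                 resistance = as.vector(t(r$preclean))),
      data.frame(sample_id = r$sample_id, label = r$class_label,
                 environment = r$environment,
                 sensor = rep(sensors, each = ncol(r$resistance)),
                 t = rep(seq_len(ncol(r$resistance)) - 1L,
                         times = length(sensors)),
                 resistance = as.vector(t(r$resistance)))
    )
  }))
  base <- do.call(rbind, lapply(records, function(r)
    data.frame(sample_id = r$sample_id, sensor = rownames(r$preclean),
               mean_preclean_resistance = rowMeans(r$preclean))))
  rec_path <- file.path(dir, "records.csv")
  base_path <- file.path(dir, "baseline.csv")
  utils::write.csv(long, rec_path, row.names = FALSE)
  utils::write.csv(base, base_path, row.names = FALSE)
  invisible(c(records = rec_path, baseline = base_path))
}

#' Read records from long-format CSV
#'
#' Reads the dialect written by \code{\link{write_records}}. Every sample
#' must provide 12 sensors x 180 recorded points; malformed samples are
#' rejected with their sample_id. If pre-clean rows (negative \code{t}) are
#' absent, a constant 60-point clean-air window is reconstructed from the
#' baseline companion file.
#'
#' @param dir directory holding \code{records.csv} and \code{baseline.csv}.
#' @return List of \code{enose_record}s (empty, with a warning, for an empty
#'   file).
#' @export
read_records <- function(dir) {
  rec_path <- file.path(dir, "records.csv")
  base_path <- file.path(dir, "baseline.csv")
  if (!file.exists(rec_path)) stop("missing ", rec_path)
  long <- tryCatch(utils::read.csv(rec_path, stringsAsFactors = FALSE),
                   error = function(e) NULL)
  if (is.null(long) || nrow(long) == 0L) {
    warning("empty records file: ", rec_path)
    return(list())
  }
  need <- c("sample_id", "label", "environment", "sensor", "t", "resistance")
  if (!all(need %in% names(long)))
    stop("records.csv lacks columns: ",
         paste(setdiff(need, names(long)), collapse = ", "))
  baseline <- if (file.exists(base_path))
    utils::read.csv(base_path, stringsAsFactors = FALSE) else NULL
  sensors <- sensor_specs()$sensor_id
  out <- lapply(split(long, long$sample_id), function(d) {
    id <- d$sample_id[1L]
    rec <- d[d$t >= 0, ]
    pre <- d[d$t < 0, ]
    got <- table(factor(rec$sensor, levels = sensors))
    if (length(unique(rec$sensor)) != 12L || any(got != 180L))
      stop("sample ", id, ": expected 12 sensors x 180 recorded points, got ",
           paste(range(got), collapse = "-"))
    resistance <- matrix(0, 12, 180, dimnames = list(sensors, NULL))
    for (s in sensors) {
      ds <- rec[rec$sensor == s, ]
      resistance[s, ] <- ds$resistance[order(ds$t)]
    }
    if (nrow(pre) > 0L) {
      preclean <- matrix(0, 12, 60, dimnames = list(sensors, NULL))
      for (s in sensors) {
        ds <- pre[pre$sensor == s, ]
        if (nrow(ds) != 60L)
          stop("sample ", id, ": expected 60 pre-clean points for ", s)
        preclean[s, ] <- ds$resistance[order(ds$t)]
      }
    } else {
      if (is.null(baseline)) stop("sample ", id,
        ": no pre-clean rows and no baseline companion file")
      bm <- baseline[baseline$sample_id == id, ]
      mp <- bm$mean_preclean_resistance[match(sensors, bm$sensor)]
      if (anyNA(mp)) stop("sample ", id, ": baseline file incomplete")
      preclean <- matrix(rep(mp, 60), 12, 60, dimnames = list(sensors, NULL))
    }
    structure(list(sample_id = id, class_label = d$label[1L],
                   environment = d$environment[1L],
                   preclean = preclean, resistance = resistance),
              class = "enose_record")
  })
  ids <- unique(long$sample_id)
  out <- out[ids] # preserve file order
  attr(out, "labels") <- vapply(out, `[[`, "", "class_label")
  out
}

#' Write a feature table to CSV
#' @param table feature table.
#' @param path output file.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path CSV written by \code{\link{write_feature_table}}.
#' @return Feature table data.frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Serialize a fitted discretizer to JSON
#' @param model an \code{enose_discretizer}.
#' @param path output JSON file.
#' @export
write_discretizer <- function(model, path) {
  stopifnot(inherits(model, "enose_discretizer"))
  obj <- lapply(model$model, function(m)
    list(breakpoints = m$breakpoints, K = m$K, global = m$global,
         class_ranges = as.data.frame(m$class_ranges)))
  # 17 significant digits so breakpoints (which are data values) round-trip
  # exactly; segment membership at the endpoints depends on it
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a discretizer from JSON
#' @param path JSON written by \code{\link{write_discretizer}}.
#' @return An \code{enose_discretizer}.
#' @export
read_discretizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- lapply(obj, function(m) {
    cr <- as.matrix(m$class_ranges)
    list(breakpoints = as.numeric(m$breakpoints %||% numeric(0)),
         K = as.integer(m$K), global = as.numeric(m$global),
         class_ranges = cr)
  })
  structure(list(features = names(model), model = model),
            class = "enose_discretizer")
}
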