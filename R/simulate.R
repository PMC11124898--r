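# Acquisition timing of the instrument: 60 s clean-air pre-clean, 90 s
# headspace injection, 90 s cleaning, all sampled at 1 Hz.
PRECLEAN_LEN <- 60L
INJECT_LEN <- 90L
CLEAN_LEN <- 90L
RECORD_LEN <- INJECT_LEN + CLEAN_LEN # 180 response values per sensor

#' Simulate one sensor-array record
#'
#' Generates the raw resistance trace of the 12-sensor MOS array for a single
#' sample. The relative-conductivity response follows saturating-exponential
#' adsorption toward a class- and sensor-specific peak amplitude during the
#' 90 s injection phase and exponential desorption back to baseline during
#' the 90 s cleaning phase:
#' \deqn{x(t) = 1 + (A - 1)(1 - e^{-t/\tau_r}), \quad t \le 90}
#' \deqn{x(t) = 1 + (x(90) - 1) e^{-(t - 90)/\tau_d}, \quad t > 90}
#' In storage mode a lognormal, class-independent ambient-gas offset is added
#' to the effective amplitude of every sensor (ambient volatiles enter the
#' chamber with the headspace gas, so the offset follows the same kinetics).
#' The trace is converted to resistance through the sensor's clean-air base
#' resistance, so downstream baseline correction is genuinely exercised.
#'
#' @param class_label one of "normal", "slight", "total".
#' @param env an \code{\link{environment_config}} object.
#' @param profiles 12 x 3 peak-amplitude matrix, see
#'   \code{\link{class_profiles}}; defaults to the environment's table.
#' @param seed optional integer; when given the record is a deterministic
#'   function of it.
#' @param sample_id identifier stored in the record.
#' @return An object of class \code{enose_record}: list with
#'   \code{sample_id}, \code{class_label}, \code{environment},
#'   \code{preclean} (12 x 60 resistance matrix) and \code{resistance}
#'   (12 x 180 resistance matrix), rownames S1..S12.
#' @export
#' @examples
#' env <- environment_config("laboratory", noise_free = TRUE)
#' rec <- simulate_record("total", env, seed = 1)
#' dim(rec$resistance)
simulate_record <- function(class_label, env,
                            profiles = class_profiles(env$environment),
                            seed = NULL, sample_id = "sample") {
  check_class_label(class_label)
  stopifnot(inherits(env, "enose_env"))
  if (!is.matrix(profiles) || nrow(profiles) != 12L ||
      !all(CLASS_LABELS %in% colnames(profiles)))
    stop("profiles must be a 12 x 3 matrix covering all three classes")
  if (any(profiles < 1)) stop("peak amplitudes must be >= 1")
  sim <- function() {
    specs <- sensor_specs()
    A <- profiles[, class_label]
    # per-sample biological spread of the peak amplitude (median-preserving)
    if (env$amplitude_cv > 0)
      A <- 1 + (A - 1) * exp(stats::rnorm(12, 0, env$amplitude_cv))
    if (env$ambient_offset_scale > 0) {
      # one ambient level per sample (all sensors breathe the same air),
      # modulated by a per-sensor sensitivity; class-independent
      level <- stats::rlnorm(1, meanlog = log(env$ambient_offset_scale),
                             sdlog = env$ambient_sample_sdlog)
      sens <- stats::rlnorm(12, meanlog = 0,
                            sdlog = env$ambient_sensor_sdlog)
      A <- A + level * sens
    }
    t_in <- seq_len(INJECT_LEN)
    t_cl <- seq_len(CLEAN_LEN)
    x <- matrix(0, 12, RECORD_LEN)
    for (s in 1:12) {
      rise <- 1 + (A[s] - 1) * (1 - exp(-t_in / env$rise_tau))
      x90 <- rise[INJECT_LEN]
      fall <- 1 + (x90 - 1) * exp(-t_cl / env$decay_tau)
      x[s, ] <- c(rise, fall)
    }
    if (env$drift_rate != 0)
      x <- x + matrix(env$drift_rate * (PRECLEAN_LEN + seq_len(RECORD_LEN)),
                      12, RECORD_LEN, byrow = TRUE)
    if (env$noise_sd > 0)
      x <- x + matrix(stats::rnorm(12 * RECORD_LEN, 0, env$noise_sd),
                      12, RECORD_LEN)
    # a MOS response cannot drop appreciably below clean-air conductivity
    x <- pmax(x, 1 - 3 * env$noise_sd, 0.05)
    base <- specs$base_resistance
    g0 <- matrix(1, 12, PRECLEAN_LEN)
    if (env$drift_rate != 0)
      g0 <- g0 + matrix(env$drift_rate * seq_len(PRECLEAN_LEN),
                        12, PRECLEAN_LEN, byrow = TRUE)
    if (env$noise_sd > 0)
      g0 <- g0 + matrix(stats::rnorm(12 * PRECLEAN_LEN, 0, env$noise_sd / 2),
                        12, PRECLEAN_LEN)
    g0 <- pmax(g0, 0.05)
    preclean <- base / g0
    resistance <- base / x
    rownames(preclean) <- rownames(resistance) <- specs$sensor_id
    structure(list(sample_id = sample_id, class_label = class_label,
                   environment = env$environment,
                   preclean = preclean, resistance = resistance),
              class = "enose_record")
  }
  if (is.null(seed)) sim() else with_seed(seed, sim())
}

#' @export
print.enose_record <- function(x, ...) {
  cat("E-nose record", x$sample_id, "-", x$class_label,
      paste0("(", x$environment, ")"), "\n",
      " 12 sensors x", ncol(x$resistance), "points +",
      ncol(x$preclean), "pre-clean points\n")
  invisible(x)
}

#' Simulate a balanced labelled dataset
#'
#' Generates \code{3 * n_per_class} records, balanced over the three rot
#' classes and deterministically shuffled by \code{seed}. Each record is
#' itself a deterministic function of the root seed, so two calls with the
#' same arguments are identical.
#'
#' @param n_per_class samples per class (default 100, the study size of
#'   300 samples per environment).
#' @param env an \code{\link{environment_config}}.
#' @param seed root integer seed.
#' @param profiles optional amplitude matrix passed to
#'   \code{\link{simulate_record}}.
#' @return A list of \code{enose_record} objects with a
#'   \code{"labels"} attribute.
#' @export
simulate_dataset <- function(n_per_class = 100, env = environment_config(),
                             seed = 1, profiles = class_profiles(env$environment)) {
  if (!is.numeric(n_per_class) || n_per_class < 1)
    stop("n_per_class must be >= 1")
  n_per_class <- as.integer(n_per_class)
  labels <- rep(CLASS_LABELS, each = n_per_class)
  ids <- sprintf("%s-%s-%03d", substr(env$environment, 1, 4),
                 labels, rep(seq_len(n_per_class), times = 3))
  records <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    records[[i]] <- simulate_record(
      labels[i], env, profiles = profiles,
      seed = substream_seed(seed, paste0("record-", ids[i])),
      sample_id = ids[i])
  }
  ord <- with_seed(substream_seed(seed, "shuffle"),
                   sample.int(length(records)))
  records <- records[ord]
  attr(records, "labels") <- vapply(records, `[[`, "", "class_label")
  records
}
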