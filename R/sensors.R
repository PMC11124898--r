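#' Default MOS sensor array specification
#'
#' The 12-sensor metal-oxide array used throughout the package: sensor ids
#' S1..S12, commercial model names, the gas families each model mainly
#' responds to, and a nominal clean-air base resistance in ohms. The base
#' resistance only sets the scale of simulated raw resistances; the
#' relative-conductivity response is independent of it.
#'
#' @return A data.frame with columns \code{sensor_id}, \code{name},
#'   \code{target_note}, \code{base_resistance}.
#' @export
#' @examples
#' sensor_specs()
sensor_specs <- function() {
  data.frame(
    sensor_id = paste0("S", 1:12),
    name = c("MQ8", "TGS2600", "TGS2602", "MQ135", "TGS2603", "TGS2609",
             "MQ136", "TGS2611", "TGS2620", "MQ138", "TGS2610", "TGS2612"),
    target_note = c(
      "hydrogen",
      "hydrogen, ethanol, methane, isobutane",
      "ammonia and hydrogen sulfide",
      "ammonia, hydrogen sulfide, benzene",
      "ethanol, trimethylamine, hydrogen sulfide",
      "hydrogen, carbon monoxide",
      "hydrogen sulfide",
      "methane",
      "organic solvent vapours, alcohol, methanol",
      "methylbenzene, acetone, ethanol, methanal",
      "propane, butane",
      "methane, propane, butane"),
    base_resistance = c(10000, 22000, 18000, 15000, 20000, 25000,
                        12000, 30000, 16000, 14000, 35000, 33000),
    stringsAsFactors = FALSE
  )
}

#' Default class peak-amplitude profiles
#'
#' Per-sensor peak relative-conductivity amplitudes (dimensionless, >= 1)
#' for the three rot classes, per environment. Amplitude 1 means no response.
#' Laboratory S4 and S5 rows and the storage S8 row carry the reported peak
#' values of the instrument; the remaining sensors follow the qualitative
#' selectivity pattern of the array: strong alcohol sensors (S2, S5, S9)
#' respond to every class, broad-spectrum sensors (S1, S4, S8, S10) respond
#' weakly to normal samples and strongly to rot, the high-detection-limit
#' alkane sensors (S11, S12) and the ammonia/sulfide sensor (S3) respond
#' appreciably only to total rot. Storage amplitudes sit above laboratory
#' ones, most visibly for normal and slightly rotten samples, reflecting the
#' ambient-gas background of a storage facility.
#'
#' @param environment "laboratory" or "storage".
#' @return A 12 x 3 numeric matrix, rownames S1..S12, colnames
#'   \code{c("normal","slight","total")}; each row is non-decreasing.
#' @export
class_profiles <- function(environment = c("laboratory", "storage")) {
  environment <- match.arg(environment)
  lab <- rbind(
    S1  = c(1.08, 1.30, 2.10),
    S2  = c(1.30, 1.60, 2.40),
    S3  = c(1.03, 1.08, 1.90),
    S4  = c(1.11, 1.27, 2.05),
    S5  = c(1.39, 1.73, 2.67),
    S6  = c(1.10, 1.25, 1.80),
    S7  = c(1.05, 1.15, 1.95),
    S8  = c(1.12, 1.33, 2.20),
    S9  = c(1.35, 1.65, 2.50),
    S10 = c(1.10, 1.30, 2.15),
    S11 = c(1.02, 1.06, 1.60),
    S12 = c(1.02, 1.05, 1.55)
  )
  colnames(lab) <- CLASS_LABELS
  if (environment == "laboratory") return(lab)
  # Storage: responses elevated by background gases, strongly for normal and
  # slightly rotten samples, mildly for totally rotten ones whose own
  # volatiles already dominate the sensor surface.
  elev <- cbind(normal = rep(0.45, 12), slight = rep(0.55, 12),
                total = rep(0.65, 12))
  st <- lab + elev
  st["S8", ] <- c(1.71, 2.01, 3.03)
  st
}

#' Environment configuration for the simulator
#'
#' Bundles the disturbance model of an acquisition environment: the scale of
#' the class-independent ambient-gas conductivity offset (lognormal,
#' per sample and sensor), the standard deviation of additive measurement
#' noise on the response, and a slow linear baseline drift rate. Storage mode
#' has a strictly larger ambient offset scale and noise than laboratory mode.
#'
#' @param environment "laboratory" or "storage".
#' @param ambient_offset_scale median of the lognormal ambient conductivity
#'   offset added to the response (dimensionless, >= 0).
#' @param ambient_sample_sdlog lognormal sdlog of the shared per-sample
#'   ambient level (its tail width controls how scattered samples become).
#' @param ambient_sensor_sdlog lognormal sdlog of the per-sensor sensitivity
#'   to the ambient level.
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   response (dimensionless, >= 0).
#' @param drift_rate linear conductivity drift per second (can be 0).
#' @param amplitude_cv coefficient of variation of the per-sample peak
#'   amplitude around its class profile (biological spread between samples).
#' @param rise_tau,decay_tau adsorption and desorption time constants in
#'   seconds (> 0).
#' @param noise_free if TRUE, zero every stochastic disturbance (ambient
#'   offsets, measurement noise, amplitude spread) so records follow the
#'   class-profile kinetics exactly; used for parameter-recovery checks.
#' @return An object of class \code{enose_env}.
#' @export
environment_config <- function(environment = c("laboratory", "storage"),
                               ambient_offset_scale = NULL,
                               ambient_sample_sdlog = 1.0,
                               ambient_sensor_sdlog = 0.3,
                               noise_sd = NULL,
                               drift_rate = 0,
                               amplitude_cv = 0.10,
                               rise_tau = 12,
                               decay_tau = 25,
                               noise_free = FALSE) {
  environment <- match.arg(environment)
  if (noise_free) {
    ambient_offset_scale <- 0
    noise_sd <- 0
    amplitude_cv <- 0
  }
  defaults <- list(
    laboratory = list(ambient = 0.02, noise = 0.01),
    storage    = list(ambient = 0.25, noise = 0.02)
  )[[environment]]
  ambient_offset_scale <- ambient_offset_scale %||% defaults$ambient
  noise_sd <- noise_sd %||% defaults$noise
  stopifnot(ambient_offset_scale >= 0, noise_sd >= 0, is.finite(drift_rate),
            amplitude_cv >= 0)
  if (rise_tau <= 0 || decay_tau <= 0)
    stop("rise_tau and decay_tau must be positive")
  structure(list(environment = environment,
                 ambient_offset_scale = ambient_offset_scale,
                 ambient_sample_sdlog = ambient_sample_sdlog,
                 ambient_sensor_sdlog = ambient_sensor_sdlog,
                 noise_sd = noise_sd,
                 drift_rate = drift_rate,
                 amplitude_cv = amplitude_cv,
                 rise_tau = rise_tau,
                 decay_tau = decay_tau),
            class = "enose_env")
}

#' @export
print.enose_env <- function(x, ...) {
  cat("E-nose environment:", x$environment, "\n",
      " ambient offset scale:", x$ambient_offset_scale,
      " noise sd:", x$noise_sd,
      " drift:", x$drift_rate, "/s\n",
      " amplitude cv:", x$amplitude_cv,
      " rise tau:", x$rise_tau, "s, decay tau:", x$decay_tau, "s\n")
  invisible(x)
}
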