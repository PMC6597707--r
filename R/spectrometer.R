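#' Idealized ion-momentum spectrometer configuration
#'
#' Single uniform-field extraction region of a COLTRIMS-style ion arm: a
#' static field over one acceleration length pushes ions onto a
#' position-sensitive detector. No drift tube, lens or magnetic field.
#'
#' @param extraction_field_Vm extraction field (V/m), > 0.
#' @param acceleration_length_m field-region length (m), > 0.
#' @param detector_radius_mm active detector radius (mm), > 0.
#' @param t0_ns time-of-flight offset (ns).
#' @return list of class `cei_spectrometer`.
#' @export
spectrometer_config <- function(extraction_field_Vm = 2000,
                                acceleration_length_m = 0.10,
                                detector_radius_mm = 60,
                                t0_ns = 0) {
  stopifnot(extraction_field_Vm > 0, acceleration_length_m > 0,
            detector_radius_mm > 0)
  structure(list(extraction_field_Vm = extraction_field_Vm,
                 acceleration_length_m = acceleration_length_m,
                 detector_radius_mm = detector_radius_mm,
                 t0_ns = t0_ns),
            class = "cei_spectrometer")
}

.si_motion <- function(species, config) {
  u <- unit_system()
  sp <- species_lookup(species)
  m <- sp$mass * u$amu_kg                                    # kg
  a <- sp$charge * u$elementary_charge_C *
    config$extraction_field_Vm / m                           # m/s^2
  list(m_kg = m, a = a, p_si = u$au_momentum_si)
}

#' Map a fragment momentum to a detector hit
#'
#' The axial time of flight solves L = (p_z/m) t + (q E / 2 m) t^2 with the
#' detector axis (z) positive toward the detector; transverse position is
#' ballistic: x = (p_x/m) t. Hits landing beyond the detector radius are
#' retained but flagged out-of-acceptance.
#'
#' @param momentum 3-vector or n x 3 matrix of momenta (a.u.).
#' @param species species label (scalar or length n).
#' @param config a `cei_spectrometer`.
#' @return data.frame: `tof_ns`, `x_mm`, `y_mm`, `species`,
#'   `in_acceptance`.
#' @export
forward_model <- function(momentum, species, config = spectrometer_config()) {
  momentum <- rbind(momentum)
  n <- nrow(momentum)
  species <- rep_len(species, n)
  out <- vector("list", length(unique(species)))
  tof <- x <- y <- numeric(n)
  for (sp in unique(species)) {
    i <- which(species == sp)
    mo <- .si_motion(sp, config)
    vz <- momentum[i, 3] * mo$p_si / mo$m_kg                 # m/s
    # positive root of L = vz t + a t^2 / 2
    t <- (-vz + sqrt(vz^2 + 2 * mo$a * config$acceleration_length_m)) / mo$a
    if (any(t > 1e-4)) stop("time of flight exceeds 100 microseconds")
    tof[i] <- t * 1e9 + config$t0_ns
    x[i] <- momentum[i, 1] * mo$p_si / mo$m_kg * t * 1e3     # mm
    y[i] <- momentum[i, 2] * mo$p_si / mo$m_kg * t * 1e3
  }
  data.frame(tof_ns = tof, x_mm = x, y_mm = y, species = species,
             in_acceptance = sqrt(x^2 + y^2) <= config$detector_radius_mm,
             stringsAsFactors = FALSE)
}

#' Reconstruct a momentum vector from a detector hit
#'
#' Algebraic inverse of [forward_model()] under a species (mass/charge)
#' hypothesis: p_z = m L / t' - q E t' / 2, p_x = m x / t', p_y = m y / t'
#' with t' = tof - t0.
#'
#' @param tof_ns time of flight (ns), vectorized.
#' @param x_mm,y_mm detector position (mm), vectorized.
#' @param species species hypothesis (scalar or vector).
#' @param config a `cei_spectrometer`.
#' @return n x 3 matrix of momenta (a.u.).
#' @export
reconstruct_momentum <- function(tof_ns, x_mm, y_mm, species,
                                 config = spectrometer_config()) {
  n <- length(tof_ns)
  species <- rep_len(species, n)
  tp <- (tof_ns - config$t0_ns) * 1e-9
  if (any(tp <= 0)) stop("time of flight must exceed t0")
  p <- matrix(NA_real_, n, 3)
  for (sp in unique(species)) {
    i <- which(species == sp)
    mo <- .si_motion(sp, config)
    vz <- config$acceleration_length_m / tp[i] - mo$a * tp[i] / 2
    p[i, 1] <- mo$m_kg * (x_mm[i] * 1e-3 / tp[i]) / mo$p_si
    p[i, 2] <- mo$m_kg * (y_mm[i] * 1e-3 / tp[i]) / mo$p_si
    p[i, 3] <- mo$m_kg * vz / mo$p_si
  }
  p
}

#' Time of flight of an ion at rest
#'
#' Closed form t0 + sqrt(2 L m / (q E)); the anchor of the per-species TOF
#' windows and of the PIPICO map's channel islands.
#'
#' @param species species label (vectorized).
#' @param config a `cei_spectrometer`.
#' @return TOF (ns).
#' @export
tof_at_rest <- function(species, config = spectrometer_config()) {
  vapply(species, function(sp) {
    mo <- .si_motion(sp, config)
    sqrt(2 * config$acceleration_length_m / mo$a) * 1e9 + config$t0_ns
  }, 0)
}
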