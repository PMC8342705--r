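# Lightweight S3 containers for the oscillator model. All internal
# frequencies are angular (rad/s); user-facing fields that are cyclic are
# suffixed _hz. The two conventions are never mixed silently.

#' Define a molecular species
#'
#' A species carries the per-molecule physical parameters of the oscillator:
#' net charge Q, molecular mass M, a literature dipole moment (debye) used
#' as the damping-calibration target, and optionally a damping constant
#' `gamma` (rad/s equivalent, per second). Inert species (e.g. ZnO
#' particles, with near-zero net charge and much higher mass than the
#' proteins) are flagged so mixture rules can exclude them.
#'
#' @param name Species label.
#' @param charge_Q Net charge per molecule, coulombs; > 0.
#' @param mass_M Mass per molecule, kilograms; > 0.
#' @param dipole_lit Literature dipole moment, debye; > 0. May be `NA` for
#'   inert species.
#' @param gamma Optional damping constant, 1/s; set by
#'   [calibrate_damping()] when absent.
#' @param inert Logical; `TRUE` excludes the species from oscillator
#'   strength (and, by default policy, damping) mixture sums.
#' @return An object of class `molecular_species`.
#' @examples
#' insulin <- molecular_species("insulin", 74.805e-10, 9.52e-18, 369)
#' @export
molecular_species <- function(name, charge_Q, mass_M, dipole_lit = NA_real_,
                              gamma = NULL, inert = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!inert) {
    stopifnot(is.numeric(charge_Q), charge_Q > 0,
              is.numeric(mass_M), mass_M > 0)
    if (!is.na(dipole_lit)) stopifnot(dipole_lit > 0)
  }
  if (!is.null(gamma)) stopifnot(is.numeric(gamma), gamma > 0)
  structure(
    list(name = name, charge_Q = charge_Q, mass_M = mass_M,
         dipole_lit = dipole_lit, gamma = gamma, inert = isTRUE(inert)),
    class = "molecular_species"
  )
}

#' @export
print.molecular_species <- function(x, ...) {
  cat(sprintf("<molecular_species> %s%s\n", x$name,
              if (x$inert) " (inert)" else ""))
  cat(sprintf("  Q = %.6g C, M = %.6g kg, dipole_lit = %s D, gamma = %s 1/s\n",
              x$charge_Q, x$mass_M,
              if (is.na(x$dipole_lit)) "NA" else format(x$dipole_lit),
              if (is.null(x$gamma)) "<uncalibrated>" else format(x$gamma)))
  invisible(x)
}

#' Define the driving-field configuration
#'
#' The probe antenna drives the sample at a fixed microwave frequency. The
#' study conditions are 6.41 GHz, field amplitude 4.9 V/m, and responses
#' evaluated at t = 1 microsecond (close to the protein relaxation time).
#'
#' @param drive_frequency_hz Cyclic drive frequency, Hz; > 0.
#' @param field_amplitude_E0 Electric-field amplitude, V/m; > 0.
#' @param eval_time_t Evaluation time for time-dependent responses, seconds.
#' @return An object of class `field_config` with the derived angular
#'   frequency `drive_omega = 2 * pi * drive_frequency_hz` (rad/s).
#' @examples
#' field_config()  # the study's probe settings
#' @export
field_config <- function(drive_frequency_hz = 6.41e9,
                         field_amplitude_E0 = 4.9,
                         eval_time_t = 1e-6) {
  stopifnot(is.numeric(drive_frequency_hz), drive_frequency_hz > 0,
            is.numeric(field_amplitude_E0), field_amplitude_E0 > 0,
            is.numeric(eval_time_t), is.finite(eval_time_t))
  structure(
    list(drive_frequency_hz = drive_frequency_hz,
         drive_omega = 2 * pi * drive_frequency_hz,
         field_amplitude_E0 = field_amplitude_E0,
         eval_time_t = eval_time_t),
    class = "field_config"
  )
}

#' @export
print.field_config <- function(x, ...) {
  cat(sprintf("<field_config> f = %.6g Hz (omega = %.6g rad/s), E0 = %.3g V/m, t = %.3g s\n",
              x$drive_frequency_hz, x$drive_omega, x$field_amplitude_E0,
              x$eval_time_t))
  invisible(x)
}

#' Define an oscillator ensemble
#'
#' The ensemble aggregates the N molecules of a sample into the quantities
#' the model equations need: the oscillator strength S = N Q^2 / M
#' (summed over non-inert components for mixtures), the effective damping
#' constant, and the molecule count (used to express per-molecule
#' quantities).
#'
#' @param n_molecules_N Number of (non-inert) molecules; > 0.
#' @param strength_NQ2_over_M Aggregate N Q^2 / M, C^2/kg; > 0.
#' @param gamma_eff Effective damping constant, 1/s; > 0.
#' @return An object of class `oscillator_ensemble`.
#' @export
oscillator_ensemble <- function(n_molecules_N, strength_NQ2_over_M, gamma_eff) {
  stopifnot(is.numeric(n_molecules_N), n_molecules_N > 0,
            is.numeric(strength_NQ2_over_M), strength_NQ2_over_M > 0,
            is.numeric(gamma_eff), gamma_eff > 0)
  structure(
    list(n_molecules_N = n_molecules_N,
         strength_NQ2_over_M = strength_NQ2_over_M,
         gamma_eff = gamma_eff),
    class = "oscillator_ensemble"
  )
}

#' @export
print.oscillator_ensemble <- function(x, ...) {
  cat(sprintf("<oscillator_ensemble> N = %.6g, S = N Q^2/M = %.6g C^2/kg, gamma_eff = %.6g 1/s\n",
              x$n_molecules_N, x$strength_NQ2_over_M, x$gamma_eff))
  invisible(x)
}

#' Build an ensemble for a pure species
#'
#' Convenience wrapper combining [estimate_molecule_count()] with the
#' species constants. The species must already carry a damping constant
#' unless `gamma` is supplied.
#'
#' @param species A [molecular_species()].
#' @param concentration Mass concentration, kg/L.
#' @param volume Sample volume, litres.
#' @param gamma Damping constant override, 1/s.
#' @return An [oscillator_ensemble()].
#' @export
pure_ensemble <- function(species, concentration, volume, gamma = species$gamma) {
  stopifnot(inherits(species, "molecular_species"), !species$inert)
  if (is.null(gamma)) {
    stop("species '", species$name,
         "' has no damping constant; calibrate first or pass `gamma`")
  }
  N <- estimate_molecule_count(concentration, volume, species$mass_M)
  oscillator_ensemble(N, N * species$charge_Q^2 / species$mass_M, gamma)
}
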