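# Per-sample, per-temperature orchestration: replicate averaging, one-off
# damping calibration per pure species, mixture rules, natural-frequency
# inversion, and the relative-change (radar) summary against a reference
# sample.

.coolest_pure_reference <- function(registry, avg) {
  # for each non-inert species: the pure sample and coolest temperature
  # used for damping calibration (first registry sample wins ties)
  out <- list()
  for (sid in names(registry$samples)) {
    comp <- registry$samples[[sid]]$components
    if (nrow(comp) != 1L) next
    spn <- comp$species[1L]
    if (registry$species[[spn]]$inert || spn %in% names(out)) next
    rows <- avg[avg$sample_id == sid & avg$mean > 1, , drop = FALSE]
    if (!nrow(rows)) next
    coolest <- rows[which.min(rows$temperature_C), , drop = FALSE]
    out[[spn]] <- list(sample_id = sid,
                       temperature_C = coolest$temperature_C,
                       epsilon_r = coolest$mean)
  }
  out
}

#' Run the thermal sweep analysis
#'
#' End-to-end model inversion for every (sample, temperature) in a
#' measurement table: averages replicate runs, calibrates the damping
#' constant once per pure species at its coolest measured temperature
#' (species with a registry-fixed `gamma_per_s` skip calibration),
#' applies the mixture rules for multi-component samples, inverts the
#' permittivity model for the natural frequency, and evaluates the
#' per-molecule dipole amplitude and polarization current density at the
#' configured evaluation time. Deterministic given its inputs; input row
#' order is immaterial.
#'
#' Rows with mean permittivity <= 1 cannot be inverted and are skipped
#' with a logged diagnostic (attribute `skipped`), never silently.
#' Non-real natural-frequency roots are reported flagged, with the
#' complex-pair modulus in `f0_hz` columns.
#'
#' @param registry A [corona_registry()].
#' @param measurements Measurement records ([read_measurements()] schema);
#'   every `sample_id` must be declared in the registry.
#' @param field A [field_config()]; defaults to the registry's.
#' @param mode Inversion dialect, `"consistent"` (default) or
#'   `"as_printed"` (audit; not round-trippable).
#' @param recalibrate_per_temperature Logical; if `TRUE`, pure samples are
#'   recalibrated at every temperature instead of once at the coolest.
#' @param include_inert_damping Passed to [build_ensemble()].
#' @return A data.frame with one row per (sample, temperature): mean and
#'   spread of the permittivity, both natural-frequency roots in Hz
#'   (modulus for complex roots) with reality flags, the selected root,
#'   per-molecule dipole (C m), polarization current density amplitude
#'   (A/m^2), effective damping, the relative residual of substituting the
#'   selected root back into the forward model, and a diagnostics string.
#'   Attributes:
#'   `solutions` (the full `oscillator_solution` objects),
#'   `calibrations` (per-species [calibrate_damping()] results),
#'   `skipped` (diagnostics for non-invertible rows).
#' @export
run_sweep <- function(registry, measurements, field = registry$field,
                      mode = c("consistent", "as_printed"),
                      recalibrate_per_temperature = FALSE,
                      include_inert_damping = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(registry, "corona_registry"), is.data.frame(measurements))
  empty <- data.frame(
    sample_id = character(0), temperature_C = numeric(0),
    epsilon_r_mean = numeric(0), epsilon_r_spread = numeric(0),
    n_runs = integer(0), f0_hz_1 = numeric(0), f0_hz_2 = numeric(0),
    root_real_1 = logical(0), root_real_2 = logical(0),
    f0_hz_selected = numeric(0), selected_real = logical(0),
    dipole_per_molecule_Cm = numeric(0), jp_amplitude_A_m2 = numeric(0),
    gamma_eff = numeric(0), roundtrip_rel_residual = numeric(0),
    diagnostics = character(0),
    stringsAsFactors = FALSE)
  if (nrow(measurements) == 0L) return(empty)

  unknown <- setdiff(unique(measurements$sample_id), names(registry$samples))
  if (length(unknown)) {
    stop("measurement rows reference unknown sample(s): ",
         paste(unknown, collapse = ", "))
  }
  avg <- average_runs(measurements)
  skipped <- avg[avg$mean <= 1, , drop = FALSE]
  if (nrow(skipped)) {
    message("skipping ", nrow(skipped),
            " (sample, temperature) group(s) with mean epsilon_r <= 1: ",
            paste(sprintf("%s@%g", skipped$sample_id, skipped$temperature_C),
                  collapse = ", "))
  }
  avg <- avg[avg$mean > 1, , drop = FALSE]

  # damping constants: registry-fixed, else calibrated at the coolest
  # temperature of a pure sample of the species
  species <- registry$species
  calib <- list()
  need <- unique(unlist(lapply(registry$samples[unique(avg$sample_id)],
                               function(s) s$components$species)))
  need <- need[!vapply(species[need], `[[`, logical(1), "inert")]
  anchors <- .coolest_pure_reference(registry, avg)
  for (spn in need) {
    if (!is.null(species[[spn]]$gamma)) next
    if (is.null(anchors[[spn]])) {
      stop("species '", spn, "' has no fixed damping constant and no pure ",
           "sample with invertible measurements to calibrate against")
    }
    a <- anchors[[spn]]
    comp <- registry$samples[[a$sample_id]]
    sp <- species[[spn]]
    N <- estimate_molecule_count(comp$components$concentration,
                                 comp$components$volume, sp$mass_M)
    ens0 <- oscillator_ensemble(N, N * sp$charge_Q^2 / sp$mass_M, gamma_eff = 1)
    cal <- calibrate_damping(sp, ens0, field, a$epsilon_r)
    calib[[spn]] <- cal
    species[[spn]]$gamma <- cal$gamma
  }

  rows <- vector("list", nrow(avg))
  solutions <- vector("list", nrow(avg))
  for (i in seq_len(nrow(avg))) {
    sid <- avg$sample_id[i]; tc <- avg$temperature_C[i]
    sp_here <- species
    if (recalibrate_per_temperature) {
      comp <- registry$samples[[sid]]
      if (nrow(comp$components) == 1L) {
        spn <- comp$components$species[1L]
        if (!sp_here[[spn]]$inert && is.null(registry$species[[spn]]$gamma)) {
          sp0 <- registry$species[[spn]]
          N <- estimate_molecule_count(comp$components$concentration,
                                       comp$components$volume, sp0$mass_M)
          ens0 <- oscillator_ensemble(N, N * sp0$charge_Q^2 / sp0$mass_M, 1)
          sp_here[[spn]]$gamma <-
            calibrate_damping(sp0, ens0, field, avg$mean[i])$gamma
        }
      }
    }
    ens <- build_ensemble(registry$samples[[sid]], sp_here,
                          include_inert_damping = include_inert_damping)
    sol <- invert_natural_frequency(ens, field, avg$mean[i], mode = mode)
    solutions[[i]] <- sol
    residual <- tryCatch(
      abs(suppressWarnings(
        forward_permittivity(ens, field, sol$selected_root)) - avg$mean[i]) /
        avg$mean[i],
      error = function(e) NA_real_)
    rows[[i]] <- data.frame(
      sample_id = sid, temperature_C = tc,
      epsilon_r_mean = avg$mean[i], epsilon_r_spread = avg$spread[i],
      n_runs = avg$n_runs[i],
      f0_hz_1 = Mod(sol$omega0_roots[1]) / (2 * pi),
      f0_hz_2 = Mod(sol$omega0_roots[2]) / (2 * pi),
      root_real_1 = sol$root_real[1], root_real_2 = sol$root_real[2],
      f0_hz_selected = sol$f0_hz, selected_real = sol$selected_real,
      dipole_per_molecule_Cm = sol$dipole_per_molecule,
      jp_amplitude_A_m2 = sol$jp_amplitude,
      gamma_eff = ens$gamma_eff,
      roundtrip_rel_residual = residual,
      diagnostics = paste(sol$diagnostics, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ord <- order(out$sample_id, out$temperature_C)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  names(solutions) <- sprintf("%s@%g", avg$sample_id, avg$temperature_C)
  attr(out, "solutions") <- solutions[ord]
  attr(out, "calibrations") <- calib
  attr(out, "skipped") <- skipped
  out
}

.RADAR_QUANTITIES <- c("epsilon_r", "dipole", "jp", "f0", "zeta", "enthalpy")

#' Relative-change summary against a reference sample
#'
#' For each sample, the relative change of each physical parameter with
#' respect to the reference sample (the radar-chart view):
#' \eqn{|x_{sample} - x_{ref}| / |x_{ref}|}, evaluated at a declared
#' comparison temperature for the model-derived quantities (permittivity,
#' per-molecule dipole, polarization current density, natural frequency)
#' and from replicate aggregates for zeta potential and unfolding
#' enthalpy. The reference row is identically zero.
#'
#' Model quantities of rows whose natural-frequency roots are not real
#' (`f0`, `dipole`, `jp`) are excluded (`NA`) by default; the permittivity
#' itself is always compared. Quantities without data are `NA`.
#'
#' @param results A [run_sweep()] result.
#' @param aux Auxiliary records ([read_aux()] schema), or `NULL`.
#' @param reference_id Sample id of the baseline (e.g. pure insulin).
#' @param temperature Comparison temperature, degC (default 30).
#' @return A data.frame with one row per sample and one column per
#'   quantity (`epsilon_r`, `dipole`, `jp`, `f0`, `zeta`, `enthalpy`).
#' @export
radar_summary <- function(results, aux = NULL, reference_id,
                          temperature = 30) {
  stopifnot(is.data.frame(results))
  at_T <- results[results$temperature_C == temperature, , drop = FALSE]
  if (!reference_id %in% at_T$sample_id) {
    stop("reference sample '", reference_id, "' has no sweep result at ",
         temperature, " degC")
  }
  aux_mean <- if (!is.null(aux) && nrow(aux)) average_runs(aux) else NULL

  value_of <- function(sid, what) {
    row <- at_T[at_T$sample_id == sid, , drop = FALSE]
    switch(what,
      epsilon_r = if (nrow(row)) row$epsilon_r_mean else NA_real_,
      dipole = if (nrow(row) && row$selected_real) row$dipole_per_molecule_Cm else NA_real_,
      jp = if (nrow(row) && row$selected_real) row$jp_amplitude_A_m2 else NA_real_,
      f0 = if (nrow(row) && row$selected_real) row$f0_hz_selected else NA_real_,
      zeta = {
        if (is.null(aux_mean)) NA_real_ else {
          m <- aux_mean[aux_mean$sample_id == sid &
                          aux_mean$quantity == "zeta_mV", "mean"]
          if (length(m)) m else NA_real_
        }
      },
      enthalpy = {
        if (is.null(aux_mean)) NA_real_ else {
          m <- aux_mean[aux_mean$sample_id == sid &
                          aux_mean$quantity == "enthalpy_J_per_g_degC", "mean"]
          if (length(m)) m else NA_real_
        }
      })
  }

  sample_ids <- unique(c(reference_id,
                         sort(setdiff(at_T$sample_id, reference_id))))
  ref_vals <- vapply(.RADAR_QUANTITIES, function(q) value_of(reference_id, q),
                     numeric(1))
  zero_ref <- !is.na(ref_vals) & ref_vals == 0
  if (any(zero_ref)) {
    stop("reference quantity value is zero for: ",
         paste(.RADAR_QUANTITIES[zero_ref], collapse = ", "),
         " (relative change undefined)")
  }
  out <- do.call(rbind, lapply(sample_ids, function(sid) {
    vals <- vapply(.RADAR_QUANTITIES, function(q) value_of(sid, q), numeric(1))
    rel <- abs(vals - ref_vals) / abs(ref_vals)
    df <- data.frame(sample_id = sid, t(rel), stringsAsFactors = FALSE)
    names(df) <- c("sample_id", .RADAR_QUANTITIES)
    df
  }))
  rownames(out) <- NULL
  attr(out, "temperature") <- temperature
  attr(out, "reference_id") <- reference_id
  out
}
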