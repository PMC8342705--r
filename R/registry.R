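# Sample registry: a YAML config declaring the driving field, the species
# constants, and the composition of each sample. Config units are the
# bench-friendly ones (GHz, V/m, microseconds, microlitres, mg/ml); they
# are converted to SI on read and back on write.

#' Assemble a sample registry
#'
#' @param field A [field_config()].
#' @param species Named list of [molecular_species()] objects.
#' @param samples Named list of [sample_composition()] objects (names must
#'   match the `sample_id`s).
#' @return An object of class `corona_registry`.
#' @export
corona_registry <- function(field, species, samples) {
  stopifnot(inherits(field, "field_config"),
            is.list(species), length(species) >= 1L,
            all(vapply(species, inherits, logical(1), "molecular_species")),
            is.list(samples),
            all(vapply(samples, inherits, logical(1), "sample_composition")))
  names(species) <- vapply(species, `[[`, character(1), "name")
  names(samples) <- vapply(samples, `[[`, character(1), "sample_id")
  used <- unique(unlist(lapply(samples, function(s) s$components$species)))
  missing <- setdiff(used, names(species))
  if (length(missing)) {
    stop("samples reference undeclared species: ", paste(missing, collapse = ", "))
  }
  refs <- vapply(samples, `[[`, logical(1), "is_reference")
  if (sum(refs) > 1L) stop("more than one reference sample declared")
  structure(list(field = field, species = species, samples = samples),
            class = "corona_registry")
}

#' @export
print.corona_registry <- function(x, ...) {
  cat(sprintf("<corona_registry> %d species, %d samples\n",
              length(x$species), length(x$samples)))
  print(x$field)
  invisible(x)
}

#' Read a sample registry from YAML
#'
#' Expected layout:
#' ```yaml
#' field: {frequency_ghz: 6.41, e0_v_per_m: 4.9, t_us: 1.0}
#' species:
#'   insulin: {charge_q_c: 74.805e-10, mass_m_kg: 9.52e-18,
#'             dipole_debye: 369, inert: false}
#' samples:
#'   I:
#'     reference: true
#'     components:
#'       - {species: insulin, volume_ul: 250, conc_mg_per_ml: 6.9}
#' ```
#' Optional per-species key `gamma_per_s` fixes the damping constant
#' (otherwise it is calibrated by the pipeline).
#'
#' @param path Path to a YAML file.
#' @return A [corona_registry()].
#' @export
read_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("field", "species", "samples")) {
    if (is.null(cfg[[k]])) stop("registry ", path, " lacks section '", k, "'")
  }
  fc <- cfg$field
  field <- field_config(
    drive_frequency_hz = as.numeric(fc$frequency_ghz) * 1e9,
    field_amplitude_E0 = as.numeric(fc$e0_v_per_m),
    eval_time_t = as.numeric(fc$t_us) * 1e-6
  )
  species <- lapply(names(cfg$species), function(nm) {
    s <- cfg$species[[nm]]
    molecular_species(
      name = nm,
      charge_Q = as.numeric(s$charge_q_c),
      mass_M = as.numeric(s$mass_m_kg),
      dipole_lit = if (is.null(s$dipole_debye)) NA_real_ else as.numeric(s$dipole_debye),
      gamma = if (is.null(s$gamma_per_s)) NULL else as.numeric(s$gamma_per_s),
      inert = isTRUE(s$inert)
    )
  })
  names(species) <- names(cfg$species)
  samples <- lapply(names(cfg$samples), function(nm) {
    sm <- cfg$samples[[nm]]
    comps <- sm$components
    if (is.null(comps) || !length(comps)) {
      stop("sample '", nm, "' has no components")
    }
    sample_composition(
      sample_id = nm,
      species = vapply(comps, `[[`, character(1), "species"),
      volume = vapply(comps, function(co) as.numeric(co$volume_ul), numeric(1)) * 1e-6,
      concentration = vapply(comps, function(co) as.numeric(co$conc_mg_per_ml),
                             numeric(1)) * 1e-3,
      is_reference = isTRUE(sm$reference)
    )
  })
  names(samples) <- names(cfg$samples)
  corona_registry(field, species, samples)
}

#' Write a sample registry to YAML
#'
#' Inverse of [read_registry()] (same units in the file).
#'
#' @param registry A [corona_registry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "corona_registry"))
  f <- registry$field
  cfg <- list(
    field = list(frequency_ghz = f$drive_frequency_hz / 1e9,
                 e0_v_per_m = f$field_amplitude_E0,
                 t_us = f$eval_time_t * 1e6),
    species = lapply(registry$species, function(s) {
      out <- list(charge_q_c = s$charge_Q, mass_m_kg = s$mass_M)
      if (!is.na(s$dipole_lit)) out$dipole_debye <- s$dipole_lit
      if (!is.null(s$gamma)) out$gamma_per_s <- s$gamma
      if (s$inert) out$inert <- TRUE
      out
    }),
    samples = lapply(registry$samples, function(sm) {
      comp <- sm$components
      out <- list(components = lapply(seq_len(nrow(comp)), function(i) {
        list(species = comp$species[i],
             volume_ul = comp$volume[i] * 1e6,
             conc_mg_per_ml = comp$concentration[i] * 1e3)
      }))
      if (sm$is_reference) out$reference <- TRUE
      out
    })
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
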