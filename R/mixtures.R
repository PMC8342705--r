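# Mixture rules for multi-component samples: volume-weighted effective
# damping and additive oscillator strength, plus molecule-count estimation
# from concentration and volume. Inert particles (ZnO) carry no oscillator
# strength; by default they are excluded from the damping average too (the
# policy is a flag, not a hard-coded species list).

#' Estimate the number of molecules in a sample component
#'
#' N = concentration x volume / mass per molecule. Real-valued; never
#' rounded. For mixtures each component's N is computed from its own
#' concentration and its own contributed volume (pre-mix mass is
#' conserved).
#'
#' @param concentration Mass concentration, kg/L; > 0.
#' @param volume Volume, litres; > 0.
#' @param mass_M Mass per molecule, kilograms; > 0.
#' @return Number of molecules (dimensionless, real-valued).
#' @examples
#' # insulin: 6.9 mg/ml in a 250 microlitre holder
#' estimate_molecule_count(6.9e-3, 250e-6, 9.52e-18)
#' @export
estimate_molecule_count <- function(concentration, volume, mass_M) {
  stopifnot(is.numeric(concentration), all(concentration > 0),
            is.numeric(volume), all(volume > 0))
  if (any(!is.numeric(mass_M)) || any(mass_M <= 0)) {
    stop("mass_M must be a positive mass per molecule (kg)")
  }
  concentration * volume / mass_M
}

#' Volume-weighted effective damping of a mixture
#'
#' \deqn{\gamma_{mixed} = \sum_i \gamma_i V_i / \sum_i V_i}
#' The published rule is binary; it is extended here to any number of
#' components by the same volume weighting (required for the ternary
#' insulin:papain:ZnO 8:1:4 mixture).
#'
#' @param gammas Component damping constants, 1/s; all > 0.
#' @param volumes Component volumes (any common unit); all > 0.
#' @return Effective damping constant, 1/s. Lies between `min(gammas)`
#'   and `max(gammas)`.
#' @examples
#' mixed_damping(c(10, 21), c(10, 1))  # insulin:papain at 10:1 -> 11
#' @export
mixed_damping <- function(gammas, volumes) {
  if (length(gammas) == 0L) stop("empty component list")
  stopifnot(length(gammas) == length(volumes),
            is.numeric(gammas), all(gammas > 0),
            is.numeric(volumes), all(volumes > 0))
  sum(gammas * volumes) / sum(volumes)
}

#' Additive oscillator strength of a mixture
#'
#' \deqn{S = \sum_i N_i Q_i^2 / M_i} over the non-inert components.
#' Inert components (e.g. ZnO, with near-zero net charge and much higher
#' mass than the proteins) contribute zero by policy.
#'
#' @param N Component molecule counts.
#' @param Q Component charges, C.
#' @param M Component masses, kg.
#' @param inert Logical vector; `TRUE` components are excluded.
#' @return Aggregate oscillator strength, C^2/kg.
#' @export
mixed_strength <- function(N, Q, M, inert = rep(FALSE, length(N))) {
  stopifnot(length(N) == length(Q), length(N) == length(M),
            length(N) == length(inert))
  keep <- !inert
  if (!any(keep)) return(0)
  stopifnot(all(N[keep] > 0), all(Q[keep] > 0), all(M[keep] > 0))
  sum(N[keep] * Q[keep]^2 / M[keep])
}

#' Define a sample composition
#'
#' A pure or mixed sample: its component species with the volume and mass
#' concentration each contributes. Mixing ratios (2:1 insulin:ZnO, 10:1
#' insulin:papain, 8:1:4 insulin:papain:ZnO) are expressed through the
#' component volumes.
#'
#' @param sample_id Sample label.
#' @param species Character vector of component species names (resolved
#'   against a registry).
#' @param volume Component volumes, litres; all > 0.
#' @param concentration Component mass concentrations, kg/L (of each
#'   component's stock, i.e. pre-mix).
#' @param is_reference Flag marking the radar-comparison baseline.
#' @return An object of class `sample_composition`; `total_volume` is the
#'   sum of component volumes.
#' @export
sample_composition <- function(sample_id, species, volume, concentration,
                               is_reference = FALSE) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id),
            length(species) >= 1L,
            length(volume) == length(species),
            length(concentration) == length(species),
            all(volume > 0), all(concentration > 0))
  structure(
    list(sample_id = sample_id,
         components = data.frame(species = species, volume = volume,
                                 concentration = concentration,
                                 stringsAsFactors = FALSE),
         total_volume = sum(volume),
         is_reference = isTRUE(is_reference)),
    class = "sample_composition"
  )
}

#' @export
print.sample_composition <- function(x, ...) {
  cat(sprintf("<sample_composition> %s%s, total volume %.4g L\n", x$sample_id,
              if (x$is_reference) " (reference)" else "", x$total_volume))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Build the effective oscillator ensemble for a sample
#'
#' Resolves a [sample_composition()] against a species registry, computes
#' each component's molecule count from its own concentration and volume,
#' and applies the mixture rules: additive strength over non-inert
#' components and volume-weighted damping. Every non-inert species must
#' carry a damping constant (calibrated or supplied).
#'
#' @param composition A [sample_composition()].
#' @param species_list Named list of [molecular_species()] objects.
#' @param gamma_overrides Optional named numeric vector of damping
#'   constants (1/s) taking precedence over the species' own `gamma`.
#' @param include_inert_damping Logical; if `TRUE`, inert components with
#'   a damping constant participate in the volume-weighted damping
#'   average. Default `FALSE` (inert species excluded from both mixture
#'   rules).
#' @return An [oscillator_ensemble()] whose `n_molecules_N` sums the
#'   non-inert components.
#' @export
build_ensemble <- function(composition, species_list, gamma_overrides = NULL,
                           include_inert_damping = FALSE) {
  stopifnot(inherits(composition, "sample_composition"))
  comp <- composition$components
  missing <- setdiff(comp$species, names(species_list))
  if (length(missing)) {
    stop("unknown species in sample '", composition$sample_id, "': ",
         paste(missing, collapse = ", "))
  }
  sp <- species_list[comp$species]
  inert <- vapply(sp, function(s) s$inert, logical(1))
  gam <- vapply(seq_along(sp), function(i) {
    s <- sp[[i]]
    if (!is.null(gamma_overrides) && s$name %in% names(gamma_overrides)) {
      return(gamma_overrides[[s$name]])
    }
    if (is.null(s$gamma)) NA_real_ else s$gamma
  }, numeric(1))

  keep_n <- !inert
  if (!any(keep_n)) {
    stop("sample '", composition$sample_id, "' has no non-inert component")
  }
  N_i <- estimate_molecule_count(comp$concentration[keep_n],
                                 comp$volume[keep_n],
                                 vapply(sp[keep_n], `[[`, numeric(1), "mass_M"))
  S <- mixed_strength(N_i,
                      vapply(sp[keep_n], `[[`, numeric(1), "charge_Q"),
                      vapply(sp[keep_n], `[[`, numeric(1), "mass_M"))

  keep_g <- if (include_inert_damping) !is.na(gam) else (!inert & !is.na(gam))
  if (any(!inert & is.na(gam))) {
    stop("sample '", composition$sample_id,
         "': non-inert component(s) without damping constant: ",
         paste(comp$species[!inert & is.na(gam)], collapse = ", "))
  }
  gamma_eff <- mixed_damping(gam[keep_g], comp$volume[keep_g])
  oscillator_ensemble(sum(N_i), S, gamma_eff)
}
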