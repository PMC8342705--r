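# Driven-damped Lorentz oscillator: forward permittivity model, its exact
# inversion for the natural frequency, time-dependent polarization
# responses, and damping calibration against a literature dipole moment.
#
# Conventions (fixed package-wide):
#  * omega, omega0, gamma are angular (rad/s); reported frequencies are
#    cyclic (f = omega / 2pi).
#  * x denotes omega0^2 - omega^2 throughout; for epsilon_r > 1 the
#    inversion is a quadratic in x: x^2 - B x + (gamma*omega)^2 = 0 with
#    B = S / (eps0 * (epsilon_r - 1)), S = N Q^2 / M.
#  * Complex roots (negative discriminant) are returned flagged, never
#    silently converted to magnitudes. The quadratic identity
#    x^2 + (gamma*omega)^2 = B x holds for complex roots too, so the
#    forward model still reproduces epsilon_r exactly when evaluated in
#    complex arithmetic.

# relative tolerance for classifying the quadratic discriminant as zero
# (degenerate double root); guards against sign flicker at the bracket
# edge gamma = B / (2 omega)
.DISC_REL_TOL <- 1e-12

#' Forward Lorentz-oscillator permittivity
#'
#' Evaluates the relative permittivity of the driven, damped oscillator
#' ensemble at natural angular frequency `omega0`:
#' \deqn{\epsilon_r = 1 + \frac{S\,(\omega_0^2-\omega^2)}
#'   {\epsilon_0[(\omega_0^2-\omega^2)^2 + (\gamma\omega)^2]}}
#' with oscillator strength \eqn{S = N Q^2 / M}. Exact evaluation; no
#' fitting. `omega0` may be complex (a flagged root from
#' [invert_natural_frequency()]); for exact quadratic roots the imaginary
#' part of the result cancels and the real value is returned.
#'
#' @param ens An [oscillator_ensemble()].
#' @param field A [field_config()].
#' @param omega0 Natural angular frequency, rad/s; numeric or complex,
#'   vectorised.
#' @return Relative permittivity (dimensionless), same length as `omega0`.
#' @export
forward_permittivity <- function(ens, field, omega0) {
  stopifnot(inherits(ens, "oscillator_ensemble"), inherits(field, "field_config"),
            is.numeric(omega0) || is.complex(omega0))
  w <- field$drive_omega
  gw <- ens$gamma_eff * w
  x <- omega0^2 - w^2
  val <- 1 + (ens$strength_NQ2_over_M / corona_constants$epsilon0) *
    x / (x^2 + gw^2)
  if (is.complex(val)) {
    rel_im <- abs(Im(val)) / pmax(1, abs(Re(val)))
    if (any(rel_im > 1e-6)) {
      warning("forward_permittivity: non-negligible imaginary part (max rel ",
              format(max(rel_im), digits = 3),
              "); omega0 is not a root of the inversion quadratic")
    }
    val <- Re(val)
  }
  if (any(!is.finite(val))) {
    stop("forward_permittivity: non-finite result; parameter magnitudes invalid")
  }
  val
}

#' Invert the permittivity model for the natural frequency
#'
#' Solves the forward model for \eqn{\omega_0} at a measured relative
#' permittivity. In `"consistent"` mode the model is inverted exactly as a
#' quadratic in \eqn{x = \omega_0^2 - \omega^2}:
#' \eqn{x = [B \pm \sqrt{B^2 - 4\gamma^2\omega^2}]/2},
#' \eqn{B = S/(\epsilon_0(\epsilon_r - 1))}, so every real root
#' substituted back reproduces `epsilon_r` to machine precision. When the
#' discriminant is negative the complex-conjugate pair is returned,
#' flagged, never dropped. `"as_printed"` mode evaluates the published
#' closed form with its dimensionally inconsistent discriminant
#' \eqn{A^2 - 4A(\omega^4 + \gamma^2\omega^2 + B\omega^2)},
#' \eqn{A = B + 2\omega^2}; its output does not round-trip through the
#' forward model and is flagged accordingly (audit use only).
#'
#' @param ens An [oscillator_ensemble()].
#' @param field A [field_config()].
#' @param epsilon_r Measured relative permittivity; must be > 1 (at
#'   `epsilon_r = 1` the model forces \eqn{\omega_0 = \omega} and B
#'   diverges).
#' @param mode `"consistent"` (default) or `"as_printed"`.
#' @return An object of class `oscillator_solution`: complex vector
#'   `omega0_roots` (rad/s, ascending by real part) with `root_real`
#'   flags, `selected_root` (smaller real root, or the positive-imaginary
#'   member of the complex pair when no real root exists), `f0_hz`,
#'   per-molecule dipole amplitude (C m), polarization current density
#'   amplitude at `eval_time_t` (A/m^2; `NA` for non-real roots), and
#'   diagnostics.
#' @export
invert_natural_frequency <- function(ens, field, epsilon_r,
                                     mode = c("consistent", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ens, "oscillator_ensemble"), inherits(field, "field_config"),
            is.numeric(epsilon_r), length(epsilon_r) == 1L, is.finite(epsilon_r))
  if (epsilon_r <= 1) {
    stop("degenerate input: epsilon_r must be > 1 (got ", epsilon_r,
         "); B = S/(eps0*(epsilon_r - 1)) is undefined or divergent")
  }
  w <- field$drive_omega
  g <- ens$gamma_eff
  S <- ens$strength_NQ2_over_M
  B <- S / (corona_constants$epsilon0 * (epsilon_r - 1))
  diagnostics <- character()

  if (mode == "consistent") {
    disc <- B^2 - 4 * g^2 * w^2
    if (abs(disc) <= .DISC_REL_TOL * B^2) {
      # double root at the critical damping gamma = B / (2 omega)
      x <- complex(real = rep(B / 2, 2), imaginary = 0)
      diagnostics <- c(diagnostics, "degenerate_discriminant_double_root")
    } else if (disc > 0) {
      r <- sqrt(disc)
      x <- complex(real = c((B - r) / 2, (B + r) / 2), imaginary = 0)
    } else {
      r <- sqrt(-disc)
      x <- complex(real = B / 2, imaginary = c(-r, r) / 2)
      diagnostics <- c(diagnostics,
                       "no_real_root: discriminant B^2 - 4*gamma^2*omega^2 < 0")
    }
    omega0sq <- x + w^2
    round_trippable <- TRUE
  } else {
    A <- B + 2 * w^2
    C <- w^4 + g^2 * w^2 + B * w^2
    disc_p <- A^2 - 4 * A * C
    rp <- sqrt(as.complex(disc_p))
    omega0sq <- (A + c(-1, 1) * rp) / 2
    x <- omega0sq - w^2
    diagnostics <- c(diagnostics,
                     "as_printed: closed form does not invert the forward model; not round-trippable")
    round_trippable <- FALSE
  }

  root_real <- abs(Im(omega0sq)) <= 1e-12 * pmax(abs(Re(omega0sq)), 1) &
    Re(omega0sq) > 0
  if (any(Re(omega0sq) <= 0)) {
    diagnostics <- c(diagnostics, "negative_omega0_squared")
  }
  omega0 <- sqrt(omega0sq)
  ord <- order(Re(omega0))
  omega0 <- omega0[ord]; root_real <- root_real[ord]; x <- x[ord]

  if (any(root_real)) {
    sel <- which(root_real)[1L]
  } else {
    sel <- which(Im(omega0) >= 0)[1L]
    if (is.na(sel)) sel <- 1L
  }
  selected <- omega0[sel]
  x_sel <- x[sel]

  # per-molecule dipole amplitude: charge * displacement amplitude
  # = (Q^2/M) E0 / sqrt(x^2 + (gamma w)^2); modulus for complex roots
  denom <- Mod(sqrt(x_sel^2 + (g * w)^2))
  dipole <- (S / ens$n_molecules_N) * field$field_amplitude_E0 / denom

  jp <- if (root_real[sel] && round_trippable) {
    polarization_current(ens, field, Re(selected), field$eval_time_t,
                         mode = "derivative_consistent")
  } else {
    NA_real_
  }

  structure(
    list(epsilon_r_in = epsilon_r,
         mode = mode,
         B = B,
         omega0_roots = omega0,
         root_real = root_real,
         selected_root = selected,
         selected_real = root_real[sel],
         f0_hz = Mod(selected) / (2 * pi),
         dipole_per_molecule = dipole,
         jp_amplitude = jp,
         gamma_eff = g,
         round_trippable = round_trippable,
         diagnostics = diagnostics),
    class = "oscillator_solution"
  )
}

#' @export
print.oscillator_solution <- function(x, ...) {
  cat(sprintf("<oscillator_solution> epsilon_r = %g (%s mode)\n",
              x$epsilon_r_in, x$mode))
  for (i in seq_along(x$omega0_roots)) {
    cat(sprintf("  root %d: %s rad/s [%s]\n", i,
                format(x$omega0_roots[i], digits = 10),
                if (x$root_real[i]) "real" else "complex"))
  }
  cat(sprintf("  selected: |omega0| = %.6g rad/s (f0 = %.6g Hz), dipole/molecule = %.6g C m\n",
              Mod(x$selected_root), x$f0_hz, x$dipole_per_molecule))
  if (length(x$diagnostics)) {
    cat("  diagnostics:", paste(x$diagnostics, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Complex polarization response
#'
#' Evaluates the complex oscillator response
#' \deqn{\tilde P(t) = \frac{S E_0}{\epsilon_0}
#'   \frac{(\omega_0^2-\omega^2) + i\gamma\omega}
#'        {(\omega_0^2-\omega^2)^2 + (\gamma\omega)^2} e^{-i\omega t}}
#' (a susceptibility-scaled field response, units V/m; multiply the real
#' part by \eqn{\epsilon_0} for a polarization density in C/m^2), together
#' with the per-molecule dipole amplitude used by the damping calibration.
#'
#' @param ens An [oscillator_ensemble()].
#' @param field A [field_config()].
#' @param omega0 Natural angular frequency, rad/s (real).
#' @param t Time(s), seconds; vectorised.
#' @return A list with `value` (complex, length of `t`), `amplitude` (the
#'   complex bracket at t = 0), and `dipole_per_molecule` (C m).
#' @export
polarization <- function(ens, field, omega0, t = field$eval_time_t) {
  stopifnot(inherits(ens, "oscillator_ensemble"), inherits(field, "field_config"),
            is.numeric(omega0), length(omega0) == 1L, is.finite(omega0),
            is.numeric(t), all(is.finite(t)))
  w <- field$drive_omega
  g <- ens$gamma_eff
  S <- ens$strength_NQ2_over_M
  E0 <- field$field_amplitude_E0
  x <- omega0^2 - w^2
  den <- x^2 + (g * w)^2
  amplitude <- (S * E0 / (corona_constants$epsilon0 * den)) *
    complex(real = x, imaginary = g * w)
  value <- amplitude * exp(complex(imaginary = -w * t))
  dipole <- (S / ens$n_molecules_N) * E0 / sqrt(den)
  list(value = value, amplitude = amplitude, dipole_per_molecule = dipole)
}

#' Polarization current density
#'
#' In `"derivative_consistent"` mode (default) returns the exact time
#' derivative of the real polarization density
#' \eqn{\epsilon_0 \mathrm{Re}\,\tilde P(t)}:
#' \deqn{J_P(t) = \frac{S E_0}{(\omega_0^2-\omega^2)^2 + (\gamma\omega)^2}
#'   \left[\gamma\omega^2\cos\omega t -
#'         (\omega_0^2-\omega^2)\,\omega\sin\omega t\right]}
#' which matches a centred finite difference of [polarization()]. In
#' `"as_printed"` mode the published expression is evaluated literally,
#' retaining its extra \eqn{(\omega_0^2-\omega^2)} prefactor; it is not
#' the derivative of the polarization and is provided for audit only.
#'
#' @inheritParams polarization
#' @param mode `"derivative_consistent"` or `"as_printed"`.
#' @return Current density in A/m^2, same length as `t`.
#' @export
polarization_current <- function(ens, field, omega0, t = field$eval_time_t,
                                 mode = c("derivative_consistent", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ens, "oscillator_ensemble"), inherits(field, "field_config"),
            is.numeric(omega0), length(omega0) == 1L, is.finite(omega0),
            is.numeric(t), all(is.finite(t)))
  w <- field$drive_omega
  g <- ens$gamma_eff
  S <- ens$strength_NQ2_over_M
  E0 <- field$field_amplitude_E0
  x <- omega0^2 - w^2
  den <- x^2 + (g * w)^2
  osc <- g * w^2 * cos(w * t) - x * w * sin(w * t)
  base <- S * E0 * osc / den
  switch(mode,
         derivative_consistent = base,
         as_printed = x * base)
}

#' Calibrate the damping constant from a literature dipole moment
#'
#' The damping constant is treated as an empirical parameter and fixed so
#' that the per-molecule dipole amplitude implied by the model at a
#' reference permittivity equals the species' literature dipole moment.
#' For each trial damping the natural frequency is re-solved with
#' [invert_natural_frequency()] and the dipole amplitude
#' \eqn{Q^2 E_0 / (M\sqrt{(\omega_0^2-\omega^2)^2 + (\gamma\omega)^2})}
#' evaluated at the selected (smaller) root; this quantity is strictly
#' decreasing in the damping, so a bracketed root search on
#' \eqn{\log\gamma} is deterministic.
#'
#' The search runs over \eqn{\gamma \in} `gamma_range`, truncated above at
#' the critical damping \eqn{B/(2\omega)} beyond which the inversion has
#' no real root. If the target dipole lies outside the achievable range
#' the nearest-achievable damping and dipole are returned with a
#' `no_solution` diagnostic — never silently clipped.
#'
#' @param species A [molecular_species()] with `dipole_lit` set (debye).
#' @param ens An [oscillator_ensemble()] for the reference sample
#'   (supplies S and the trial dampings are substituted into it).
#' @param field A [field_config()].
#' @param epsilon_r_ref Reference relative permittivity (> 1), typically
#'   the species' measurement at the coolest temperature.
#' @param gamma_range Search bracket for the damping constant, 1/s.
#' @param tol Relative tolerance on the achieved dipole.
#' @return An object of class `damping_calibration`: `gamma` (1/s),
#'   `achieved_dipole_Cm`, `target_dipole_Cm`, `converged` (logical),
#'   `diagnostic` (`"ok"` or a `no_solution` message), `gamma_range`.
#' @export
calibrate_damping <- function(species, ens, field, epsilon_r_ref,
                              gamma_range = c(1e-3, 1e15), tol = 1e-8) {
  stopifnot(inherits(species, "molecular_species"),
            inherits(ens, "oscillator_ensemble"),
            inherits(field, "field_config"),
            is.numeric(epsilon_r_ref), length(epsilon_r_ref) == 1L)
  if (epsilon_r_ref <= 1) {
    stop("degenerate reference: epsilon_r_ref must be > 1")
  }
  if (is.na(species$dipole_lit) || species$dipole_lit <= 0) {
    stop("species '", species$name, "' has no positive literature dipole moment")
  }
  target <- debye_to_si(species$dipole_lit)
  w <- field$drive_omega
  S <- ens$strength_NQ2_over_M
  B <- S / (corona_constants$epsilon0 * (epsilon_r_ref - 1))
  gamma_crit <- B / (2 * w)        # largest damping with a real root
  lo <- gamma_range[1L]
  hi <- min(gamma_range[2L], gamma_crit)
  if (hi <= lo) {
    stop("calibration bracket is empty: critical damping ",
         format(gamma_crit), " 1/s lies below the lower bound")
  }

  dipole_at <- function(gamma) {
    ens_g <- oscillator_ensemble(ens$n_molecules_N, S, gamma)
    sol <- invert_natural_frequency(ens_g, field, epsilon_r_ref,
                                    mode = "consistent")
    sol$dipole_per_molecule
  }
  f <- function(lg) log(dipole_at(exp(lg))) - log(target)

  f_lo <- f(log(lo)); f_hi <- f(log(hi))
  if (f_lo * f_hi > 0) {
    # no bracket: report the nearest achievable endpoint, never clip silently
    at_hi <- abs(f_hi) < abs(f_lo)
    g_near <- if (at_hi) hi else lo
    diag <- if (f_hi > 0) {
      "no_solution: target dipole below the achievable range (minimum at the critical damping)"
    } else {
      "no_solution: target dipole above the achievable range (maximum at the lower damping bound)"
    }
    return(structure(
      list(gamma = g_near,
           achieved_dipole_Cm = dipole_at(g_near),
           target_dipole_Cm = target,
           converged = FALSE,
           diagnostic = diag,
           gamma_range = c(lo, hi)),
      class = "damping_calibration"))
  }

  root <- stats::uniroot(f, lower = log(lo), upper = log(hi), tol = 1e-13)
  gamma_star <- exp(root$root)
  achieved <- dipole_at(gamma_star)
  rel <- abs(achieved - target) / target
  structure(
    list(gamma = gamma_star,
         achieved_dipole_Cm = achieved,
         target_dipole_Cm = target,
         converged = rel <= tol,
         diagnostic = if (rel <= tol) "ok" else
           paste0("converged to relative dipole error ", format(rel, digits = 3)),
         gamma_range = c(lo, hi)),
    class = "damping_calibration")
}

#' @export
print.damping_calibration <- function(x, ...) {
  cat(sprintf("<damping_calibration> gamma = %.8g 1/s (%s)\n", x$gamma,
              x$diagnostic))
  cat(sprintf("  dipole: achieved %.6g C m vs target %.6g C m\n",
              x$achieved_dipole_Cm, x$target_dipole_Cm))
  invisible(x)
}
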