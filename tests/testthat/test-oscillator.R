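test_that("forward permittivity is exactly 1 on resonance and in the overdamped limit", {
  field <- study_field()
  w <- field$drive_omega
  set.seed(11)
  for (i in 1:20) {
    ens <- oscillator_ensemble(1e11, 10^runif(1, 8, 14), 10^runif(1, 3, 12))
    expect_identical(forward_permittivity(ens, field, w), 1)
  }
  ens <- oscillator_ensemble(1e11, 1e12, 1e30)
  expect_equal(forward_permittivity(ens, field, 1.7 * w), 1, tolerance = 1e-12)
})

test_that("forward permittivity matches the hand-derived symbolic case", {
  # S = 2 eps0 w^2, omega0^2 = 2 w^2, gamma = w:
  # eps = 1 + 2 w^2 * w^2 / (w^4 + w^4) = 2
  field <- study_field()
  w <- field$drive_omega
  ens <- oscillator_ensemble(1, 2 * corona_constants$epsilon0 * w^2, w)
  expect_equal(forward_permittivity(ens, field, sqrt(2) * w), 2,
               tolerance = 1e-14)
})

test_that("inversion rejects degenerate permittivity", {
  case <- local({set.seed(1); draw_real_root_case()})
  expect_error(invert_natural_frequency(case$ens, case$field, 1),
               "degenerate")
  expect_error(invert_natural_frequency(case$ens, case$field, 0.5),
               "degenerate")
})

test_that("both real roots round-trip through the forward model within 1e-9", {
  set.seed(42)
  for (i in 1:50) {
    case <- draw_real_root_case()
    sol <- invert_natural_frequency(case$ens, case$field, case$epsilon_r)
    expect_true(all(sol$root_real))
    for (r in sol$omega0_roots) {
      expect_rel_equal(forward_permittivity(case$ens, case$field, r),
                       case$epsilon_r, 1e-9)
    }
    expect_identical(Mod(sol$selected_root), min(Mod(sol$omega0_roots)))
  }
})

test_that("inversion roots coincide with the brute-force scan minima", {
  set.seed(7)
  for (i in 1:5) {
    case <- draw_real_root_case()
    sol <- invert_natural_frequency(case$ens, case$field, case$epsilon_r)
    oracle <- brute_force_minima_x(case$ens, case$field, case$epsilon_r,
                                   n_grid = 2e5)
    x_roots <- Re(sol$omega0_roots^2) - case$field$drive_omega^2
    for (xr in x_roots) {
      expect_true(min(abs(oracle$x_min - xr)) <= oracle$step,
                  label = "analytic root within one grid step of a scan minimum")
    }
  }
})

test_that("critical damping yields the double root (B + 2 w^2) / 2", {
  field <- study_field()
  w <- field$drive_omega
  S <- 3.7e12; epsilon_r <- 68
  B <- S / (corona_constants$epsilon0 * (epsilon_r - 1))
  ens <- oscillator_ensemble(1e11, S, B / (2 * w))
  sol <- invert_natural_frequency(ens, field, epsilon_r)
  expect_true(all(sol$root_real))
  expect_rel_equal(Re(sol$omega0_roots^2), rep((B + 2 * w^2) / 2, 2), 1e-9)
  expect_match(paste(sol$diagnostics, collapse = " "), "double_root")
})

test_that("overdamped inversion flags the complex pair and still round-trips", {
  field <- study_field()
  w <- field$drive_omega
  S <- 1.065e12; epsilon_r <- 370
  B <- S / (corona_constants$epsilon0 * (epsilon_r - 1))
  ens <- oscillator_ensemble(1.812e11, S, 3 * B / (2 * w))
  sol <- invert_natural_frequency(ens, field, epsilon_r)
  expect_false(any(sol$root_real))
  expect_false(sol$selected_real)
  expect_match(paste(sol$diagnostics, collapse = " "), "no_real_root")
  # conjugate pair in omega0^2
  x <- sol$omega0_roots^2 - w^2
  expect_equal(Conj(x[1]), x[2], tolerance = 1e-12)
  # the quadratic identity makes the forward model reproduce epsilon_r
  expect_rel_equal(forward_permittivity(ens, field, sol$selected_root),
                   epsilon_r, 1e-9)
})

test_that("as-printed inversion is flagged non-round-trippable", {
  case <- local({set.seed(3); draw_real_root_case()})
  sol <- invert_natural_frequency(case$ens, case$field, case$epsilon_r,
                                  mode = "as_printed")
  expect_false(sol$round_trippable)
  expect_match(paste(sol$diagnostics, collapse = " "), "as_printed")
})

test_that("polarization phase, resonance, and modulus identities hold", {
  field <- study_field()
  w <- field$drive_omega
  ens <- oscillator_ensemble(1e11, 2.4e12, 0.2 * w)
  omega0 <- 1.6 * w

  # t = 0: the phase factor is 1
  p0 <- polarization(ens, field, omega0, t = 0)
  expect_identical(p0$value, p0$amplitude)

  # on resonance the real part of the amplitude vanishes
  pres <- polarization(ens, field, w, t = 0)
  expect_equal(Re(pres$amplitude), 0)
  expect_gt(Im(pres$amplitude), 0)

  # |a + ib| identity: modulus = S E0 / (eps0 sqrt(x^2 + (gamma w)^2))
  x <- omega0^2 - w^2
  expected <- ens$strength_NQ2_over_M * field$field_amplitude_E0 /
    (corona_constants$epsilon0 * sqrt(x^2 + (ens$gamma_eff * w)^2))
  expect_rel_equal(Mod(p0$amplitude), expected, 1e-12)

  # |value| is time-independent
  pt <- polarization(ens, field, omega0, t = c(0, 1e-10, 1e-6))
  expect_rel_equal(Mod(pt$value), rep(expected, 3), 1e-12)
})

test_that("polarization current is the derivative of the polarization density", {
  field <- study_field()
  w <- field$drive_omega
  h <- 1e-15
  set.seed(99)
  for (i in 1:100) {
    ens <- oscillator_ensemble(1e11, 10^runif(1, 10, 13), 10^runif(1, 8, 11))
    omega0 <- runif(1, 1.05, 3) * w
    t <- runif(1, 0, 2 * pi / w)
    jp <- polarization_current(ens, field, omega0, t)
    p_plus <- Re(polarization(ens, field, omega0, t + h)$value)
    p_minus <- Re(polarization(ens, field, omega0, t - h)$value)
    fd <- corona_constants$epsilon0 * (p_plus - p_minus) / (2 * h)
    # relative to the current amplitude (J passes through zero twice a cycle)
    amp <- ens$strength_NQ2_over_M * field$field_amplitude_E0 * w *
      sqrt((omega0^2 - w^2)^2 + (ens$gamma_eff * w)^2) /
      ((omega0^2 - w^2)^2 + (ens$gamma_eff * w)^2)
    expect_lt(abs(jp - fd) / amp, 1e-6)
  }
})

test_that("on resonance the current reduces to a pure cosine from the damping term", {
  field <- study_field()
  w <- field$drive_omega
  ens <- oscillator_ensemble(1e11, 5e11, 0.7 * w)
  t <- seq(0, 2 * pi / w, length.out = 17)
  jp <- polarization_current(ens, field, w, t)
  expected <- ens$strength_NQ2_over_M * field$field_amplitude_E0 *
    ens$gamma_eff * w^2 * cos(w * t) / (ens$gamma_eff * w)^2
  expect_equal(jp, expected, tolerance = 1e-14)
})

test_that("as-printed current carries the extra (omega0^2 - omega^2) prefactor", {
  field <- study_field()
  w <- field$drive_omega
  ens <- oscillator_ensemble(1e11, 5e11, 0.3 * w)
  omega0 <- 1.9 * w
  t <- c(0, 3e-11, 1e-6)
  expect_equal(polarization_current(ens, field, omega0, t, mode = "as_printed"),
               (omega0^2 - w^2) *
                 polarization_current(ens, field, omega0, t,
                                      mode = "derivative_consistent"),
               tolerance = 1e-14)
  # an omega-independent signal has zero derivative: on a constant
  # polarization the current vanishes (t-grid of the cosine's zeros)
  tz <- (pi / 2 + pi * 0:3) / w
  jp <- polarization_current(ens, field, w, tz)  # x = 0: pure cosine term
  expect_equal(jp, ens$strength_NQ2_over_M * field$field_amplitude_E0 *
                 cos(w * tz) / ens$gamma_eff, tolerance = 1e-8)
})

test_that("damping calibration recovers a planted constant from its own dipole", {
  field <- study_field()
  w <- field$drive_omega
  set.seed(5)
  for (i in 1:10) {
    S <- 10^runif(1, 11, 13)
    epsilon_r <- runif(1, 5, 300)
    N <- 10^runif(1, 10, 12)
    B <- S / (corona_constants$epsilon0 * (epsilon_r - 1))
    gamma_true <- runif(1, 0.1, 0.9) * B / (2 * w)
    ens <- oscillator_ensemble(N, S, gamma_true)
    sol <- invert_natural_frequency(ens, field, epsilon_r)
    # plant the species dipole at exactly the model-implied amplitude
    dipole_debye <- sol$dipole_per_molecule / corona_constants$debye_Cm
    # species Q, M consistent with the ensemble: Q^2/M = S/N
    sp <- molecular_species("planted", charge_Q = 1e-9,
                            mass_M = 1e-9^2 / (S / N),
                            dipole_lit = dipole_debye)
    cal <- calibrate_damping(sp, ens, field, epsilon_r)
    expect_true(cal$converged)
    expect_rel_equal(cal$gamma, gamma_true, 1e-6)
  }
})

test_that("calibration is monotone: larger planted damping recovers larger gamma", {
  field <- study_field()
  w <- field$drive_omega
  S <- 1.2e12; epsilon_r <- 50; N <- 1e11
  B <- S / (corona_constants$epsilon0 * (epsilon_r - 1))
  gammas <- c(0.2, 0.6) * B / (2 * w)
  rec <- vapply(gammas, function(g) {
    ens <- oscillator_ensemble(N, S, g)
    sol <- invert_natural_frequency(ens, field, epsilon_r)
    sp <- molecular_species("m", 1e-9, 1e-9^2 / (S / N),
                            sol$dipole_per_molecule / corona_constants$debye_Cm)
    calibrate_damping(sp, ens, field, epsilon_r)$gamma
  }, numeric(1))
  expect_true(rec[1] < rec[2])
})

test_that("literature dipole targets are accepted and the unreachable regime is diagnosed", {
  # insulin (369 D) and papain (150 D) targets are valid inputs, but with
  # the literature charge/mass/concentration the minimum achievable
  # per-molecule dipole (at critical damping) is orders of magnitude
  # larger, so calibration reports the nearest-achievable damping with an
  # explicit no-solution diagnostic rather than clipping silently.
  field <- study_field()
  w <- field$drive_omega
  insulin <- molecular_species("insulin", 74.805e-10, 9.52e-18, 369)
  papain <- molecular_species("papain", 4.01e-8, 3.88e-17, 150)
  for (case in list(list(sp = insulin, conc = 6.9e-3, er = 68),
                    list(sp = papain, conc = 10e-3, er = 27))) {
    sp <- case$sp
    N <- estimate_molecule_count(case$conc, 250e-6, sp$mass_M)
    S <- N * sp$charge_Q^2 / sp$mass_M
    ens <- oscillator_ensemble(N, S, 1)
    cal <- calibrate_damping(sp, ens, field, case$er)
    expect_false(cal$converged)
    expect_match(cal$diagnostic, "no_solution")
    B <- S / (corona_constants$epsilon0 * (case$er - 1))
    expect_rel_equal(cal$gamma, B / (2 * w), 1e-9)
    expect_gt(cal$achieved_dipole_Cm, cal$target_dipole_Cm)
  }
  expect_error(calibrate_damping(insulin,
                                 oscillator_ensemble(1e11, 1e12, 1),
                                 field, 1), "degenerate")
})
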