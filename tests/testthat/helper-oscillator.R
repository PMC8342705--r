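# Shared fixtures for the oscillator tests: random but physically valid
# parameter draws, and the brute-force grid oracle for the inversion.

study_field <- function() field_config(6.41e9, 4.9, 1e-6)

# random ensemble + permittivity guaranteed to have two real roots:
# gamma is drawn strictly inside (0, B / (2 omega))
draw_real_root_case <- function(field = study_field()) {
  w <- field$drive_omega
  S <- 10^stats::runif(1, 11, 13)
  epsilon_r <- stats::runif(1, 2, 500)
  B <- S / (corona_constants$epsilon0 * (epsilon_r - 1))
  gamma <- stats::runif(1, 0.05, 0.95) * B / (2 * w)
  list(ens = oscillator_ensemble(1e11, S, gamma),
       field = field, epsilon_r = epsilon_r, B = B)
}

# brute-force oracle: scan |forward(omega0) - epsilon_r| on a dense grid
# of x = omega0^2 - omega^2 and return the x positions of its local
# minima (interior grid points only)
brute_force_minima_x <- function(ens, field, epsilon_r, n_grid = 1e6) {
  w <- field$drive_omega
  S <- ens$strength_NQ2_over_M
  B <- S / (corona_constants$epsilon0 * (epsilon_r - 1))
  x <- seq(B / n_grid, 1.05 * B, length.out = n_grid)
  eps <- 1 + (S / corona_constants$epsilon0) * x / (x^2 + (ens$gamma_eff * w)^2)
  v <- abs(eps - epsilon_r)
  n <- length(v)
  interior <- 2:(n - 1)
  mins <- interior[v[interior] <= v[interior - 1] & v[interior] <= v[interior + 1]]
  list(x_min = x[mins], step = x[2] - x[1])
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("max rel err %.3g <= %.3g",
                              max(abs(actual - expected) / abs(expected)), tol))
}
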