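# Pumped-frequency resonant-absorption verification: simulate the power
# absorbed while sweeping a signal generator across the neighbourhood of
# the predicted natural frequency, and detect the resonance peak.
#
# The absorbed-power lineshape is modelled as the Lorentzian consistent
# with the package's oscillator,
#   A(w) = P_pump * (gamma*w)^2 / ((w0^2 - w^2)^2 + (gamma*w)^2),
# which equals the pump power exactly on resonance.

#' Simulate a resonant-absorption scan
#'
#' @param omega0_true True natural angular frequency, rad/s.
#' @param gamma Damping constant, 1/s; > 0.
#' @param grid Strictly increasing grid of pump angular frequencies,
#'   rad/s. A warning diagnostic is attached if it does not span
#'   `omega0_true`.
#' @param pump_power Pump power, watts (e.g. `dbm_to_watts(-50)`).
#' @param noise_sd Additive noise standard deviation, watts; >= 0.
#' @param seed Integer RNG seed; the same seed reproduces the scan
#'   exactly and the caller's RNG state is untouched.
#' @return An object of class `absorption_scan`: `pump_omega` (rad/s),
#'   `pump_frequencies` (Hz), `absorbed_power` (W), `pump_power`,
#'   `noise_sd`, and `diagnostics`.
#' @export
simulate_absorption <- function(omega0_true, gamma, grid,
                                pump_power = dbm_to_watts(-50),
                                noise_sd = 0, seed = 1L) {
  stopifnot(is.numeric(omega0_true), omega0_true > 0,
            is.numeric(gamma), gamma > 0,
            is.numeric(grid), length(grid) >= 2L, all(diff(grid) > 0),
            is.numeric(pump_power), pump_power > 0,
            is.numeric(noise_sd), noise_sd >= 0)
  diagnostics <- character()
  if (omega0_true < grid[1L] || omega0_true > grid[length(grid)]) {
    diagnostics <- "grid does not span omega0_true"
    warning(diagnostics)
  }
  gw <- gamma * grid
  clean <- pump_power * gw^2 / ((omega0_true^2 - grid^2)^2 + gw^2)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  } else {
    rep(0, length(grid))
  }
  structure(
    list(pump_omega = grid,
         pump_frequencies = grid / (2 * pi),
         absorbed_power = clean + noise,
         pump_power = pump_power,
         noise_sd = noise_sd,
         diagnostics = diagnostics),
    class = "absorption_scan"
  )
}

#' @export
print.absorption_scan <- function(x, ...) {
  cat(sprintf("<absorption_scan> %d points, %.6g-%.6g Hz, pump %.3g W, noise sd %.3g W\n",
              length(x$pump_omega), min(x$pump_frequencies),
              max(x$pump_frequencies), x$pump_power, x$noise_sd))
  invisible(x)
}

#' Locate the resonance in an absorption scan
#'
#' Finds the grid point of maximum absorbed power and refines it by
#' three-point parabolic interpolation through the peak and its
#' neighbours (log-free, on the raw powers). A flat scan carries no
#' resonance information and is an error.
#'
#' @param scan An [simulate_absorption()] result, or any list with
#'   `pump_omega` and `absorbed_power`.
#' @return Resonance frequency in Hz (cyclic). The corresponding angular
#'   frequency is attached as attribute `omega`.
#' @export
find_resonance <- function(scan) {
  w <- scan$pump_omega
  p <- scan$absorbed_power
  stopifnot(length(w) >= 3L, length(p) == length(w))
  if (diff(range(p)) == 0) {
    stop("no-peak: absorbed power is flat across the scan")
  }
  i <- which.max(p)
  if (i == 1L || i == length(p)) {
    # peak on the boundary: parabola undefined, also implies a monotone
    # ramp or a grid that does not span the resonance
    if (all(diff(p) >= 0) || all(diff(p) <= 0)) {
      stop("no-peak: absorbed power is monotone across the scan")
    }
    omega_hat <- w[i]
  } else {
    # parabola through (w[i-1], p[i-1]), (w[i], p[i]), (w[i+1], p[i+1]);
    # assumes locally uniform spacing
    h1 <- w[i] - w[i - 1L]; h2 <- w[i + 1L] - w[i]
    denom <- p[i - 1L] - 2 * p[i] + p[i + 1L]
    delta <- if (denom == 0) 0 else 0.5 * (p[i - 1L] - p[i + 1L]) / denom
    omega_hat <- w[i] + delta * (h1 + h2) / 2
  }
  structure(omega_hat / (2 * pi), omega = omega_hat)
}
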