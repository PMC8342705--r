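# Synthetic-data generation: forward-simulated dielectric temperature
# sweeps with known ground truth (for parameter-recovery testing) and the
# built-in example dataset reproducing the study's reported insulin /
# papain / ZnO values.

#' Define a synthetic ground truth
#'
#' Ground truth for one simulated sample: a damping constant and the true
#' natural angular frequency at each temperature, plus the measurement
#' noise model. The default temperature dependence used by
#' [linear_omega0()] is linear, emulating the roughly proportional
#' permittivity-temperature trend of the pure-protein sweeps; noise is
#' multiplicative on the permittivity (the reported error bars grow with
#' the permittivity magnitude).
#'
#' @param sample_id Sample label.
#' @param gamma_true Damping constant, 1/s; > 0.
#' @param omega0_true Natural angular frequencies (rad/s) at each
#'   temperature; all finite and > 0.
#' @param temperatures Degrees Celsius, same length as `omega0_true`;
#'   default the study sweep 30-55 degC in 5 degC steps.
#' @param noise_sd Multiplicative permittivity noise standard deviation
#'   (dimensionless); >= 0.
#' @param n_runs Replicate runs per temperature; default 2 (the study's
#'   repeatability protocol).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(sample_id, gamma_true, omega0_true,
                            temperatures = seq(30, 55, by = 5),
                            noise_sd = 0.05, n_runs = 2L) {
  stopifnot(is.numeric(gamma_true), gamma_true > 0,
            is.numeric(omega0_true), all(is.finite(omega0_true)),
            all(omega0_true > 0),
            length(omega0_true) == length(temperatures),
            is.numeric(noise_sd), noise_sd >= 0,
            n_runs >= 1L)
  structure(
    list(sample_id = sample_id, gamma_true = gamma_true,
         omega0_true = omega0_true, temperatures = temperatures,
         noise_sd = noise_sd, n_runs = as.integer(n_runs)),
    class = "synthetic_truth"
  )
}

#' Linear natural-frequency-temperature map
#'
#' Convenience for [synthetic_truth()]: \eqn{\omega_0(T) = a + b T}.
#'
#' @param a Intercept, rad/s.
#' @param b Slope, rad/s per degC.
#' @param temperatures Degrees Celsius.
#' @return Natural angular frequencies, rad/s.
#' @export
linear_omega0 <- function(a, b, temperatures = seq(30, 55, by = 5)) {
  a + b * temperatures
}

#' Generate synthetic dielectric measurements
#'
#' Forward-simulates the measurement table for a ground truth:
#' \eqn{\epsilon_r(T, run) = \epsilon_r^{fwd}(\omega_0^{true}(T)) (1 + \eta)},
#' \eqn{\eta \sim N(0, \sigma)}, clipped below at `1 + 1e-6` with the
#' number of clipped draws recorded. Deterministic given `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param truth A [synthetic_truth()].
#' @param ens An [oscillator_ensemble()]; its damping is replaced by the
#'   truth's `gamma_true` for the forward evaluation.
#' @param field A [field_config()].
#' @param seed Integer RNG seed.
#' @return A data.frame in the canonical measurement schema with
#'   attributes `clipped` (count of clipped draws) and `truth`.
#' @export
generate_measurements <- function(truth, ens, field, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(ens, "oscillator_ensemble"),
            inherits(field, "field_config"))
  ens_true <- oscillator_ensemble(ens$n_molecules_N, ens$strength_NQ2_over_M,
                                  truth$gamma_true)
  eps_true <- forward_permittivity(ens_true, field, truth$omega0_true)
  nT <- length(truth$temperatures)
  nrun <- truth$n_runs
  eta <- with_seed(seed, stats::rnorm(nT * nrun, mean = 0, sd = truth$noise_sd))
  eps <- rep(eps_true, times = nrun) * (1 + eta)
  clip <- eps < 1 + 1e-6
  if (any(clip)) eps[clip] <- 1 + 1e-6
  out <- data.frame(
    sample_id = truth$sample_id,
    temperature_C = rep(truth$temperatures, times = nrun),
    epsilon_r = eps,
    run = rep(seq_len(nrun), each = nT),
    stringsAsFactors = FALSE
  )
  attr(out, "clipped") <- sum(clip)
  attr(out, "truth") <- truth
  out
}

#' Built-in insulin / papain / ZnO example dataset
#'
#' The canonical worked example shipped with the package: the reported
#' relative permittivities of pure insulin, papain at three
#' concentrations, and the insulin + ZnO mixtures over the 30-55 degC
#' sweep; the triplicate zeta-potential runs; the mean unfolding
#' enthalpies; and a registry with the literature species constants
#' (insulin Q = 74.805e-10 C, M = 9.52e-18 kg, dipole 369 D; papain
#' Q = 4.01e-8 C, M = 3.88e-17 kg, dipole 150 D; ZnO flagged inert) and
#' the probe field settings (6.41 GHz, 4.9 V/m, t = 1 us). Mixture
#' compositions follow the fixed 2:1 insulin:ZnO volume ratio in the
#' 250 ul sample holder.
#'
#' Zeta-potential entries use the dilutions measured by DLS (sample `P` is
#' diluted papain, distinct from the dielectric sample `P1`).
#'
#' @return A list with elements `registry` ([corona_registry()]),
#'   `measurements` and `aux` (canonical data.frames).
#' @export
corona_fixture <- function() {
  field <- field_config(6.41e9, 4.9, 1e-6)
  species <- list(
    insulin = molecular_species("insulin", 74.805e-10, 9.52e-18, 369),
    papain = molecular_species("papain", 4.01e-8, 3.88e-17, 150),
    zno_s = molecular_species("zno_s", NA_real_, NA_real_, inert = TRUE),
    zno_t = molecular_species("zno_t", NA_real_, NA_real_, inert = TRUE)
  )
  ul <- 1e-6; mgml <- 1e-3
  samples <- list(
    I = sample_composition("I", "insulin", 250 * ul, 6.9 * mgml,
                           is_reference = TRUE),
    P1 = sample_composition("P1", "papain", 250 * ul, 10 * mgml),
    P2 = sample_composition("P2", "papain", 250 * ul, 5 * mgml),
    P3 = sample_composition("P3", "papain", 250 * ul, 2.5 * mgml),
    IZnO_S = sample_composition("IZnO_S", c("insulin", "zno_s"),
                                c(2, 1) / 3 * 250 * ul,
                                c(6.9, 3.45) * mgml),
    IZnO_T = sample_composition("IZnO_T", c("insulin", "zno_t"),
                                c(2, 1) / 3 * 250 * ul,
                                c(6.9, 3.45) * mgml)
  )
  measurements <- data.frame(
    sample_id = c("I", "I", "P1", "P1", "P2", "P3",
                  "IZnO_S", "IZnO_S", "IZnO_T", "IZnO_T"),
    temperature_C = c(30, 55, 30, 55, 30, 30, 30, 55, 30, 55),
    epsilon_r = c(68, 370, 27, 31, 24, 22, 40, 167, 95, 351),
    run = 1L,
    stringsAsFactors = FALSE
  )
  zeta <- list(
    ZnO_S = c(-10.9, -10.4, -11.4),
    ZnO_T = c(-19.9, -21.2, -16.4),
    I = c(-12.3, -11.7, -12.9),
    P = c(5.98, 6.68, 5.62),
    IZnO_S = c(-17.3, -18.3, -18.8),
    IZnO_T = c(-16.2, -16.7, -17.4),
    PZnO_S = c(15.2, 15.2, 15.3),
    PZnO_T = c(6.38, 6.84, 6.84),
    IP = c(13.5, 12.9, 13.4),
    IZnO_S_P = c(13.3, 13, 12.4),
    IZnO_T_P = c(9.96, 11, 11.7)
  )
  enthalpy <- c(I = 69.67, P = 103.28, ZnO_S = 8.08, ZnO_T = 7.13,
                IZnO_S = 62.15, IZnO_T = 38.26, PZnO_S = 107.70,
                PZnO_T = 125.35, IP = 213.35, IZnO_S_P = 83.67,
                IZnO_T_P = 120.44)
  aux <- rbind(
    data.frame(sample_id = rep(names(zeta), each = 3L),
               quantity = "zeta_mV",
               value = unlist(zeta, use.names = FALSE),
               run = rep(1:3, times = length(zeta)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = names(enthalpy),
               quantity = "enthalpy_J_per_g_degC",
               value = unname(enthalpy),
               run = 1L,
               stringsAsFactors = FALSE)
  )
  rownames(aux) <- NULL
  list(registry = corona_registry(field, species, samples),
       measurements = measurements, aux = aux)
}

#' Default synthetic study conditions
#'
#' The generator's reference configuration: an insulin-like ensemble
#' (literature charge and mass, 6.9 mg/ml in the 250 ul holder) driven at
#' the probe settings, with damping 0.5 x the drive angular frequency and
#' a natural frequency falling linearly from 2.0 to 1.4 x the drive
#' angular frequency across the 30-55 degC sweep. On the lower inversion
#' branch this makes the permittivity rise with temperature (from ~25 to
#' ~60) while the mechanical frequency falls, the qualitative behaviour
#' observed for thermally stressed insulin. Two replicate runs and 5%
#' multiplicative noise by default.
#'
#' @param noise_sd Multiplicative permittivity noise sd.
#' @param n_runs Replicate runs per temperature.
#' @param temperatures Sweep temperatures, degC.
#' @return A list with `truth` ([synthetic_truth()]), `ensemble`,
#'   `field`, and a single-sample `registry` whose species carries the
#'   true damping (so [run_sweep()] on generated data skips calibration).
#' @export
default_synthetic_study <- function(noise_sd = 0.05, n_runs = 2L,
                                    temperatures = seq(30, 55, by = 5)) {
  field <- field_config(6.41e9, 4.9, 1e-6)
  w <- field$drive_omega
  gamma_true <- 0.5 * w
  # omega0 falls from 2.0 w at 30 degC to 1.4 w at 55 degC
  slope <- -0.6 * w / 25
  omega0 <- linear_omega0(a = 2.0 * w - 30 * slope, b = slope, temperatures)
  truth <- synthetic_truth("synthetic", gamma_true, omega0, temperatures,
                           noise_sd = noise_sd, n_runs = n_runs)
  species <- list(
    insulin_like = molecular_species("insulin_like", 74.805e-10, 9.52e-18,
                                     dipole_lit = 369, gamma = gamma_true)
  )
  samples <- list(
    synthetic = sample_composition("synthetic", "insulin_like",
                                   250e-6, 6.9e-3, is_reference = TRUE)
  )
  registry <- corona_registry(field, species, samples)
  ens <- pure_ensemble(species$insulin_like, 6.9e-3, 250e-6)
  list(truth = truth, ensemble = ens, field = field, registry = registry)
}
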