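# Physical constants used throughout; full precision, never redefined locally.

#' Physical constants
#'
#' Constants used by the oscillator model, exposed for reproducibility:
#' `epsilon0` is the vacuum permittivity (8.8541878128e-12 F/m) and
#' `debye_Cm` the SI value of one debye (3.33564e-30 C m).
#'
#' @format A named list with elements `epsilon0` (F/m) and `debye_Cm` (C m).
#' @export
corona_constants <- list(
  epsilon0 = 8.8541878128e-12,
  debye_Cm = 3.33564e-30
)

#' Convert a dipole moment from debye to SI units
#'
#' Literature protein dipole moments (e.g. 369 D for insulin, 150 D for
#' papain) are quoted in debye; the oscillator calibration works in
#' coulomb-metres. One debye is 3.33564e-30 C m.
#'
#' @param d Numeric vector of dipole moments in debye.
#' @return Dipole moments in coulomb-metres. Exactly linear in `d`.
#' @examples
#' debye_to_si(369)
#' @export
debye_to_si <- function(d) {
  stopifnot(is.numeric(d), all(is.finite(d)))
  d * corona_constants$debye_Cm
}

#' Convert a power level from dBm to watts
#'
#' Standard conversion `10^(p/10)` milliwatts. The pump level used in the
#' resonant-absorption verification experiment, -50 dBm, corresponds to
#' 1e-8 W (10 nW).
#'
#' @param p Numeric vector of power levels in dBm.
#' @return Power in watts.
#' @examples
#' dbm_to_watts(-50)
#' @export
dbm_to_watts <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)))
  10^(p / 10) * 1e-3
}
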