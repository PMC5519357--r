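#' @title Physical constants and unit conversions
#' @name units
#' @description
#' All internal physics is done in K, nm, nm2 and nm4; the area expansion
#' modulus crosses the package boundary in mN/m and the bending rigidity in
#' both joules and units of the thermal energy kBT. Every conversion used
#' anywhere in the package lives in this file so the unit bookkeeping is
#' auditable in one place.
NULL

# CODATA 2018 exact value, J/K
.kB <- 1.380649e-23

#' Boltzmann constant
#'
#' @return The Boltzmann constant in J/K (CODATA exact value).
#' @export
#' @examples
#' boltzmann_constant()
boltzmann_constant <- function() .kB

#' Thermal energy kB*T
#'
#' @param temperature Absolute temperature in K.
#' @return Thermal energy in joules.
#' @export
kBT_joules <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  .kB * temperature
}

#' Convert degrees Celsius to kelvin
#'
#' @param celsius Temperature in degrees Celsius.
#' @return Temperature in K.
#' @export
#' @examples
#' celsius_to_kelvin(30) # 303.15
celsius_to_kelvin <- function(celsius) celsius + 273.15

#' Area expansion modulus: mN/m to kBT/nm2
#'
#' 1 mN/m = 1e-3 J/m^2 = 1e-21 J/nm^2, so the conversion depends on
#' temperature through kBT. At 303.15 K, 1 kBT/nm2 is about 4.186 mN/m.
#'
#' @param ka_mNm Modulus in mN/m.
#' @param temperature Absolute temperature in K.
#' @return Modulus in kBT per nm2.
#' @export
ka_mNm_to_kBT_nm2 <- function(ka_mNm, temperature) {
  ka_mNm * 1e-21 / kBT_joules(temperature)
}

#' Area expansion modulus: kBT/nm2 to mN/m
#'
#' @param ka_kBT Modulus in kBT per nm2.
#' @param temperature Absolute temperature in K.
#' @return Modulus in mN/m.
#' @export
ka_kBT_nm2_to_mNm <- function(ka_kBT, temperature) {
  ka_kBT * kBT_joules(temperature) / 1e-21
}

#' Bending rigidity: joules to kBT
#'
#' @param kappa_J Bending rigidity in joules.
#' @param temperature Absolute temperature in K.
#' @return Bending rigidity in units of kBT.
#' @export
kappa_joules_to_kBT <- function(kappa_J, temperature) {
  kappa_J / kBT_joules(temperature)
}

#' Bending rigidity: kBT to joules
#'
#' @param kappa_kBT Bending rigidity in kBT.
#' @param temperature Absolute temperature in K.
#' @return Bending rigidity in joules.
#' @export
kappa_kBT_to_joules <- function(kappa_kBT, temperature) {
  kappa_kBT * kBT_joules(temperature)
}

#' Stationary area variance implied by a fluctuation modulus
#'
#' Inverts the fluctuation relation K_A = kB T A0 / var(A): for a tensionless
#' membrane of mean area `area0` at temperature `temperature` with area
#' expansion modulus `ka_mNm`, the equilibrium variance of the projected area
#' is kB T A0 / K_A.
#'
#' @param ka_mNm Area expansion modulus in mN/m.
#' @param area0_nm2 Mean (tensionless) membrane area in nm2.
#' @param temperature Absolute temperature in K.
#' @return Variance of the instantaneous area, in nm4.
#' @export
#' @examples
#' area_variance_nm4(240, 130, 303.15) # about 2.27 nm4
area_variance_nm4 <- function(ka_mNm, area0_nm2, temperature) {
  stopifnot(ka_mNm > 0, area0_nm2 > 0)
  # kBT [J] * A0 [nm2 -> m2: 1e-18] / K_A [mN/m -> N/m: 1e-3] gives m4;
  # 1 m4 = 1e36 nm4, net factor 1e21.
  kBT_joules(temperature) * area0_nm2 / ka_mNm * 1e21
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
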