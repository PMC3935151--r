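# Gas constant in L atm mol^-1 K^-1
.R_GAS_L_ATM <- 0.0820573661

#' Microcosm and flux-chamber geometry
#'
#' Bundle the physical dimensions of the incubation vessels used to
#' area-normalize fluxes. Defaults describe the standard microcosm setup:
#' an 11 mm diameter mat core in a 14 mL serum vial with 4 mL site water,
#' and a 1.5 L benthic flux chamber. The mat area enclosed by the flux
#' chamber is site-specific and has no default; [dic_flux()] errors until
#' it is supplied.
#'
#' @param vial_volume_mL Total serum-vial volume (mL).
#' @param liquid_volume_mL Liquid phase volume in the vial (mL); the
#'   headspace is `vial_volume_mL - liquid_volume_mL`.
#' @param core_diameter_mm Diameter of the mat core (mm).
#' @param chamber_volume_L Flux-chamber water volume (L).
#' @param chamber_area_m2 Mat area enclosed by the flux chamber (m^2), or
#'   `NA` if unknown.
#' @param temperature_K Headspace temperature (K) for ideal-gas conversion.
#' @param pressure_atm Headspace pressure (atm).
#'
#' @return A list of class `mat_geometry`.
#' @examples
#' geo <- mat_geometry()
#' core_area(geo$core_diameter_mm)
#' @export
mat_geometry <- function(vial_volume_mL = 14,
                         liquid_volume_mL = 4,
                         core_diameter_mm = 11,
                         chamber_volume_L = 1.5,
                         chamber_area_m2 = NA_real_,
                         temperature_K = 298.15,
                         pressure_atm = 1) {
  stopifnot(vial_volume_mL > 0, liquid_volume_mL > 0,
            core_diameter_mm > 0, chamber_volume_L > 0,
            temperature_K > 0, pressure_atm > 0)
  if (vial_volume_mL <= liquid_volume_mL) {
    stop("headspace volume (vial - liquid) must be positive", call. = FALSE)
  }
  if (!is.na(chamber_area_m2) && chamber_area_m2 <= 0) {
    stop("`chamber_area_m2` must be positive", call. = FALSE)
  }
  structure(
    list(
      vial_volume_mL = vial_volume_mL,
      liquid_volume_mL = liquid_volume_mL,
      headspace_mL = vial_volume_mL - liquid_volume_mL,
      core_diameter_mm = core_diameter_mm,
      chamber_volume_L = chamber_volume_L,
      chamber_area_m2 = chamber_area_m2,
      temperature_K = temperature_K,
      pressure_atm = pressure_atm
    ),
    class = "mat_geometry"
  )
}

#' Cross-sectional area of a mat core
#'
#' @param diameter_mm Core diameter in millimetres.
#' @return Area in m^2 (11 mm -> 9.503e-5 m^2).
#' @examples
#' core_area(11)
#' @export
core_area <- function(diameter_mm) {
  if (!is.numeric(diameter_mm) || any(diameter_mm <= 0)) {
    stop("`diameter_mm` must be positive", call. = FALSE)
  }
  pi * (diameter_mm / 2000)^2
}

#' Moles of gas in a vial headspace from a mixing ratio
#'
#' Ideal-gas conversion of a headspace mixing ratio (ppm by volume) to an
#' absolute amount.
#'
#' @param ppm Mixing ratio in parts per million by volume.
#' @param headspace_mL Headspace volume (mL).
#' @param T_K Temperature (K).
#' @param P_atm Pressure (atm).
#' @return Amount in mmol: `ppm * 1e-6 * P V / (R T)` with V in litres.
#' @examples
#' headspace_amount(5000, 10) # ~2.04e-3 mmol H2 in a 10 mL headspace
#' @export
headspace_amount <- function(ppm, headspace_mL, T_K = 298.15, P_atm = 1) {
  if (any(T_K <= 0)) stop("`T_K` must be positive", call. = FALSE)
  if (any(headspace_mL <= 0) || any(P_atm <= 0)) {
    stop("headspace volume and pressure must be positive", call. = FALSE)
  }
  if (any(ppm < 0)) stop("`ppm` must be non-negative", call. = FALSE)
  total_mmol <- 1000 * P_atm * (headspace_mL / 1000) / (.R_GAS_L_ATM * T_K)
  ppm * 1e-6 * total_mmol
}

# Inverse of headspace_amount: mixing ratio producing `mmol` in the headspace.
headspace_ppm <- function(mmol, headspace_mL, T_K = 298.15, P_atm = 1) {
  total_mmol <- 1000 * P_atm * (headspace_mL / 1000) / (.R_GAS_L_ATM * T_K)
  1e6 * mmol / total_mmol
}
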