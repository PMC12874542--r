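# Unit conventions: all lengths in nm, volumes in nm^3, refractive indices
# dimensionless. Particle diameters are carried in um in tables and converted
# to nm only at the shift-reporting boundary. All Da<->g and cm^3<->nm^3
# conversions live in this file and nowhere else.

DALTON_GRAMS <- 1.66054e-24 # g per Da
NM3_PER_CM3 <- 1e21

#' Per-molecule volume from molecular mass and bulk density
#'
#' Converts a molecular mass and a bulk mass density into the volume
#' occupied by a single molecule, in cubic nanometers. Used for the
#' anchor-block correction, where the embedded polystyrene block of each
#' grafted diblock copolymer adds its bulk volume to the substrate bead.
#'
#' @param mass_kda molecular mass in kDa.
#' @param density_g_cm3 bulk mass density in g/cm^3.
#' @return volume of one molecule in nm^3.
#' @examples
#' molecular_volume(3.8, 1.05) # PS anchor block, about 6.0 nm^3
#' @export
molecular_volume <- function(mass_kda, density_g_cm3) {
  stopifnot(mass_kda >= 0, density_g_cm3 > 0)
  mass_kda * 1000 * DALTON_GRAMS / density_g_cm3 * NM3_PER_CM3
}

#' Mass concentration to molecular number density
#'
#' Converts a polymer mass concentration (g/cm^3) into a number density in
#' molecules per nm^3, given the molecular weight. This is the internal
#' concentration unit for refractometry: the volume fraction of polymer is
#' then simply number density times per-molecule specific volume.
#'
#' @param c_mass_g_cm3 mass concentration in g/cm^3.
#' @param mw_kda molecular weight in kDa.
#' @return number density in molecules/nm^3.
#' @export
number_density <- function(c_mass_g_cm3, mw_kda) {
  stopifnot(all(c_mass_g_cm3 >= 0), mw_kda > 0)
  c_mass_g_cm3 / (mw_kda * 1000 * DALTON_GRAMS * NM3_PER_CM3)
}

#' Convert percent weight/volume to g/cm^3
#'
#' 40% w/v means 40 g per 100 mL, i.e. 0.40 g/cm^3.
#'
#' @param percent concentration in % w/v.
#' @return concentration in g/cm^3.
#' @export
percent_wv_to_g_cm3 <- function(percent) {
  stopifnot(all(percent >= 0))
  percent / 100
}
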