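# Dissolved organic matter: production, adsorption equilibrium, leaching.

#' DOM adsorption coefficient
#'
#' Semi-empirical linear dependence on pH and clay: more clay binds DOM,
#' lower pH also immobilizes it.
#'
#' @param pH soil pH.
#' @param fClay clay fraction (0-1).
#' @param aKD,bKD,cKD regression coefficients (m^3 kg^-1 soil).
#' @return adsorption coefficient K_D, m^3 kg^-1 soil.
#' @export
dom_adsorption_coefficient <- function(pH, fClay, aKD = 0.001226,
                                       bKD = 0.000212, cKD = 0.00374) {
  aKD - bKD * pH + cKD * fClay
}

#' Daily DOM production
#'
#' Root exudation plus a fraction of yesterday's total respiration (high
#' biological activity solubilizes organic matter); the respiration-linked
#' share is drawn from the SOM pool.
#'
#' @param C_exud exudation input, g C m^-3 day^-1.
#' @param f_DOM fraction of total respiration appearing as DOM.
#' @param R_tot total respiration of the previous day, g C m^-3 day^-1.
#' @return DOM production, g C m^-3 day^-1.
#' @export
dom_production <- function(C_exud, f_DOM, R_tot) {
  stopifnot(C_exud >= 0, f_DOM >= 0, R_tot >= 0)
  C_exud + f_DOM * R_tot
}

#' DOM leaching for one day
#'
#' The DOM pool equilibrates instantaneously between adsorbed and dissolved
#' phases (ratio K_D times the soil mass per unit volume); the dissolved
#' concentration in the layer water leaves with the draining water, capped
#' at the available pool.
#'
#' @param DOM DOM pool, g C m^-3.
#' @param SW layer water, l m^-3.
#' @param drainage draining water, l m^-3 day^-1.
#' @param K_D adsorption coefficient, m^3 kg^-1.
#' @param D_b bulk density, g cm^-3.
#' @return leached carbon, g C m^-3 day^-1.
#' @export
leach_dom <- function(DOM, SW, drainage, K_D, D_b) {
  if (DOM <= 0 || SW <= 0 || drainage <= 0) return(0)
  dissolved_frac <- 1 / (1 + K_D * 1000 * D_b)  # D_b g cm^-3 -> kg m^-3
  conc <- DOM * dissolved_frac / SW             # g C per l of soil water
  min(DOM, conc * drainage)
}
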