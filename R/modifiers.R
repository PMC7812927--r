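# Growth-rate modifiers: moisture, temperature, pH, C:N, recalcitrance.
# All modifiers are dimensionless fractions in [0, 1] applied
# multiplicatively to g_max (or, optionally, by the most-limiting rule).

#' Overall moisture modifier
#'
#' Hump-shaped response to relative saturation: activity rises with moisture
#' up to half saturation and stays optimal above it (waterlogging is handled
#' per pore class, not here). Continuous at V/P_vol = 0.5.
#'
#' @param V water volume, l m^-3.
#' @param P_vol pore volume, l m^-3. Zero pore volume means no habitat:
#'   modifier 0.
#' @return modifier in [0, 1].
#' @export
moisture_modifier_total <- function(V, P_vol) {
  if (P_vol <= 0) return(0)
  x <- V / P_vol
  stopifnot(x >= 0, x <= 1 + 1e-9)
  if (x < 0.5) 4 * x * (1 - x) else 1
}

#' Per-class moisture modifiers
#'
#' Biotic activity concentrates at the wet/dry interface: saturated classes
#' (below the partially filled one) get 0, the partial class gets the
#' aerated-share weighting, the class one size above gets the complementary
#' water-share weighting (it is moist but not yet dry), and classes further
#' above are fully dry (0). With `eq16_alt = TRUE` the class above uses the
#' aerated-share weighting instead.
#'
#' @param alloc output of [allocate_water_to_classes()].
#' @param m_tot overall moisture modifier from [moisture_modifier_total()].
#' @param eq16_alt alternative weighting for the class above the partial one.
#' @return named numeric of per-class modifiers in [0, 1].
#' @export
moisture_modifier_by_class <- function(alloc, m_tot, eq16_alt = FALSE) {
  m <- setNames(numeric(5), PORE_CLASSES)
  j <- alloc$partial
  if (is.na(j)) return(m)  # fully saturated: no aerated habitat
  W <- alloc$water[[j]]; A <- alloc$aerated[[j]]
  tot <- W + A
  if (tot <= 0) return(m)
  m[j] <- A / tot * m_tot
  if (j < 5) {
    m[j + 1] <- if (eq16_alt) A / tot * m_tot else W / tot * m_tot
  }
  m
}

#' Temperature modifier on growth
#'
#' Q10-shaped rise from the minimum temperature to the optimum, plateau at 1
#' between the optimum and the maximum, zero outside the tolerated range.
#'
#' @param T_C temperature, degrees C.
#' @param T_min,T_opt,T_max cardinal temperatures (T_min < T_opt < T_max).
#' @param Q Q10 factor.
#' @return modifier in [0, 1].
#' @export
temperature_modifier <- function(T_C, T_min = 0, T_opt = 25, T_max = 40,
                                 Q = 2) {
  stopifnot(T_min < T_opt, T_opt < T_max)
  if (T_C < T_min || T_C >= T_max) return(0)
  if (T_C < T_opt) Q^((T_C - T_opt) / 10) else 1
}

#' Temperature factor on respiration
#'
#' The same Q10 function as growth but without the plateau, so above the
#' optimum respiration keeps rising while growth does not and biomass can
#' decline. Applied over the whole temperature axis (maintenance respiration
#' does not switch off at the growth limits).
#'
#' @inheritParams temperature_modifier
#' @return positive factor (1 at the optimum; may exceed 1).
#' @export
respiration_temperature_factor <- function(T_C, T_opt = 25, Q = 2) {
  Q^((T_C - T_opt) / 10)
}

#' pH modifier for microbes
#'
#' Growth falls off tenfold per pH unit beyond a threshold: above 8 for
#' fungi, below 3 for bacteria (thresholds applied at one-decimal
#' precision); otherwise 1, always clamped to at most 1.
#'
#' @param pH soil pH.
#' @param guild "fungi" or "bacteria".
#' @return modifier in (0, 1].
#' @export
ph_modifier_microbe <- function(pH, guild = c("fungi", "bacteria")) {
  guild <- match.arg(guild)
  m <- if (guild == "fungi" && pH >= 8.1) {
    1 / ((pH - 8) * 10)
  } else if (guild == "bacteria" && pH <= 2.9) {
    1 / ((3 - pH) * 10)
  } else 1
  min(1, m)
}

#' pH-dependent maximum growth rate of ecosystem engineers
#'
#' Engineers (earthworm-type fauna) cannot grow below pH 3, ramp linearly to
#' their full maximum growth rate at pH 5, and are unaffected above.
#'
#' @param g_max maximum growth rate, g C g C^-1 day^-1.
#' @param pH soil pH.
#' @return effective maximum growth rate.
#' @export
ph_gmax_engineers <- function(g_max, pH) {
  stopifnot(g_max >= 0)
  if (pH < 3) 0
  else if (pH < 5) (g_max / 2) * (pH - 3)
  else g_max
}

#' C:N modifier on litter/SOM consumption
#'
#' Consumers with a low C:N ratio are nitrogen-limited on high-C:N
#' substrate; the power p_mCN (0-1) sets the sensitivity.
#'
#' @param CN_consumer consumer C:N ratio.
#' @param CN_substrate substrate C:N ratio.
#' @param p_mCN sensitivity exponent in [0, 1].
#' @return modifier in (0, 1].
#' @export
cn_modifier <- function(CN_consumer, CN_substrate, p_mCN) {
  stopifnot(CN_consumer > 0, CN_substrate > 0, p_mCN >= 0, p_mCN <= 1)
  min(1, (CN_consumer / CN_substrate)^p_mCN)
}

#' Recalcitrance modifier on litter/SOM consumption
#'
#' Linear (not power) penalty so that fully recalcitrant substrate is not
#' consumed at all when the sensitivity p_mRec is 1 and consumption is
#' unaffected when it is 0.
#'
#' @param Rec recalcitrant fraction of the substrate (0-1).
#' @param p_mRec sensitivity in [0, 1].
#' @return modifier in [0, 1].
#' @export
recalcitrance_modifier <- function(Rec, p_mRec) {
  stopifnot(Rec >= 0, Rec <= 1, p_mRec >= 0, p_mRec <= 1)
  min(1, 1 - p_mRec * Rec)
}

#' Combine growth modifiers
#'
#' Default is full multiplicativity; the "most limiting" mode instead takes
#' the minimum component.
#'
#' @param m_T,m_pH,m_CN,m_rec,m_H2O component modifiers in [0, 1].
#' @param mode "product" or "min".
#' @return combined modifier in [0, 1].
#' @export
combine_modifiers <- function(m_T = 1, m_pH = 1, m_CN = 1, m_rec = 1,
                              m_H2O = 1, mode = c("product", "min")) {
  mode <- match.arg(mode)
  comps <- c(m_T, m_pH, m_CN, m_rec, m_H2O)
  stopifnot(all(comps >= 0), all(comps <= 1))
  if (mode == "product") prod(comps) else min(comps)
}
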