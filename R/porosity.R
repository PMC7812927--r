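# Pore-structure module: particle density, total porosity, aggregation,
# engineer burrows, and the daily five-class pore-size distribution.

#' Soil particle density from organic-matter content
#'
#' Mixes mineral particle density (2.65 g cm^-3) and organic particle
#' density (1.35 g cm^-3) harmonically by mass.
#'
#' @param pct_SOM soil organic matter content, mass percent (0-100).
#' @param D_m mineral particle density, g cm^-3.
#' @param D_SOM organic particle density, g cm^-3.
#' @return particle density D_s, g cm^-3.
#' @export
#' @examples
#' particle_density(3) # ~2.576
particle_density <- function(pct_SOM, D_m = 2.65, D_SOM = 1.35) {
  if (any(pct_SOM < 0 | pct_SOM > 100)) {
    stop("pct_SOM must be between 0 and 100")
  }
  100 / (pct_SOM / D_SOM + (100 - pct_SOM) / D_m)
}

#' Total porosity from bulk and particle density
#'
#' @param D_s particle density, g cm^-3.
#' @param D_b bulk density, g cm^-3; must satisfy 0 < D_b < D_s.
#' @return total porosity, percent of soil volume.
#' @export
total_porosity_percent <- function(D_s, D_b) {
  if (any(D_b <= 0) || any(D_b >= D_s)) {
    stop("bulk density D_b must satisfy 0 < D_b < D_s")
  }
  (D_s - D_b) / D_s * 100
}

#' Aggregated fraction of SOM
#'
#' Fraction (0-1) of the SOM pool bound in aggregates, driven by fungal and
#' mycorrhizal biomass. Returns 0 when the SOM pool is empty (degenerate
#' case: no matrix to aggregate).
#'
#' @param B_fung,B_myc fungal and mycorrhizal biomass, g C m^-3.
#' @param B_SOM SOM pool, g C m^-3.
#' @param c_agg empirical scaling constant (default 10).
#' @return aggregation fraction in [0, 1].
#' @export
aggregation_fraction <- function(B_fung, B_myc, B_SOM, c_agg = 10) {
  if (B_SOM <= 0) return(0)
  min(1, c_agg * (B_fung + B_myc) / B_SOM)
}

#' Aggregation porosity
#'
#' Extra pore volume created by aggregation, proportional to the aggregated
#' SOM mass and capped: aggregation can add at most ~2% porosity
#' (20 l m^-3 by default), beyond which further aggregation restructures
#' rather than creates pore space.
#'
#' @param Ag aggregation fraction (0-1).
#' @param B_SOM SOM pool, g C m^-3.
#' @param k_agg pore volume per unit aggregated C, l g C^-1 m^-3 (default 2).
#' @param PV_Ag_cap cap on aggregation porosity, l m^-3 (default 20).
#' @return aggregation pore volume, l m^-3.
#' @export
aggregation_porosity <- function(Ag, B_SOM, k_agg = 2, PV_Ag_cap = 20) {
  stopifnot(Ag >= 0, Ag <= 1)
  min(PV_Ag_cap, k_agg * Ag * B_SOM)
}

#' Daily burrow-volume update
#'
#' Burrow (biopore) volume tracks engineer biomass up to a maximum, but
#' abandoned burrows collapse only slowly: existing biopore volume decays
#' geometrically with a mean lifespan of ten years (rate 1/3650 per day).
#' The volume is the larger of the biomass-supported volume and the decayed
#' previous volume.
#'
#' @param PV_B_prev previous biopore volume, l m^-3.
#' @param B_eng engineer biomass, g C m^-3.
#' @param VE_ratio burrow volume per unit engineer biomass, l g C^-1.
#' @param PV_Bmax maximum biopore volume, l m^-3.
#' @param tPV_B daily burrow turnover rate (default 1/3650).
#' @return biopore volume, l m^-3.
#' @export
burrow_volume_update <- function(PV_B_prev, B_eng, VE_ratio = 0.05,
                                 PV_Bmax = 50, tPV_B = 1 / 3650) {
  max(min(PV_Bmax, VE_ratio * B_eng), PV_B_prev * (1 - tPV_B))
}

#' Five-class pore-size distribution
#'
#' Distributes total porosity over the five size classes. Macroporosity is
#' textural plus biopores; a fraction (1 - f_PV) of the biopore volume is
#' compensated by compaction of mesopores (engineers push soil aside and
#' produce dense casts). Aggregation moves half of the affected textural
#' mesoporosity into micro- and bacterial pores (split equally) and adds the
#' (capped) aggregation porosity, also split equally between those two
#' classes. Inaccessible porosity is constant. Classes are clamped at zero;
#' any clamped deficit is reported.
#'
#' @param Ag aggregation fraction (0-1).
#' @param PV_B biopore volume, l m^-3.
#' @param B_SOM SOM pool, g C m^-3.
#' @param pv_text named numeric of five textural pore volumes, l m^-3
#'   (names as in [PORE_CLASSES]).
#' @param f_PV fraction of biopore volume that adds to total porosity.
#' @param k_agg,PV_Ag_cap see [aggregation_porosity()].
#' @return list with `pv` (named volumes, l m^-3), `PV_Ag` (capped
#'   aggregation porosity actually added), and `clamped` (total deficit
#'   removed by the zero clamp, l m^-3).
#' @export
pore_size_distribution <- function(Ag, PV_B, B_SOM, pv_text, f_PV = 0.5,
                                   k_agg = 2, PV_Ag_cap = 20) {
  stopifnot(Ag >= 0, Ag <= 1, PV_B >= 0)
  pv_text <- pv_text[PORE_CLASSES]
  PV_Ag <- aggregation_porosity(Ag, B_SOM, k_agg, PV_Ag_cap)
  agg_half <- PV_Ag / 2                       # added to micro and bacterial
  meso_shift <- (Ag / 4) * pv_text[["meso"]]  # each, from mesopore conversion

  raw <- c(
    inaccessible = pv_text[["inaccessible"]],
    bacterial    = pv_text[["bacterial"]] + agg_half + meso_shift,
    micro        = pv_text[["micro"]] + agg_half + meso_shift,
    meso         = pv_text[["meso"]] - (1 - f_PV) * PV_B -
                   (Ag / 2) * pv_text[["meso"]],
    macro        = pv_text[["macro"]] + PV_B
  )
  clamped <- -sum(pmin(raw, 0))
  if (clamped > 1e-12) {
    warning(sprintf("pore class clamped at zero (deficit %.4g l m^-3)",
                    clamped))
  }
  list(pv = pmax(raw, 0), PV_Ag = PV_Ag, clamped = clamped)
}

#' Fraction of soil surface occupied by macropores
#'
#' Macropores are assumed vertical and cylindrical, spanning the layer, so
#' their areal fraction equals their volumetric fraction.
#'
#' @param PV_macro macropore volume, l m^-3.
#' @return surface-area fraction in [0, 1].
#' @export
macropore_surface_fraction <- function(PV_macro) {
  min(1, max(0, PV_macro / 1000))
}

#' Textural pore-class fractions and matrix infiltration from clay content
#'
#' A simple linear pedotransfer rule: more clay shifts porosity from meso-
#' and macropores towards inaccessible, bacterial and micropores, and slows
#' matrix infiltration. The five class coefficients sum to one for any clay
#' fraction.
#'
#' @param fClay clay content as a fraction (0-1).
#' @return list with `frac` (named class fractions of total porosity,
#'   summing to 1) and `I_maxMat` (maximal matrix infiltration, mm day^-1).
#' @export
texture_hydraulics <- function(fClay) {
  stopifnot(fClay >= 0, fClay <= 0.45)
  frac <- c(
    inaccessible = 0.05 + 0.50 * fClay,
    bacterial    = 0.10 + 0.30 * fClay,
    micro        = 0.30 + 0.40 * fClay,
    meso         = 0.45 - 1.00 * fClay,
    macro        = 0.10 - 0.20 * fClay
  )
  list(frac = frac, I_maxMat = 55 * (1 - 2 * fClay))
}
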