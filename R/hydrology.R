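# Hydrology module: daily single-layer water balance with macropore bypass.
#
# Unit bridging: precipitation in mm day^-1 over 1 m^2 equals l m^-2 day^-1;
# dividing by the layer thickness (m) converts to l m^-3 day^-1, the unit of
# the pore volumes. `layer_thickness` therefore appears in every mm <-> l
# m^-3 conversion below.

#' Net precipitation
#'
#' @param P precipitation, mm day^-1.
#' @param E evapotranspiration, mm day^-1.
#' @return net precipitation, mm day^-1 (negative values draw down storage).
#' @export
net_precipitation <- function(P, E) {
  stopifnot(all(P >= 0), all(E >= 0))
  P - E
}

#' Maximal infiltration rate through macropores
#'
#' Macropore volume (not limiting at the daily scale) plus the infiltration
#' capacity of the layer in which the macropores end -- for the single-layer
#' configuration, the configured subsoil drainage capacity.
#'
#' @param PV_macro macropore volume, l m^-3.
#' @param layer_thickness layer thickness, m.
#' @param I_maxMat_below infiltration capacity of the underlying layer,
#'   mm day^-1.
#' @return macropore infiltration capacity, mm day^-1.
#' @export
macropore_capacity <- function(PV_macro, layer_thickness, I_maxMat_below) {
  stopifnot(PV_macro >= 0, I_maxMat_below >= 0)
  PV_macro * layer_thickness + I_maxMat_below
}

#' Partition net precipitation into runoff, matrix fill and macropore bypass
#'
#' Runoff occurs only when net precipitation exceeds the combined matrix and
#' macropore capacity. Of the infiltrating water, the matrix receives at
#' most its free pore space, its infiltration capacity and the non-macropore
#' share of the rain; the remainder bypasses through macropores. The three
#' components always sum to max(P_net, 0).
#'
#' @param P_net net precipitation, mm day^-1.
#' @param I_maxMat matrix infiltration capacity, mm day^-1.
#' @param I_maxPor macropore infiltration capacity, mm day^-1.
#' @param SA_macro macropore surface-area fraction (0-1).
#' @param PV_tot total pore volume, l m^-3.
#' @param SW current layer water, l m^-3.
#' @param layer_thickness layer thickness, m.
#' @return named numeric: runoff, matrix_fill, bypass (all mm day^-1).
#' @export
partition_water <- function(P_net, I_maxMat, I_maxPor, SA_macro,
                            PV_tot, SW, layer_thickness) {
  if (P_net <= 0) {
    return(c(runoff = 0, matrix_fill = 0, bypass = 0))
  }
  runoff <- max(0, P_net - (I_maxPor + I_maxMat))
  Pn <- P_net - runoff
  free_mm <- max(0, PV_tot - SW) * layer_thickness
  fill <- max(0, min(free_mm, I_maxMat * (1 - SA_macro), Pn * (1 - SA_macro)))
  c(runoff = runoff, matrix_fill = fill, bypass = Pn - fill)
}

#' Field capacity of a pore state
#'
#' Water content with macropores (and, by default, mesopores) drained.
#'
#' @param pv named five-class pore volumes, l m^-3.
#' @param meso_drains do mesopores drain freely above field capacity?
#' @return field capacity, l m^-3.
#' @export
field_capacity <- function(pv, meso_drains = TRUE) {
  fc <- pv[["inaccessible"]] + pv[["bacterial"]] + pv[["micro"]]
  if (!meso_drains) fc <- fc + pv[["meso"]]
  fc
}

#' One day of the layer water balance
#'
#' Positive net precipitation is partitioned by [partition_water()]; matrix
#' water above field capacity spills (spilling bucket) and joins the
#' macropore bypass as drainage. Negative net precipitation (E > P) extracts
#' water from storage down to the wilting point (the inaccessible pore
#' volume). Drainage is computed by exact mass balance (bypass + matrix
#' spill); the literal surface-area drainage expression is returned alongside
#' as `drainage_eq_literal` for comparison only.
#'
#' @param SW layer water at the start of the day, l m^-3.
#' @param P,E precipitation and evapotranspiration, mm day^-1.
#' @param pv named five-class pore volumes, l m^-3.
#' @param I_maxMat matrix infiltration capacity, mm day^-1.
#' @param subsoil_imax infiltration capacity of the underlying layer,
#'   mm day^-1.
#' @param layer_thickness layer thickness, m.
#' @param meso_drains see [field_capacity()].
#' @return list: SW (end of day, l m^-3), runoff and matrix_fill and bypass
#'   (mm day^-1), drainage (l m^-3 day^-1), et_actual (l m^-3 day^-1),
#'   drainage_eq_literal (mm day^-1, diagnostic).
#' @export
water_step <- function(SW, P, E, pv, I_maxMat, subsoil_imax,
                       layer_thickness, meso_drains = TRUE) {
  PV_tot <- sum(pv)
  P_net <- net_precipitation(P, E)
  SA <- macropore_surface_fraction(pv[["macro"]])
  runoff <- 0; fill <- 0; bypass <- 0; spill <- 0; et <- 0
  if (P_net >= 0) {
    I_maxPor <- macropore_capacity(pv[["macro"]], layer_thickness,
                                   subsoil_imax)
    part <- partition_water(P_net, I_maxMat, I_maxPor, SA, PV_tot, SW,
                            layer_thickness)
    runoff <- part[["runoff"]]; fill <- part[["matrix_fill"]]
    bypass <- part[["bypass"]]
    SW <- SW + fill / layer_thickness
    fc <- field_capacity(pv, meso_drains)
    spill <- max(0, SW - fc)
    SW <- SW - spill
  } else {
    demand <- -P_net / layer_thickness
    wp <- pv[["inaccessible"]]
    et <- min(demand, max(0, SW - wp))
    SW <- SW - et
  }
  # porosity may have shrunk below current storage: route the excess down
  if (SW > PV_tot) {
    spill <- spill + (SW - PV_tot)
    SW <- PV_tot
  }
  Pn <- max(P_net, 0) - runoff
  free_mm <- max(0, PV_tot - SW) * layer_thickness
  lit <- Pn * SA + Pn -
    min(free_mm, I_maxMat * (1 - SA), Pn * (1 - SA))
  list(SW = SW, runoff = runoff, matrix_fill = fill, bypass = bypass,
       drainage = bypass / layer_thickness + spill, et_actual = et,
       drainage_eq_literal = if (P_net > 0) lit else 0)
}

#' Allocate layer water across pore-size classes
#'
#' Smallest-first filling (mimicking matric-potential ordering): classes
#' fill in the order inaccessible, bacterial, micro, meso, macro, so at most
#' one class is partially filled and all others are either saturated or
#' dry. `partial` is the first not-completely-full class (NA when the soil
#' is saturated).
#'
#' @param SW layer water, l m^-3; values above the total pore volume are
#'   clipped with a warning.
#' @param pv named five-class pore volumes, l m^-3.
#' @return list: `water` and `aerated` (named l m^-3 per class, summing to
#'   SW and PV_tot - SW), `partial` (index into [PORE_CLASSES] or NA).
#' @export
allocate_water_to_classes <- function(SW, pv) {
  pv <- pv[PORE_CLASSES]
  PV_tot <- sum(pv)
  if (SW > PV_tot + 1e-9) {
    warning("SW exceeds total pore volume; clipping")
    SW <- PV_tot
  }
  SW <- min(max(SW, 0), PV_tot)
  water <- setNames(numeric(5), PORE_CLASSES)
  rest <- SW
  partial <- NA_integer_
  for (i in seq_along(pv)) {
    water[i] <- min(rest, pv[i])
    rest <- rest - water[i]
    if (is.na(partial) && water[i] < pv[i]) partial <- i
  }
  list(water = water, aerated = pv - water, partial = partial)
}
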