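# Model state: pools, litter/SOM quality, biopore volume, water, cumulative
# diagnostics; initialization and the carbon-conservation diagnostic.

#' Initialize model state from a configuration
#'
#' Pools are set to the configured initial values; the biopore volume to the
#' engineer-supported volume; the pore-size distribution follows from
#' initial aggregation and biopores; water starts at field capacity unless
#' `hydro$SW0` is given.
#'
#' @param config an `sfw_config` from [site_config()].
#' @return list of class `sfw_state`: `pools` (named, g C m^-3), litter/SOM
#'   quality (CN_lit, Rec_lit, CN_SOM, Rec_SOM), `PV_B` (l m^-3), `SW`
#'   (l m^-3), `R_tot_prev` (g C m^-3 day^-1), cumulative diagnostics
#'   CO2_cum, DOM_leached_cum, bioturb_export_cum, inputs_cum, and `day`.
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "sfw_config"))
  p <- config$pools0
  q <- config$quality
  PV_B <- min(config$pores$PV_Bmax,
              config$pores$VE_ratio * p[["engineers"]])
  ps <- pore_state(config, p, PV_B)
  SW <- config$hydro$SW0
  if (is.na(SW)) SW <- field_capacity(ps$pv, config$pores$meso_drains)
  SW <- min(SW, sum(ps$pv))
  structure(list(pools = p, CN_lit = q$CN_lit, Rec_lit = q$Rec_lit,
                 CN_SOM = q$CN_SOM, Rec_SOM = q$Rec_SOM, PV_B = PV_B,
                 SW = SW, R_tot_prev = 0, CO2_cum = 0, DOM_leached_cum = 0,
                 bioturb_export_cum = 0, inputs_cum = 0, day = 0L),
            class = "sfw_state")
}

# current pore-size distribution for a pool vector and biopore volume
pore_state <- function(config, pools, PV_B) {
  po <- config$pores
  Ag <- aggregation_fraction(pools[["fungi"]], pools[["mycorrhiza"]],
                             pools[["SOM"]], po$c_agg)
  psd <- pore_size_distribution(Ag, PV_B, pools[["SOM"]],
                                config$derived$pv_text, po$f_PV, po$k_agg,
                                po$PV_Ag_cap)
  c(psd, list(Ag = Ag))
}

#' Total-carbon conservation diagnostic
#'
#' Sum of all pools plus the cumulative sinks (respired CO2, leached DOM,
#' bioturbation export) minus cumulative external inputs. Constant over a
#' simulation up to floating-point tolerance: every flux is either between
#' tracked pools or recorded in a cumulative term.
#'
#' @param state an `sfw_state`.
#' @return total carbon, g C m^-3.
#' @export
total_carbon <- function(state) {
  sum(state$pools) + state$CO2_cum + state$DOM_leached_cum +
    state$bioturb_export_cum - state$inputs_cum
}
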