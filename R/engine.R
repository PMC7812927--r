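# Simulation engine: the daily calculation order, the conserving
# forward-Euler update, and the full run loop.
#
# The daily sequence is: (a) pore-size distribution and macropore surface
# area, (b) water balance and per-class water allocation, (c) DOM
# production and leaching, (d) per-link substrate accessibility,
# (e) growth-rate modifiers, (f) carbon fluxes for all pools, (g) conserving
# Euler update, (h) litter/SOM quality update, (i) engineering effects
# (burrow volume, bioturbation export), (j) structural-change hook (none by
# default). `daily_step()` composes the documented module operations in
# exactly this order; `run_simulation()` executes the same algorithm in
# compiled code.

TRACE_COLS <- c("day", POOLS, "CO2_cum", "DOM_leached_cum",
                "bioturb_export_cum", "inputs_cum", "SW", "runoff",
                "matrix_fill", "bypass", "et_actual", "drainage", "leach",
                "R_tot", paste0("pv_", PORE_CLASSES), "PV_B", "Ag",
                "CN_lit", "Rec_lit", "CN_SOM", "Rec_SOM",
                "resp_bacteria", "resp_fungi", "resp_mycorrhiza",
                "cons_litter_bacteria", "cons_SOM_bacteria",
                "cons_litter_engineers")

#' Conserving forward-Euler update with per-pool flux limiting
#'
#' Pools are advanced one day explicitly. If a pool's outgoing fluxes would
#' drive it negative, all of them are scaled by available/required; the
#' scaling factors are returned so the caller can scale the matched gains of
#' the receiving pools, keeping the update carbon-conserving.
#'
#' @param pools named pool vector, g C m^-3.
#' @param inflow,outflow per-pool flux totals, g C m^-3 day^-1 (outflows
#'   unscaled).
#' @return list: `pools` (updated, using the scaled outflows), `lambda`
#'   (per-pool outflow scaling in (0, 1]).
#' @export
flux_limited_euler <- function(pools, inflow, outflow) {
  lambda <- ifelse(outflow > pools & outflow > 0, pools / outflow, 1)
  lambda <- pmin(pmax(lambda, 0), 1)
  new <- pools + inflow - lambda * outflow
  list(pools = pmax(new, 0), lambda = lambda)
}

#' Advance the model state by one day
#'
#' Reference implementation composing the module operations in the daily
#' calculation order (see the package vignette). Identical, up to
#' floating-point roundoff, to one day of the compiled engine used by
#' [run_simulation()].
#'
#' @param state an `sfw_state`.
#' @param clim one climate day: list/row with `precip_mm`, `et_mm`,
#'   `temp_C`.
#' @param config an `sfw_config`.
#' @return list: `state` (advanced), `record` (named numeric of the daily
#'   trace row).
#' @export
daily_step <- function(state, clim, config) {
  p <- state$pools
  tx <- config$texture
  th <- tx$layer_thickness

  # (a) pore structure from current biology
  ps <- pore_state(config, p, state$PV_B)
  pv <- ps$pv

  # (b) water balance and allocation
  ws <- water_step(state$SW, clim$precip_mm, clim$et_mm, pv,
                   config$hydro$I_maxMat, config$hydro$subsoil_imax, th,
                   config$pores$meso_drains)
  SW <- ws$SW
  alloc <- allocate_water_to_classes(SW, pv)

  # (c) DOM production from yesterday's activity, then leaching
  sol <- min(config$dom$f_DOM * state$R_tot_prev, p[["SOM"]])
  p[["SOM"]] <- p[["SOM"]] - sol
  p[["DOM"]] <- p[["DOM"]] + sol + config$inputs$exudation
  inputs_cum <- state$inputs_cum + config$inputs$exudation
  K_D <- dom_adsorption_coefficient(tx$pH, tx$fClay, config$dom$aKD,
                                    config$dom$bKD, config$dom$cKD)
  leach <- leach_dom(p[["DOM"]], SW, ws$drainage, K_D, tx$D_b)
  p[["DOM"]] <- p[["DOM"]] - leach
  leach_cum <- state$DOM_leached_cum + leach

  # (d, e) moisture field entering accessibility and modifiers
  if (config$modifiers$use_H2O) {
    m_tot_H2O <- moisture_modifier_total(SW, sum(pv))
    m_class <- moisture_modifier_by_class(alloc, m_tot_H2O,
                                          config$modifiers$eq16_alt)
    denom <- sum(pv[2:5])
    m_lit <- if (denom > 0) sum(pv[2:5] * m_class[2:5]) / denom else 0
  } else {
    m_class <- setNames(rep(1, 5), PORE_CLASSES)
    m_lit <- 1
  }

  # (f) fluxes
  led <- pool_derivatives(p, state, pv, m_class, m_lit, clim$temp_C, config)

  # (g) conserving Euler update
  out <- setNames(numeric(12), POOLS)
  out[1:9] <- led$R + led$Dt + led$prey_loss
  for (l in seq_along(led$li_cons)) {
    s <- led$li_source[l]
    if (s %in% c(10L, 11L)) out[s] <- out[s] + led$li_cons[l]
  }
  lambda <- setNames(rep(1, 12), POOLS)
  pos <- out > p & out > 0
  lambda[pos] <- p[pos] / out[pos]
  # herbivory is bounded by root production: the standing root pool sets
  # the Monod substrate level, but sustained offtake cannot exceed the
  # daily root growth
  root_out <- sum(led$li_cons[led$li_source == 0L])
  lam_root <- if (root_out > config$inputs$root_growth && root_out > 0)
    config$inputs$root_growth / root_out else 1

  s_link <- ifelse(led$li_source == 0L, lam_root,
                   lambda[pmax(led$li_source, 1L)])
  G_in <- vapply(1:9, function(i)
    sum(s_link[led$li_consumer == i] * led$li_G[led$li_consumer == i]), 0)
  G_in[3] <- G_in[3] + config$inputs$myc_alloc
  R_s <- lambda[1:9] * led$R
  Dt_s <- lambda[1:9] * led$Dt
  prey_s <- lambda[1:9] * led$prey_loss
  cons_s <- s_link * led$li_cons
  faec_s <- s_link * led$li_faec
  fN_s <- s_link * led$li_fN
  fRec_s <- s_link * led$li_fRec

  inflow <- setNames(numeric(12), POOLS)
  inflow[1:9] <- G_in
  inflow[["litter"]] <- config$inputs$litterfall
  som_in <- config$inputs$rootlitter + sum(faec_s) + sum(Dt_s)
  inflow[["SOM"]] <- som_in
  outflow <- setNames(numeric(12), POOLS)
  outflow[1:9] <- R_s + Dt_s + prey_s
  outflow[["litter"]] <- sum(cons_s[led$li_source == 10L])
  outflow[["SOM"]] <- sum(cons_s[led$li_source == 11L])
  p_new <- pmax(p + inflow - outflow, 0)

  R_tot <- sum(R_s)
  CO2_cum <- state$CO2_cum + R_tot
  root_cons <- sum(cons_s[led$li_source == 0L])
  inputs_cum <- inputs_cum + config$inputs$litterfall +
    config$inputs$rootlitter + config$inputs$myc_alloc + root_cons

  # (h) litter and SOM quality from the retained mass and the influxes
  q <- config$quality
  qual <- mix_quality(p_new[["litter"]], config$inputs$litterfall,
                      config$inputs$litterfall / q$CN_litterfall,
                      config$inputs$litterfall * q$Rec_litterfall,
                      state$CN_lit, state$Rec_lit)
  CN_lit <- qual[1]; Rec_lit <- qual[2]
  som_N <- config$inputs$rootlitter / q$CN_rootlitter + sum(fN_s) +
    sum(Dt_s / config$guilds$CN)
  som_rec <- config$inputs$rootlitter * q$Rec_rootlitter + sum(fRec_s)
  qual <- mix_quality(p_new[["SOM"]], som_in, som_N, som_rec,
                      state$CN_SOM, state$Rec_SOM)
  CN_SOM <- qual[1]; Rec_SOM <- qual[2]

  # (i) engineering: burrow volume tracks today's biomass, bioturbation
  # exports carbon from the layer
  PV_B <- burrow_volume_update(state$PV_B, p_new[["engineers"]],
                               config$pores$VE_ratio, config$pores$PV_Bmax,
                               config$pores$tPV_B)
  bt <- bioturbation_flux(p_new[["engineers"]], config$bioturb$rate_litter,
                          config$bioturb$rate_SOM, p_new[["litter"]],
                          p_new[["SOM"]])
  p_new[["litter"]] <- p_new[["litter"]] - bt[["litter_export"]]
  p_new[["SOM"]] <- p_new[["SOM"]] - bt[["SOM_export"]]
  biot_cum <- state$bioturb_export_cum + sum(bt)

  # (j) structural-change hook: none

  st <- structure(list(pools = p_new, CN_lit = CN_lit, Rec_lit = Rec_lit,
                       CN_SOM = CN_SOM, Rec_SOM = Rec_SOM, PV_B = PV_B,
                       SW = SW, R_tot_prev = R_tot, CO2_cum = CO2_cum,
                       DOM_leached_cum = leach_cum,
                       bioturb_export_cum = biot_cum,
                       inputs_cum = inputs_cum, day = state$day + 1L),
                  class = "sfw_state")
  is_b <- led$li_consumer == 1L
  is_e <- led$li_consumer == 7L
  rec <- c(day = st$day, p_new, CO2_cum = CO2_cum,
           DOM_leached_cum = leach_cum, bioturb_export_cum = biot_cum,
           inputs_cum = inputs_cum, SW = SW, runoff = ws$runoff,
           matrix_fill = ws$matrix_fill, bypass = ws$bypass,
           et_actual = ws$et_actual, drainage = ws$drainage, leach = leach,
           R_tot = R_tot, setNames(pv, paste0("pv_", PORE_CLASSES)),
           PV_B = PV_B, Ag = ps$Ag, CN_lit = CN_lit, Rec_lit = Rec_lit,
           CN_SOM = CN_SOM, Rec_SOM = Rec_SOM,
           resp_bacteria = R_s[1], resp_fungi = R_s[2],
           resp_mycorrhiza = R_s[3],
           cons_litter_bacteria = sum(cons_s[is_b & led$li_source == 10L]),
           cons_SOM_bacteria = sum(cons_s[is_b & led$li_source == 11L]),
           cons_litter_engineers = sum(cons_s[is_e & led$li_source == 10L]))
  names(rec) <- TRACE_COLS
  list(state = st, record = rec)
}

# N-conserving mixing of pool quality: C:N mixes harmonically (on nitrogen
# mass), recalcitrance mixes as a mass-weighted mean. The retained old mass
# is the updated pool minus the influx (floored at zero).
mix_quality <- function(pool_new, in_mass, in_N, in_rec, CN_old, Rec_old) {
  retained <- max(pool_new - in_mass, 0)
  total <- retained + in_mass
  if (total <= 0 || in_mass <= 0) return(c(CN_old, Rec_old))
  N <- retained / CN_old + in_N
  CN <- if (N > 0) total / N else CN_old
  Rec <- (retained * Rec_old + in_rec) / total
  c(CN, Rec)
}

#' Run the model for a period
#'
#' Deterministic daily simulation (no randomness in the forward model).
#' Uses the compiled engine by default; `use_compiled = FALSE` runs the
#' same algorithm through [daily_step()] (slower; used for cross-checking).
#'
#' @param config an `sfw_config`.
#' @param climate climate data.frame with columns date, precip_mm, et_mm,
#'   temp_C (see [synthetic_climate()] / [read_climate()]).
#' @param n_days number of days to simulate (default: all climate rows);
#'   the climate must cover it.
#' @param use_compiled use the compiled engine.
#' @return data.frame of daily records (class `sfw_trace`), one row per
#'   day, with the final state in attribute `final_state`.
#' @export
run_simulation <- function(config, climate, n_days = nrow(climate),
                           use_compiled = TRUE) {
  stopifnot(inherits(config, "sfw_config"))
  if (n_days > nrow(climate)) stop("climate series shorter than n_days")
  if (n_days < 1) stop("n_days must be at least 1")
  state <- init_state(config)
  if (use_compiled) {
    out <- engine_run_from(config, state, climate, n_days)
  } else {
    mat <- matrix(NA_real_, n_days, length(TRACE_COLS),
                  dimnames = list(NULL, TRACE_COLS))
    for (t in seq_len(n_days)) {
      stp <- daily_step(state, climate[t, ], config)
      state <- stp$state
      mat[t, ] <- stp$record
    }
    out <- list(trace = mat, state = state)
  }
  tr <- as.data.frame(out$trace)
  tr$date <- climate$date[seq_len(n_days)]
  attr(tr, "final_state") <- out$state
  class(tr) <- c("sfw_trace", "data.frame")
  tr
}

# marshal config+state into the compiled engine and back
engine_run_from <- function(config, state, climate, n_days) {
  g <- config$guilds
  diet <- config$diet
  size_code <- c(bacteria = 1, micro = 2, meso = 3, macro = 4)
  gm <- cbind(g$g_max, g$r, g$d, g$f_faec, g$m_faec, g$CN, g$p_mCN,
              g$p_mRec, g$T_min, g$T_opt, g$T_max, g$Q,
              size_code[g$size])
  dm <- cbind(match(diet$consumer, GUILDS),
              ifelse(diet$substrate == "roots", 13L,
                     match(diet$substrate, POOLS)),
              diet$Ks)
  tx <- config$texture; po <- config$pores; hy <- config$hydro
  dom <- config$dom; inp <- config$inputs; q <- config$quality
  mod <- config$modifiers
  pars <- c(config$derived$pv_text, po$f_PV, po$PV_Bmax, po$VE_ratio,
            po$tPV_B, po$k_agg, po$c_agg, po$PV_Ag_cap,
            as.numeric(po$meso_drains), hy$I_maxMat, hy$subsoil_imax,
            tx$layer_thickness, tx$pH, tx$fClay, tx$D_b, dom$f_DOM,
            dom$aKD, dom$bKD, dom$cKD, inp$litterfall, inp$rootlitter,
            inp$myc_alloc, inp$exudation, inp$root_pool, inp$root_growth,
            q$CN_litterfall,
            q$Rec_litterfall, q$CN_rootlitter, q$Rec_rootlitter,
            config$bioturb$rate_litter, config$bioturb$rate_SOM,
            as.numeric(mod$myc_ph_fungal), as.numeric(mod$eq16_alt),
            as.numeric(mod$use_T), as.numeric(mod$use_pH),
            as.numeric(mod$use_CN), as.numeric(mod$use_rec),
            as.numeric(mod$use_H2O),
            as.numeric(identical(mod$combine_mode, "min")))
  st0 <- c(unname(state$pools), state$CN_lit, state$Rec_lit, state$CN_SOM,
           state$Rec_SOM, state$PV_B, state$SW, state$R_tot_prev,
           state$CO2_cum, state$DOM_leached_cum, state$bioturb_export_cum,
           state$inputs_cum, state$day)
  clim <- cbind(climate$precip_mm[seq_len(n_days)],
                climate$et_mm[seq_len(n_days)],
                climate$temp_C[seq_len(n_days)])
  res <- engine_run(st0, clim, gm, dm, pars)
  colnames(res$trace) <- TRACE_COLS
  fs <- res$state
  st <- structure(list(pools = setNames(fs[1:12], POOLS), CN_lit = fs[13],
                       Rec_lit = fs[14], CN_SOM = fs[15], Rec_SOM = fs[16],
                       PV_B = fs[17], SW = fs[18], R_tot_prev = fs[19],
                       CO2_cum = fs[20], DOM_leached_cum = fs[21],
                       bioturb_export_cum = fs[22], inputs_cum = fs[23],
                       day = as.integer(fs[24])),
                  class = "sfw_state")
  list(trace = res$trace, state = st)
}
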