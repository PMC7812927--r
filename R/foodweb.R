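# Food-web carbon fluxes: Monod consumption over accessible substrate,
# respiration, turnover, predation, faeces routing and bioturbation.

#' Accessible fraction of a substrate for a consumer
#'
#' A substrate is distributed over pore-size classes in proportion to pore
#' volume (SOM over all five classes, a prey guild over the classes its own
#' body size can enter, roots over meso- and macropores). The consumer
#' reaches the classes its body size admits -- all classes except
#' inaccessible pores for engineers, which ingest bulk soil -- and each
#' reachable share is discounted by that class's moisture modifier. Surface
#' litter is outside the soil matrix: its availability is 1 here and its
#' moisture dependence is applied through the microbial moisture modifier on
#' g_max instead.
#'
#' @param consumer consumer guild name.
#' @param substrate substrate pool name ("litter", "SOM", "roots", or a
#'   guild).
#' @param pv named five-class pore volumes, l m^-3.
#' @param m_class per-class moisture modifiers,
#'   see [moisture_modifier_by_class()].
#' @return fraction in [0, 1].
#' @export
available_fraction <- function(consumer, substrate, pv, m_class) {
  if (substrate == "litter") return(1)
  sub_min <- if (substrate == "SOM") 1L
             else if (substrate == "roots") 4L
             else guild_min_class(substrate)
  denom <- sum(pv[sub_min:5])
  if (denom <= 0) return(0)
  lo <- max(guild_min_class(consumer), sub_min)
  sum(pv[lo:5] * m_class[lo:5]) / denom
}

#' Monod growth over one or more substrates
#'
#' G = sum_n g_eff * (S f_a / (K_s + S))_n * B; fluxes from multiple
#' substrates are additive.
#'
#' @param B consumer biomass, g C m^-3.
#' @param S substrate concentrations, g C m^-3 (vector).
#' @param f_a accessible fractions (vector, recycled).
#' @param Ks half-saturation constants, g C m^-3 (vector, recycled).
#' @param g_eff effective maximum growth rate(s) after modifiers.
#' @return growth, g C m^-3 day^-1.
#' @export
monod_growth <- function(B, S, f_a, Ks, g_eff) {
  stopifnot(B >= 0, all(S >= 0), all(Ks > 0))
  sum(g_eff * (S * f_a / (Ks + S))) * B
}

#' Respiration flux
#' @param B biomass, g C m^-3.
#' @param r respiration rate, g C g C^-1 day^-1.
#' @param resp_T_factor temperature factor,
#'   see [respiration_temperature_factor()].
#' @return respiration, g C m^-3 day^-1.
#' @export
respiration_flux <- function(B, r, resp_T_factor = 1) {
  stopifnot(B >= 0, r >= 0)
  r * resp_T_factor * B
}

#' Turnover (death) flux, routed to SOM
#' @param B biomass, g C m^-3.
#' @param d death rate, g C g C^-1 day^-1.
#' @return turnover, g C m^-3 day^-1.
#' @export
turnover_flux <- function(B, d) {
  stopifnot(B >= 0, d >= 0)
  d * B
}

#' Prey loss to a predation (or microbivory) link
#'
#' The prey loses the predator's growth share plus the fraction routed to
#' faeces; the predator gains the growth share and SOM gains the faeces.
#'
#' @param G_pred_share predator growth from this prey, g C m^-3 day^-1.
#' @param f_faec_pred predator faeces fraction (0-1).
#' @return named numeric: prey_loss, predator_gain, faeces.
#' @export
predation_loss <- function(G_pred_share, f_faec_pred) {
  stopifnot(G_pred_share >= 0, f_faec_pred >= 0, f_faec_pred <= 1)
  c(prey_loss = G_pred_share * (1 + f_faec_pred),
    predator_gain = G_pred_share,
    faeces = G_pred_share * f_faec_pred)
}

#' Effective faeces fraction of detritivores and engineers
#'
#' Poorer (higher C:N) substrate means more of the consumed carbon is
#' excreted; `m_faec` sets the sensitivity. Clamped to [0, 1).
#'
#' @param f_faec baseline faeces fraction (0-1).
#' @param m_faec sensitivity to substrate C:N (0-1).
#' @param CN_substrate substrate C:N ratio.
#' @param CN_consumer consumer C:N ratio.
#' @return effective faeces fraction.
#' @export
effective_faeces_fraction <- function(f_faec, m_faec, CN_substrate,
                                      CN_consumer) {
  stopifnot(CN_substrate > 0, CN_consumer > 0)
  eff <- f_faec + m_faec * (CN_substrate - CN_consumer) / CN_substrate *
    f_faec
  min(max(eff, 0), 0.999)
}

#' Bioturbation export
#'
#' Engineers move litter into their burrows and mix soil downwards. In the
#' single-layer configuration both flows leave the modelled system and are
#' tracked as cumulative export. Capped at the available pool.
#'
#' @param B_eng engineer biomass, g C m^-3.
#' @param rate_litter,rate_SOM transport rates, g C g C_eng^-1 day^-1.
#' @param litter,SOM current pools, g C m^-3.
#' @return named numeric: litter_export, SOM_export (g C m^-3 day^-1).
#' @export
bioturbation_flux <- function(B_eng, rate_litter, rate_SOM, litter, SOM) {
  stopifnot(B_eng >= 0, rate_litter >= 0, rate_SOM >= 0)
  c(litter_export = min(litter, rate_litter * B_eng),
    SOM_export = min(SOM, rate_SOM * B_eng))
}

# Assemble the unscaled daily flux ledger for all pools.
#
# Per diet link: growth G, total consumption (growth + faeces), the source
# pool it depletes (0 = external root boundary pool) and the faeces quality
# (N mass and recalcitrant mass) it delivers to SOM. Dead-substrate links
# deplete G / (1 - f_faecEff) so that faeces = consumption * f_faecEff;
# prey and root links deplete G * (1 + f_faec). Microbes produce no faeces.
# Mycorrhiza receive a fixed external carbon allocation instead of a Monod
# term. Flux limiting/scaling happens in the integrator, not here.
pool_derivatives <- function(pools, st, pv, m_class, m_lit, T_C, config) {
  g <- config$guilds
  mod <- config$modifiers
  pH <- config$texture$pH
  most_lim <- identical(mod$combine_mode, "min")

  m_T <- numeric(9); fR <- numeric(9); m_pH <- rep(1, 9); g_base <- g$g_max
  for (i in 1:9) {
    if (mod$use_T) {
      m_T[i] <- temperature_modifier(T_C, g$T_min[i], g$T_opt[i],
                                     g$T_max[i], g$Q[i])
      fR[i] <- respiration_temperature_factor(T_C, g$T_opt[i], g$Q[i])
    } else {
      m_T[i] <- 1; fR[i] <- 1
    }
    if (mod$use_pH) {
      if (GUILDS[i] == "bacteria") m_pH[i] <- ph_modifier_microbe(pH, "bacteria")
      if (GUILDS[i] == "fungi") m_pH[i] <- ph_modifier_microbe(pH, "fungi")
      if (GUILDS[i] == "mycorrhiza" && mod$myc_ph_fungal)
        m_pH[i] <- ph_modifier_microbe(pH, "fungi")
      if (GUILDS[i] == "engineers")
        g_base[i] <- ph_gmax_engineers(g$g_max[i], pH)
    }
  }

  diet <- config$diet
  nl <- nrow(diet)
  li_consumer <- match(diet$consumer, GUILDS)
  li_source <- ifelse(diet$substrate == "roots", 0L,
                      match(diet$substrate, POOLS))
  li_G <- numeric(nl); li_cons <- numeric(nl)
  li_faec <- numeric(nl); li_fN <- numeric(nl); li_fRec <- numeric(nl)

  for (l in seq_len(nl)) {
    i <- li_consumer[l]
    src <- li_source[l]
    B <- pools[[GUILDS[i]]]
    if (B <= 0) next
    sub <- diet$substrate[l]
    S <- if (sub == "roots") config$inputs$root_pool else pools[[sub]]
    if (S <= 0) next
    dead <- sub %in% c("litter", "SOM")
    m_CN <- 1; m_rec <- 1
    CN_sub <- NA_real_; Rec_sub <- 0
    if (dead) {
      CN_sub <- if (sub == "litter") st$CN_lit else st$CN_SOM
      Rec_sub <- if (sub == "litter") st$Rec_lit else st$Rec_SOM
      if (mod$use_CN && g$p_mCN[i] > 0)
        m_CN <- cn_modifier(g$CN[i], CN_sub, g$p_mCN[i])
      if (mod$use_rec && g$p_mRec[i] > 0)
        m_rec <- recalcitrance_modifier(Rec_sub, g$p_mRec[i])
    }
    f_a <- available_fraction(GUILDS[i], sub, pv, m_class)
    m_H2O_comp <- if (sub == "litter") m_lit else 1
    m_tot <- combine_modifiers(m_T[i], m_pH[i], m_CN, m_rec, m_H2O_comp,
                               mode = if (most_lim) "min" else "product")
    G <- g_base[i] * m_tot * (S * f_a / (diet$Ks[l] + S)) * B
    li_G[l] <- G
    if (dead) {
      ff <- if (GUILDS[i] %in% c("detritivores", "engineers")) {
        effective_faeces_fraction(g$f_faec[i], g$m_faec[i], CN_sub, g$CN[i])
      } else g$f_faec[i]
      li_cons[l] <- G / (1 - ff)
      li_faec[l] <- li_cons[l] - G
      li_fN[l] <- li_faec[l] / CN_sub
      li_fRec[l] <- li_faec[l] * Rec_sub
    } else {
      ff <- g$f_faec[i]
      li_cons[l] <- G * (1 + ff)
      li_faec[l] <- G * ff
      CN_f <- if (sub == "roots") config$quality$CN_rootlitter else g$CN[src]
      li_fN[l] <- li_faec[l] / CN_f
      li_fRec[l] <- 0
    }
  }

  R <- numeric(9); Dt <- numeric(9)
  for (i in 1:9) {
    B <- pools[[GUILDS[i]]]
    R[i] <- respiration_flux(B, g$r[i], fR[i])
    Dt[i] <- turnover_flux(B, g$d[i])
  }
  G_guild <- vapply(1:9, function(i) sum(li_G[li_consumer == i]), 0)
  prey_loss <- vapply(1:9, function(i) sum(li_cons[li_source == i]), 0)

  # G excludes the fixed mycorrhizal allocation, which is an external input
  # handled (unscaled) by the integrator
  list(G = G_guild, R = R, Dt = Dt, prey_loss = prey_loss,
       li_consumer = li_consumer, li_source = li_source, li_G = li_G,
       li_cons = li_cons, li_faec = li_faec, li_fN = li_fN,
       li_fRec = li_fRec)
}
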