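# Site configuration: guild biology, diet matrix, soil texture, external
# inputs, and validation. The packaged default describes a sandy, acidic
# Scots pine stand (Campine region, Belgium).

GUILD_SIZES <- c(bacteria = "bacteria", fungi = "micro", mycorrhiza = "micro",
                 bacterivores = "micro", fungivores = "micro",
                 detritivores = "meso", engineers = "macro",
                 herbivores = "meso", predators = "meso")

# smallest pore class (index into PORE_CLASSES) each body-size class can
# enter; engineers override this (they ingest bulk soil: everything except
# inaccessible pores)
SIZE_MIN_CLASS <- c(bacteria = 2L, micro = 3L, meso = 4L, macro = 5L)

#' Smallest accessible pore class per guild
#'
#' @param guild guild name.
#' @return integer index into [PORE_CLASSES]: the guild can enter this class
#'   and every larger one.
#' @export
guild_min_class <- function(guild) {
  if (guild == "engineers") return(2L)
  SIZE_MIN_CLASS[[GUILD_SIZES[[guild]]]]
}

#' Default guild parameter table
#'
#' One row per guild: maximum growth rate `g_max` (g C g C^-1 day^-1, the
#' calibrated parameters), respiration rate `r` and death rate `d` (g C
#' g C^-1 day^-1), faeces fraction `f_faec` and its C:N sensitivity
#' `m_faec` (detritivores/engineers only), tissue C:N, sensitivities to
#' substrate C:N (`p_mCN`) and recalcitrance (`p_mRec`), cardinal
#' temperatures and Q10, and body-size class.
#'
#' @return data.frame with nine rows in [GUILDS] order.
#' @export
default_guilds <- function() {
  data.frame(
    guild  = GUILDS,
    g_max  = c(2.00, 1.50, 2.00, 1.00, 1.00, 0.25, 0.25, 0.25, 0.25),
    r      = c(0.010, 0.003, 0.003, 0.010, 0.010, 0.005, 0.0035, 0.005, 0.006),
    d      = c(0.010, 0.006, 0.006, 0.010, 0.010, 0.005, 0.0035, 0.005, 0.006),
    f_faec = c(0, 0, 0, 0.3, 0.3, 0.4, 0.4, 0.3, 0.2),
    m_faec = c(0, 0, 0, 0, 0, 0.5, 0.5, 0, 0),
    CN     = c(5, 10, 10, 6, 6, 6, 6, 6, 5),
    p_mCN  = c(0.8, 0.2, 0.2, 0, 0, 0.3, 0.3, 0, 0),
    p_mRec = c(0.8, 0.1, 0.1, 0, 0, 0.5, 0.5, 0, 0),
    T_min  = rep(0, 9),
    T_opt  = c(25, 25, 25, 20, 20, 20, 20, 20, 20),
    T_max  = c(40, 40, 40, 35, 35, 35, 35, 35, 35),
    Q      = rep(2, 9),
    size   = unname(GUILD_SIZES),
    stringsAsFactors = FALSE
  )
}

#' Default diet matrix
#'
#' Edge list of trophic links. Half-saturation constants follow the rule
#' that K_s equals the standing substrate concentration for meso- and
#' macrofauna (growth could double at unlimited food), inflated by
#' `ks_mult_microbes` for the microbial pools whose laboratory growth rates
#' overstate field performance.
#'
#' @param pools0 named initial pool vector (g C m^-3).
#' @param root_pool root biomass boundary pool (g C m^-3).
#' @param ks_mult_microbes K_s inflation factor for bacteria and fungi.
#' @return data.frame with columns consumer, substrate, Ks.
#' @export
default_diet <- function(pools0, root_pool = 400, ks_mult_microbes = 2) {
  km <- ks_mult_microbes
  links <- rbind(
    data.frame(consumer = "bacteria", substrate = c("litter", "SOM"),
               Ks = km * c(pools0[["litter"]], pools0[["SOM"]])),
    data.frame(consumer = "fungi", substrate = c("litter", "SOM"),
               Ks = km * c(pools0[["litter"]], pools0[["SOM"]])),
    data.frame(consumer = "bacterivores", substrate = "bacteria",
               Ks = pools0[["bacteria"]]),
    data.frame(consumer = "fungivores", substrate = c("fungi", "mycorrhiza"),
               Ks = c(pools0[["fungi"]], pools0[["mycorrhiza"]])),
    data.frame(consumer = "detritivores", substrate = c("litter", "SOM"),
               Ks = c(pools0[["litter"]], pools0[["SOM"]])),
    data.frame(consumer = "engineers", substrate = c("litter", "SOM"),
               Ks = c(pools0[["litter"]], pools0[["SOM"]])),
    data.frame(consumer = "herbivores", substrate = "roots", Ks = root_pool),
    data.frame(consumer = "predators",
               substrate = c("bacterivores", "fungivores", "detritivores",
                             "engineers", "herbivores"),
               Ks = unname(c(pools0["bacterivores"], pools0["fungivores"],
                             pools0["detritivores"], pools0["engineers"],
                             pools0["herbivores"])))
  )
  links$Ks <- pmax(links$Ks, 1e-6)
  rownames(links) <- NULL
  links
}

#' Build a site configuration
#'
#' Assembles and validates the full model configuration. All defaults
#' describe the packaged Scots pine site; any component can be overridden.
#'
#' @param pools0 named initial pools, g C m^-3 (12 pools, [POOLS] order;
#'   DOM optional, default 1).
#' @param texture list: pct_sand, fClay (0-1), pct_SOM (mass %), D_b
#'   (g cm^-3), pH, layer_thickness (m).
#' @param quality list: CN_lit, Rec_lit, CN_SOM, Rec_SOM plus the qualities
#'   of incoming litterfall and root litter.
#' @param inputs list of external carbon inputs: litterfall and rootlitter
#'   and myc_alloc and exudation (g C m^-3 day^-1), root_pool (g C m^-3,
#'   standing fine-root boundary pool, the herbivore Monod substrate), and
#'   root_growth (g C m^-3 day^-1, root production -- the most herbivory
#'   can remove per day).
#' @param pores list: f_PV, PV_Bmax, VE_ratio, tPV_B, k_agg, c_agg,
#'   PV_Ag_cap, meso_drains, frac (optional named class fractions; derived
#'   from fClay when absent).
#' @param hydro list: I_maxMat (optional, derived from fClay), subsoil_imax,
#'   SW0 (optional, defaults to field capacity).
#' @param dom list: f_DOM, aKD, bKD, cKD (adsorption, m^3 kg^-1 terms).
#' @param bioturb list: rate_litter, rate_SOM (g C g C_eng^-1 day^-1).
#' @param guilds guild parameter table, see [default_guilds()].
#' @param diet diet matrix, see [default_diet()].
#' @param modifiers list of switches: use_pH, use_CN, use_rec, use_T,
#'   use_H2O, myc_ph_fungal, eq16_alt, combine_mode.
#' @return validated configuration object of class `sfw_config`.
#' @export
site_config <- function(pools0 = NULL, texture = list(), quality = list(),
                        inputs = list(), pores = list(), hydro = list(),
                        dom = list(), bioturb = list(), guilds = NULL,
                        diet = NULL, modifiers = list()) {
  def_pools <- c(bacteria = 15.1, fungi = 15.1, mycorrhiza = 160,
                 bacterivores = 0.1, fungivores = 0.8, detritivores = 0.6,
                 engineers = 0.2, herbivores = 0.2, predators = 0.4,
                 litter = 2680, SOM = 11470, DOM = 1)
  if (is.null(pools0)) pools0 <- def_pools
  if (!"DOM" %in% names(pools0)) pools0 <- c(pools0, DOM = 1)
  pools0 <- pools0[POOLS]
  if (anyNA(pools0)) stop("pools0 must name all pools: ",
                          paste(POOLS[is.na(pools0)], collapse = ", "))
  if (any(pools0 < 0)) stop("initial pools must be non-negative")

  texture <- modifyList(list(pct_sand = 93, fClay = 0.03, pct_SOM = 3,
                             D_b = 1.4, pH = 3.5, layer_thickness = 0.3,
                             D_m = 2.65, D_SOM = 1.35), texture)
  tx <- texture
  if (tx$layer_thickness <= 0) stop("layer_thickness must be positive")
  if (tx$fClay < 0 || tx$fClay > 1) stop("fClay must be in [0,1]")
  D_s <- particle_density(tx$pct_SOM, tx$D_m, tx$D_SOM)
  if (tx$D_b >= D_s) stop("bulk density must be below particle density")

  quality <- modifyList(list(CN_lit = 55, Rec_lit = 0.45,
                             CN_SOM = 25, Rec_SOM = 0.6,
                             CN_litterfall = 55, Rec_litterfall = 0.45,
                             CN_rootlitter = 50, Rec_rootlitter = 0.35),
                        quality)
  stopifnot(quality$CN_lit > 0, quality$CN_SOM > 0,
            quality$Rec_lit >= 0, quality$Rec_lit <= 1,
            quality$Rec_SOM >= 0, quality$Rec_SOM <= 1)

  inputs <- modifyList(list(litterfall = 400 / 365, rootlitter = 740 / 365,
                            myc_alloc = 197 / 365, exudation = 0.1,
                            root_pool = 400, root_growth = 210 / 365),
                       inputs)
  if (any(unlist(inputs) < 0)) stop("external inputs must be non-negative")

  ped <- texture_hydraulics(tx$fClay)
  pores <- modifyList(list(frac = ped$frac, f_PV = 0.5, PV_Bmax = 50,
                           VE_ratio = 0.05, tPV_B = 1 / 3650, k_agg = 2,
                           c_agg = 10, PV_Ag_cap = 20, meso_drains = TRUE),
                      pores)
  pores$frac <- pores$frac[PORE_CLASSES]
  if (abs(sum(pores$frac) - 1) > 1e-8) stop("pore fractions must sum to 1")

  hydro <- modifyList(list(I_maxMat = ped$I_maxMat, subsoil_imax = 10,
                           SW0 = NA_real_), hydro)
  dom <- modifyList(list(f_DOM = 0.02, aKD = 0.001226, bKD = 0.000212,
                         cKD = 0.00374), dom)
  bioturb <- modifyList(list(rate_litter = 0.01, rate_SOM = 0.005), bioturb)
  if (is.null(guilds)) guilds <- default_guilds()
  validate_guilds(guilds)
  if (is.null(diet)) diet <- default_diet(pools0, inputs$root_pool)
  validate_diet(diet)
  modifiers <- modifyList(list(use_pH = TRUE, use_CN = TRUE, use_rec = TRUE,
                               use_T = TRUE, use_H2O = TRUE,
                               myc_ph_fungal = TRUE, eq16_alt = FALSE,
                               combine_mode = "product"), modifiers)

  P_pct <- total_porosity_percent(D_s, tx$D_b)
  pv_text <- pores$frac * P_pct * 10  # % of volume -> l m^-3

  structure(list(pools0 = pools0, texture = texture, quality = quality,
                 inputs = inputs, pores = pores, hydro = hydro, dom = dom,
                 bioturb = bioturb, guilds = guilds, diet = diet,
                 modifiers = modifiers, derived = list(D_s = D_s,
                 P_pct = P_pct, pv_text = pv_text)),
            class = "sfw_config")
}

validate_guilds <- function(g) {
  need <- c("guild", "g_max", "r", "d", "f_faec", "m_faec", "CN", "p_mCN",
            "p_mRec", "T_min", "T_opt", "T_max", "Q", "size")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("guild table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!identical(g$guild, GUILDS)) stop("guild table must list the nine ",
                                        "guilds in canonical order")
  with(g, {
    if (any(g_max < 0 | r < 0 | d < 0)) stop("rate parameters must be >= 0")
    if (any(f_faec < 0 | f_faec > 1)) stop("f_faec must be in [0,1]")
    if (any(!(T_min < T_opt & T_opt < T_max)))
      stop("need T_min < T_opt < T_max for every guild")
    if (any(CN <= 0)) stop("C:N ratios must be positive")
  })
  invisible(TRUE)
}

validate_diet <- function(d) {
  stopifnot(all(c("consumer", "substrate", "Ks") %in% names(d)))
  if (nrow(d) == 0) stop("diet must be non-empty")
  if (any(d$Ks <= 0)) stop("K_s must be positive")
  ok_sub <- c(POOLS, "roots")
  bad <- setdiff(unique(c(d$consumer, d$substrate)), ok_sub)
  if (length(bad)) stop("unknown pool in diet: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Packaged pine-forest site configuration
#'
#' Reads the packaged site table (sandy acidic Scots pine stand: pH 3.5,
#' 93% sand, initial litter 2,680 and SOM 11,470 g C m^-3, constant annual
#' inputs) and builds the corresponding configuration.
#'
#' @param ... overrides forwarded to [site_config()].
#' @return an `sfw_config`.
#' @export
pine_forest_config <- function(...) {
  path <- system.file("extdata", "pine_site.csv", package = "soilfoodweb")
  site <- read.csv(path, stringsAsFactors = FALSE)
  val <- setNames(site$value, site$key)
  obs <- calibration_observations()
  pools0 <- setNames(obs$value, obs$pool)[POOLS[1:11]]
  pools0 <- c(pools0, DOM = 1)
  args <- list(
    pools0 = pools0,
    texture = list(pct_sand = val[["pct_sand"]], fClay = val[["fClay"]],
                   pct_SOM = val[["pct_SOM"]], D_b = val[["D_b"]],
                   pH = val[["pH"]],
                   layer_thickness = val[["layer_thickness"]]),
    inputs = list(litterfall = val[["annual_litterfall"]] / 365,
                  rootlitter = val[["annual_rootlitter"]] / 365,
                  myc_alloc = val[["annual_myc_alloc"]] / 365,
                  exudation = val[["exudation_daily"]],
                  root_pool = val[["root_pool"]],
                  root_growth = val[["fine_root_growth"]] / 365)
  )
  do.call(site_config, modifyList(args, list(...)))
}

#' Replace the nine maximum growth rates in a configuration
#'
#' @param config an `sfw_config`.
#' @param g_max numeric vector of nine growth rates in [GUILDS] order.
#' @return modified configuration.
#' @export
set_gmax <- function(config, g_max) {
  stopifnot(inherits(config, "sfw_config"), length(g_max) == 9,
            all(g_max >= 0))
  config$guilds$g_max <- as.numeric(g_max)
  config
}
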