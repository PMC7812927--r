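# Shared fixtures, built in code at test time.

# the packaged pine site, optionally modified
test_config <- function(...) pine_forest_config(...)

# short seeded climate series (cached per length/seed within a session)
test_climate <- function(n_days, seed = 11) {
  synthetic_climate(n_days, seed = seed)
}

# constant benign climate: mild, moist, no rain events beyond a steady
# drizzle; useful for closed-form comparisons
constant_climate <- function(n_days, P = 2, E = 1, T_C = 15) {
  data.frame(date = as.Date("2000-01-01") + seq_len(n_days) - 1,
             precip_mm = P, et_mm = E, temp_C = T_C)
}

# configuration with all biology switched off (zero biomass, no microbes),
# keeping hydrology and litter input running
abiotic_config <- function(litterfall = 400 / 365, exudation = 0) {
  pools0 <- setNames(rep(0, 12), POOLS)
  pools0[["litter"]] <- 2680
  pools0[["SOM"]] <- 11470
  test_config(pools0 = pools0,
              inputs = list(litterfall = litterfall, rootlitter = 0,
                            myc_alloc = 0, exudation = exudation,
                            root_pool = 400))
}

# calibrated-magnitude growth-rate vector used for deterministic
# directional experiments (posterior-scale values well inside the priors)
test_gmax <- function() {
  c(bacteria = 2.0, fungi = 0.3, mycorrhiza = 2.2, bacterivores = 0.2,
    fungivores = 0.1, detritivores = 0.1, engineers = 0.3,
    herbivores = 0.03, predators = 0.4)
}
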