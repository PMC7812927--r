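test_that("flux-limited Euler scales outflows to the available pool", {
  res <- flux_limited_euler(c(a = 1), c(a = 0), c(a = 2))
  expect_equal(res$pools[["a"]], 0)
  expect_equal(res$lambda[["a"]], 0.5)
  res <- flux_limited_euler(c(a = 5), c(a = 1), c(a = 2))
  expect_equal(res$pools[["a"]], 4)
  expect_equal(res$lambda[["a"]], 1)
  res <- flux_limited_euler(c(a = 5), c(a = 0), c(a = 0))
  expect_equal(res$pools[["a"]], 5)
})

test_that("one compiled day equals the composed module operations", {
  cfg <- test_config()
  clim <- test_climate(10)
  state <- init_state(cfg)
  for (t in 1:5) {
    ref <- daily_step(state, clim[t, ], cfg)
    eng <- soilfoodweb:::engine_run_from(cfg, state, clim[t, , drop = FALSE],
                                         1)
    expect_equal(unname(eng$trace[1, ]), unname(ref$record),
                 tolerance = 1e-10)
    expect_equal(eng$state$pools, ref$state$pools, tolerance = 1e-10)
    expect_equal(eng$state$CN_SOM, ref$state$CN_SOM, tolerance = 1e-10)
    expect_equal(eng$state$PV_B, ref$state$PV_B, tolerance = 1e-10)
    state <- ref$state
  }
})

test_that("compiled and reference paths agree over a long stretch", {
  cfg <- test_config()
  clim <- test_climate(120, seed = 5)
  t1 <- run_simulation(cfg, clim, use_compiled = TRUE)
  t2 <- run_simulation(cfg, clim, use_compiled = FALSE)
  cols <- soilfoodweb:::TRACE_COLS
  expect_equal(as.matrix(t1[, cols]), as.matrix(t2[, cols]),
               tolerance = 1e-8)
})

test_that("runs are deterministic and sized by the climate", {
  cfg <- test_config()
  clim <- test_climate(40)
  a <- run_simulation(cfg, clim)
  b <- run_simulation(cfg, clim)
  expect_identical(as.matrix(a[, soilfoodweb:::TRACE_COLS]),
                   as.matrix(b[, soilfoodweb:::TRACE_COLS]))
  expect_equal(nrow(run_simulation(cfg, clim, 1)), 1)
  expect_error(run_simulation(cfg, clim, 50), "shorter")
})

test_that("abiotic runs accumulate litter fall and nothing else", {
  cfg <- abiotic_config(litterfall = 1, exudation = 0)
  clim <- constant_climate(10)
  tr <- run_simulation(cfg, clim)
  st <- attr(tr, "final_state")
  # litter grows by exactly 1 per day; every guild stays zero
  expect_equal(tr$litter, 2680 + 1:10)
  expect_true(all(as.matrix(tr[, GUILDS]) == 0))
  expect_equal(st$CO2_cum, 0)
  # total carbon is conserved exactly (inputs are tracked)
  expect_equal(total_carbon(st), total_carbon(init_state(cfg)),
               tolerance = 1e-12)
})

test_that("a predator pool started at zero never spontaneously appears", {
  cfg <- test_config()
  cfg <- scenario_override(cfg, "no_predators", TRUE)
  tr <- run_simulation(cfg, test_climate(200))
  expect_true(all(tr$predators == 0))
})

test_that("without engineers macroporosity stays textural", {
  pools0 <- test_config()$pools0
  pools0[["engineers"]] <- 0
  cfg <- test_config(pools0 = pools0)
  tr <- run_simulation(cfg, test_climate(150))
  expect_true(all(tr$PV_B == 0))
  expect_equal(tr$pv_macro,
               rep(cfg$derived$pv_text[["macro"]], nrow(tr)))
})

test_that("with growth off, guilds decay exponentially at r + d", {
  g <- default_guilds()
  g$g_max <- rep(0, 9)
  cfg <- test_config(guilds = g,
                     inputs = list(litterfall = 0, rootlitter = 0,
                                   myc_alloc = 0, exudation = 0,
                                   root_pool = 400))
  n <- 100
  clim <- constant_climate(n, P = 2, E = 1, T_C = 20)
  tr <- run_simulation(cfg, clim)
  for (i in seq_along(GUILDS)) {
    fT <- respiration_temperature_factor(20, g$T_opt[i], g$Q[i])
    rate <- g$r[i] * fT + g$d[i]
    expect_equal(tr[[GUILDS[i]]][n],
                 cfg$pools0[[GUILDS[i]]] * (1 - rate)^n, tolerance = 1e-9)
    # daily Euler tracks the continuous exponential to first order
    expect_equal(tr[[GUILDS[i]]][n],
                 cfg$pools0[[GUILDS[i]]] * exp(-rate * n), tolerance = 0.05)
  }
})

test_that("a single Monod consumer matches a scalar ODE oracle", {
  # one consumer (bacteria) on SOM only, all modifiers off, no predators:
  # the engine must reproduce dB = (g m - r - d) B, dS = -g m B stepped
  # daily, with m the Monod term on accessible substrate
  g <- default_guilds()
  g$g_max <- c(0.3, rep(0, 8))
  pools0 <- setNames(rep(0, 12), POOLS)
  pools0[["bacteria"]] <- 10; pools0[["SOM"]] <- 5000
  diet <- data.frame(consumer = "bacteria", substrate = "SOM", Ks = 8000)
  cfg <- test_config(pools0 = pools0, guilds = g, diet = diet,
                     inputs = list(litterfall = 0, rootlitter = 0,
                                   myc_alloc = 0, exudation = 0,
                                   root_pool = 400),
                     dom = list(f_DOM = 0),
                     modifiers = list(use_T = FALSE, use_pH = FALSE,
                                      use_CN = FALSE, use_rec = FALSE,
                                      use_H2O = FALSE))
  n <- 60
  tr <- run_simulation(cfg, constant_climate(n, T_C = 20))
  pv <- soilfoodweb:::pore_state(cfg, pools0, 0)$pv
  f_a <- sum(pv[2:5]) / sum(pv)  # aggregation is zero without fungi
  B <- 10; S <- 5000
  r <- g$r[1]; d <- g$d[1]
  for (t in 1:n) {
    G <- 0.3 * (S * f_a / (8000 + S)) * B
    S <- S - G + d * B     # dead bacteria return to SOM
    B <- B + G - (r + d) * B
  }
  expect_equal(tr$bacteria[n], B, tolerance = 1e-6)
  expect_equal(tr$SOM[n], S, tolerance = 1e-6)
})

test_that("carbon closes to high precision over a full biotic year", {
  cfg <- test_config()
  tr <- run_simulation(cfg, test_climate(365, seed = 8))
  st <- attr(tr, "final_state")
  drift <- abs(total_carbon(st) - total_carbon(init_state(cfg)))
  expect_lt(drift / total_carbon(init_state(cfg)), 1e-6)
  # respiration bookkeeping: cumulative CO2 equals the summed daily totals
  expect_equal(st$CO2_cum, sum(tr$R_tot), tolerance = 1e-8)
})

test_that("daily water balance closes along a full biotic run", {
  cfg <- test_config()
  tr <- run_simulation(cfg, test_climate(365, seed = 9))
  th <- cfg$texture$layer_thickness
  sw_prev <- c(init_state(cfg)$SW, tr$SW[-nrow(tr)])
  lhs <- tr$SW - sw_prev
  rhs <- tr$matrix_fill / th - (tr$drainage - tr$bypass / th) -
    tr$et_actual
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("removing predators releases microbivores and presses fungi", {
  cfg <- set_gmax(test_config(), test_gmax())
  clim <- test_climate(365, seed = 10)
  basal <- trace_summary(run_simulation(cfg, clim))
  nopred <- trace_summary(run_simulation(
    scenario_override(cfg, "no_predators", TRUE), clim))
  micro_b <- basal$pool_mean[["bacterivores"]] +
    basal$pool_mean[["fungivores"]]
  micro_n <- nopred$pool_mean[["bacterivores"]] +
    nopred$pool_mean[["fungivores"]]
  expect_gte(micro_n, micro_b)
  expect_lte(nopred$pool_mean[["fungi"]], basal$pool_mean[["fungi"]])
})

test_that("identical climate days from a steady hydrology repeat fluxes", {
  cfg <- abiotic_config(litterfall = 0, exudation = 0)
  clim <- constant_climate(30, P = 2, E = 2, T_C = 15)  # net zero water
  tr <- run_simulation(cfg, clim)
  expect_equal(tr$drainage[20], tr$drainage[21])
  expect_equal(tr$SW[20], tr$SW[21])
  expect_equal(tr$R_tot[20], tr$R_tot[21])
})
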