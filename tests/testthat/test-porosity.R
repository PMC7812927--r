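test_that("particle density interpolates between mineral and organic limits", {
  expect_equal(particle_density(0), 2.65)
  expect_equal(particle_density(100), 1.35)
  # direct evaluation: 100 / (3/1.35 + 97/2.65)
  expect_equal(particle_density(3), 100 / (3 / 1.35 + 97 / 2.65))
  expect_equal(particle_density(3), 2.5756, tolerance = 1e-4)
  expect_error(particle_density(101), "between 0 and 100")
})

test_that("total porosity follows bulk/particle density ratio", {
  expect_equal(total_porosity_percent(2.6, 1.3), 50)
  expect_equal(total_porosity_percent(2.5756, 1.4), 45.64, tolerance = 1e-3)
  expect_equal(total_porosity_percent(2.65, 1e-9), 100, tolerance = 1e-6)
  expect_error(total_porosity_percent(2.5, 2.6), "D_b")
  expect_error(total_porosity_percent(2.5, 0))
})

test_that("aggregation fraction scales with fungal biomass and clamps", {
  expect_equal(aggregation_fraction(0, 0, 11470), 0)
  expect_equal(aggregation_fraction(600, 600, 11470), 1)  # >= SOM/10
  expect_equal(aggregation_fraction(60, 40, 11470), 10 * 100 / 11470)
  expect_equal(aggregation_fraction(60, 40, 11470), 0.0872, tolerance = 1e-3)
  expect_equal(aggregation_fraction(5, 5, 0), 0)  # degenerate: no SOM
})

test_that("aggregation porosity is proportional up to the cap", {
  expect_equal(aggregation_porosity(0, 11470), 0)
  expect_equal(aggregation_porosity(0.0005, 11470), 11.47)
  expect_equal(aggregation_porosity(0.0872, 11470), 20)  # cap binds
})

test_that("burrow volume tracks biomass and decays on a ten-year scale", {
  expect_equal(burrow_volume_update(0, 0), 0)
  # biomass-supported volume clamps at the maximum
  expect_equal(burrow_volume_update(0, 1e6, VE_ratio = 0.05, PV_Bmax = 50),
               50)
  # abandoned burrows decay geometrically at 1/3650 per day
  expect_equal(burrow_volume_update(10, 0), 10 * (1 - 1 / 3650))
  v <- 10
  for (i in 1:3650) v <- burrow_volume_update(v, 0)
  expect_equal(v, 10 * exp(-1), tolerance = 2e-4)  # e-folding ~ 10 years
})

test_that("pore-size distribution matches the componentwise identities", {
  pv_text <- c(inaccessible = 30, bacterial = 50, micro = 140, meso = 190,
               macro = 45)
  # no aggregation, no biopores: textural state exactly
  psd <- pore_size_distribution(0, 0, 11470, pv_text)
  expect_equal(psd$pv, pv_text)
  # mesopore conversion: Ag = 0.1, textmeso = 100 moves 2.5 into micro and
  # bacterial each and removes 5 from meso (no aggregation porosity: SOM 0)
  pt <- c(inaccessible = 10, bacterial = 20, micro = 30, meso = 100,
          macro = 10)
  psd <- pore_size_distribution(0.1, 0, 0, pt)
  expect_equal(psd$pv[["micro"]], 30 + 2.5)
  expect_equal(psd$pv[["bacterial"]], 20 + 2.5)
  expect_equal(psd$pv[["meso"]], 100 - 5)
  # f_PV = 1: mesopores unaffected by biopores, total rises by full PV_B
  psd1 <- pore_size_distribution(0, 8, 0, pt, f_PV = 1)
  expect_equal(psd1$pv[["meso"]], pt[["meso"]])
  expect_equal(sum(psd1$pv), sum(pt) + 8)
})

test_that("total-porosity identity holds whenever no clamping occurred", {
  pv_text <- c(inaccessible = 30, bacterial = 50, micro = 140, meso = 190,
               macro = 45)
  set.seed(1)
  for (i in 1:50) {
    Ag <- runif(1); PV_B <- runif(1, 0, 40); SOM <- runif(1, 0, 20000)
    f_PV <- runif(1)
    psd <- suppressWarnings(
      pore_size_distribution(Ag, PV_B, SOM, pv_text, f_PV))
    if (psd$clamped == 0) {
      expect_equal(sum(psd$pv),
                   sum(pv_text) + psd$PV_Ag + f_PV * PV_B,
                   tolerance = 1e-10)
    }
  }
})

test_that("aggregation never shrinks micro/bacterial pores nor grows meso", {
  pv_text <- c(inaccessible = 30, bacterial = 50, micro = 140, meso = 190,
               macro = 45)
  ags <- seq(0, 1, by = 0.05)
  res <- sapply(ags, function(a)
    pore_size_distribution(a, 5, 11470, pv_text)$pv)
  expect_true(all(diff(res["micro", ]) >= -1e-12))
  expect_true(all(diff(res["bacterial", ]) >= -1e-12))
  expect_true(all(diff(res["meso", ]) <= 1e-12))
})

test_that("pedotransfer fractions always sum to one", {
  for (fc in c(0, 0.03, 0.15, 0.3, 0.45)) {
    th <- texture_hydraulics(fc)
    expect_equal(sum(th$frac), 1)
    expect_true(all(th$frac >= 0))
    expect_gt(th$I_maxMat, 0)
  }
  # more clay: more fine porosity, slower matrix infiltration
  a <- texture_hydraulics(0.03); b <- texture_hydraulics(0.15)
  expect_gt(sum(b$frac[1:3]), sum(a$frac[1:3]))
  expect_lt(b$I_maxMat, a$I_maxMat)
})
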