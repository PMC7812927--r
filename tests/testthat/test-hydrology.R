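test_that("net precipitation is a signed difference", {
  expect_equal(net_precipitation(5, 2), 3)
  expect_equal(net_precipitation(0, 3), -3)
  expect_equal(net_precipitation(4, 4), 0)
  expect_error(net_precipitation(-1, 0))
})

test_that("macropore capacity adds pore volume and subsoil capacity", {
  expect_equal(macropore_capacity(0, 1, 10), 10)
  expect_equal(macropore_capacity(20, 1, 10), 30)
  # 66.67 l m^-3 over a 0.3 m layer is a 20 mm water column
  expect_equal(macropore_capacity(200 / 3, 0.3, 10), 30)
  expect_equal(macropore_capacity(0, 1, 0), 0)
})

test_that("infiltration partition closes and caps runoff", {
  p <- partition_water(50, 10, 20, 0.01, 400, 100, 0.3)
  expect_equal(p[["runoff"]], 20)
  expect_equal(sum(p), 50)
  expect_equal(partition_water(0, 10, 20, 0.01, 400, 100, 0.3),
               c(runoff = 0, matrix_fill = 0, bypass = 0))
  # saturated soil: nothing enters the matrix
  p <- partition_water(5, 10, 20, 0.01, 400, 400, 0.3)
  expect_equal(p[["matrix_fill"]], 0)
  expect_equal(p[["bypass"]], 5)
})

test_that("partition closure and macropore monotonicity hold generally", {
  set.seed(2)
  for (i in 1:100) {
    P_net <- runif(1, 0, 80); Imm <- runif(1, 0, 50)
    pvm <- runif(1, 0, 100); SW <- runif(1, 0, 400)
    th <- 0.3
    Ipor <- macropore_capacity(pvm, th, 10)
    SA <- macropore_surface_fraction(pvm)
    p <- partition_water(P_net, Imm, Ipor, SA, 400, SW, th)
    expect_equal(sum(p), max(P_net, 0), tolerance = 1e-12)
    expect_true(all(p >= -1e-12))
    # more macropores never cause more runoff
    Ipor2 <- macropore_capacity(pvm + 50, th, 10)
    p2 <- partition_water(P_net, Imm, Ipor2,
                          macropore_surface_fraction(pvm + 50), 400, SW, th)
    expect_lte(p2[["runoff"]], p[["runoff"]] + 1e-12)
  }
})

test_that("daily water step conserves water in every regime", {
  pv <- c(inaccessible = 30, bacterial = 50, micro = 140, meso = 190,
          macro = 45)
  th <- 0.3
  set.seed(3)
  for (i in 1:200) {
    SW0 <- runif(1, 0, sum(pv))
    P <- runif(1, 0, 60) * rbinom(1, 1, 0.7)
    E <- runif(1, 0, 6)
    ws <- water_step(SW0, P, E, pv, 40, 10, th)
    # storage change = matrix inflow - spill - actual ET
    lhs <- ws$SW - SW0
    rhs <- ws$matrix_fill / th - (ws$drainage - ws$bypass / th) -
      ws$et_actual
    expect_equal(lhs, rhs, tolerance = 1e-9)
    expect_true(ws$SW >= 0 && ws$SW <= sum(pv) + 1e-9)
    expect_equal(ws$runoff + ws$matrix_fill + ws$bypass,
                 max(P - E, 0), tolerance = 1e-9)
  }
})

test_that("water step limit cases match the drainage formulation", {
  pv <- c(inaccessible = 30, bacterial = 50, micro = 140, meso = 190,
          macro = 45)
  th <- 0.3
  # dry soil far below field capacity, small rain: only the macropore
  # share drains
  SA <- macropore_surface_fraction(pv[["macro"]])
  ws <- water_step(100, 3, 0, pv, 40, 10, th)
  expect_equal(ws$drainage, 3 * SA / th, tolerance = 1e-12)
  # at field capacity with rain at matrix capacity: all matrix inflow
  # spills again
  fc <- field_capacity(pv)
  ws <- water_step(fc, 20, 0, pv, 40, 10, th)
  expect_equal(ws$SW, fc)
  expect_equal(ws$drainage, 20 / th, tolerance = 1e-9)
  # no rain, no ET: nothing moves
  ws <- water_step(100, 0, 0, pv, 40, 10, th)
  expect_equal(ws$drainage, 0)
  expect_equal(ws$SW, 100)
  # ET draws storage down, never below the wilting point
  ws <- water_step(31, 0, 10, pv, 40, 10, th)
  expect_equal(ws$SW, pv[["inaccessible"]])
})

test_that("water allocation fills smallest pores first", {
  pv <- c(inaccessible = 30, bacterial = 50, micro = 140, meso = 190,
          macro = 45)
  # exact boundary: bacterial full, larger classes dry
  al <- allocate_water_to_classes(80, pv)
  expect_equal(unname(al$water), c(30, 50, 0, 0, 0))
  expect_equal(al$partial, 3L)
  # saturated
  al <- allocate_water_to_classes(sum(pv), pv)
  expect_equal(al$water, pv)
  expect_true(is.na(al$partial))
  # half-filled bacterial class
  al <- allocate_water_to_classes(55, pv)
  expect_equal(al$water[["bacterial"]], 25)
  expect_equal(al$partial, 2L)
  expect_warning(allocate_water_to_classes(sum(pv) + 5, pv), "clipping")
})

test_that("allocation matches a brute-force smallest-first oracle", {
  oracle <- function(SW, pv) {
    w <- numeric(5)
    for (i in 1:5) { w[i] <- min(SW, pv[i]); SW <- SW - w[i] }
    w
  }
  set.seed(4)
  for (i in 1:100) {
    pv <- setNames(runif(5, 0, 200), PORE_CLASSES)
    SW <- runif(1, 0, sum(pv))
    al <- allocate_water_to_classes(SW, pv)
    expect_equal(unname(al$water), oracle(SW, pv), tolerance = 1e-12)
    expect_equal(sum(al$water), SW, tolerance = 1e-9)
    # at most one class strictly partial
    partials <- sum(al$water > 1e-12 & al$water < pv - 1e-12)
    expect_lte(partials, 1)
  }
})
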