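test_that("network validation accepts minimal graphs and names bad elements", {
  net <- build_network(single_segment_layout())
  expect_s3_class(net, "vascular_network")
  expect_equal(nrow(net$segments), 1)

  bad <- single_segment_layout(); bad$segments[[1]]$diameter_um <- 0
  expect_error(build_network(bad), "s1.*non-positive diameter")

  noin <- single_segment_layout(); noin$inlet <- "zz"
  expect_error(build_network(noin), "inlet node 'zz'")

  disc <- single_segment_layout()
  disc$nodes[[3]] <- list(id = "orphan", x_um = 1, y_um = 1)
  expect_error(build_network(disc), "disconnected.*orphan")

  loop <- single_segment_layout(); loop$segments[[1]]$node_b <- "a"
  expect_error(build_network(loop), "self-loop")
})

test_that("bundled layout carries the expected zone hints", {
  net <- default_network()
  hint <- function(pat) unique(net$segments$zone_hint[grepl(pat, net$segments$id)])
  expect_equal(hint("^inner_"), "high")
  expect_equal(hint("^outer_"), "mid")
  expect_equal(hint("^vert_"), "low")
  expect_true(all(is.na(net$segments$zone_hint[grepl("^feed_", net$segments$id)])))
  expect_equal(length(net$follicles), 7)
})

test_that("single-segment pressure drop matches the Hagen-Poiseuille closed form", {
  net <- build_network(single_segment_layout(diameter_um = 500, length_um = 10000))
  fs <- solve_flow(net, inlet_flow_ml_min = 2.4, viscosity_mpas = 1.0)
  dp <- fs$node_pressure_pa["a"] - fs$node_pressure_pa["b"]
  q_si <- 2.4e-6 / 60                                  # m^3/s
  expected <- hp_resistance(500, 10000, 1.0) * q_si    # ~260.8 Pa
  expect_equal(unname(dp), expected, tolerance = 1e-10)
  expect_equal(unname(dp), 260.8, tolerance = 2e-4)
})

test_that("series and parallel networks match hand-computed resistances", {
  # two segments in series: total resistance adds
  lay <- single_segment_layout()
  lay$nodes[[3]] <- list(id = "c", x_um = 16000, y_um = 0)
  lay$segments[[2]] <- list(id = "s2", node_a = "b", node_b = "c",
                            diameter_um = 300, length_um = 6000)
  lay$outlet <- "c"
  fs <- solve_flow(build_network(lay), 1.2, 0.8)
  q_si <- 1.2e-6 / 60
  expected <- (hp_resistance(500, 10000, 0.8) + hp_resistance(300, 6000, 0.8)) * q_si
  dp <- unname(fs$node_pressure_pa["a"] - fs$node_pressure_pa["c"])
  expect_equal(dp, expected, tolerance = 1e-10)

  # two identical parallel branches carry exactly half each
  fp <- solve_flow(build_network(parallel_layout()), 2.4, 1.0)
  expect_equal(unname(abs(fp$segments$flow_ml_min)), rep(1.2, 4),
               tolerance = 1e-10)
})

test_that("mass is conserved at interior nodes for randomised ladder networks", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      lay <- default_chip_layout()
      for (i in seq_along(lay$segments))
        lay$segments[[i]]$diameter_um <- runif(1, 200, 800)
      fs <- solve_flow(build_network(lay), runif(1, 0.5, 5), runif(1, 0.7, 1.2))
      expect_lt(max(abs(node_imbalance(fs))), 1e-9)
    }
  })
})

test_that("wall shear follows the Poiseuille closed form and its scalings", {
  expect_equal(wall_shear(500, 0), 0)
  # entire 2.4 mL/min through one 0.5 mm channel
  tau <- wall_shear(500, 2.4, 1.0)
  expected <- 10 * 32 * 1e-3 * (2.4e-6 / 60) / (pi * (5e-4)^3)  # dyn/cm2
  expect_equal(tau, expected, tolerance = 1e-12)
  expect_equal(tau, 32.6, tolerance = 2e-3)
  # linear in Q and mu, cubic-inverse in d
  expect_equal(wall_shear(500, 1.2, 1.0), tau / 2, tolerance = 1e-12)
  expect_equal(wall_shear(500, 2.4, 0.5), tau / 2, tolerance = 1e-12)
  d <- c(200, 400, 800)
  tau_d <- wall_shear(d, 2.4, 1.0)
  expect_equal(tau_d / tau_d[1], (d[1] / d)^3, tolerance = 1e-12)
})

test_that("zone classification verifies ordering from hints and splits by thresholds", {
  fs <- solve_flow(default_network(), 2.4, 1.0)
  z <- classify_zones(fs)
  expect_true(z$ordering_ok)
  expect_lt(z$zone_means["low"], z$zone_means["mid"])
  expect_lt(z$zone_means["mid"], z$zone_means["high"])

  # thresholds path: all segments same shear -> single zone
  fp <- solve_flow(build_network(parallel_layout()), 2.4, 1.0)
  fp$segments$zone_hint <- NA_character_
  zt <- classify_zones(fp, thresholds = c(100, 200))
  expect_true(all(zt$zones$zone == "low"))
  expect_error(classify_zones(fp), "thresholds")

  # ordering violation is flagged, not raised
  fbad <- fs
  swap <- fbad$segments$zone_hint
  swap[swap == "low"] <- "tmp"; swap[swap == "high"] <- "low"; swap[swap == "tmp"] <- "high"
  fbad$segments$zone_hint <- swap
  zb <- classify_zones(fbad)
  expect_false(zb$ordering_ok)
  expect_gt(length(zb$violations), 0)
})

test_that("bundled geometry spans the physiological shear range across viscosities", {
  for (mu in c(0.7, 1.0)) {
    z <- classify_zones(solve_flow(default_network(), 2.4, mu))
    expect_true(z$ordering_ok)
    expect_gt(z$zone_means["high"] / z$zone_means["low"], 5)
  }
})
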