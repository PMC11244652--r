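test_that("erfc profile matches the semi-infinite constant-source solution", {
  expect_equal(erfc_profile(0, 100, 16, C0 = 3), 3)
  # independent oracle: erfc(z) = 2 * pnorm(-z * sqrt(2))
  z <- 240 / (2 * sqrt(16 * 3600))            # = 0.5
  expect_equal(erfc_profile(240, 3600, 16), 2 * pnorm(-z * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(erfc_profile(240, 3600, 16), 0.4795, tolerance = 1e-4)
  expect_lt(erfc_profile(5e4, 60, 16), 1e-12)
  expect_error(erfc_profile(100, 0, 16), "t > 0")
  expect_error(erfc_profile(100, -5, 16), "t > 0")
})

test_that("robin profile has the right limits and never returns NaN", {
  # sealed barrier
  expect_equal(robin_profile(c(0, 50, 200), 600, 16, 0), rep(0, 3))
  # infinite-permeability limit reduces to the erfc solution
  x <- c(10, 50, 150, 400)
  expect_equal(robin_profile(x, 1800, 16, 1e9), erfc_profile(x, 1800, 16),
               tolerance = 1e-6)
  # early-time limit at positive depth
  expect_lt(robin_profile(100, 1e-6, 16, 0.62), 1e-12)
  # overflow-prone diffusion-limited regime stays finite and bounded
  grid <- expand.grid(x = c(0, 10, 100, 1000, 5000),
                      t = c(1, 60, 3600, 1e5),
                      D = c(1, 16, 53, 500),
                      P = c(1e-3, 0.62, 10, 1e3))
  v <- with(grid, robin_profile(x, t, D, P))
  expect_true(all(is.finite(v)))
  expect_true(all(v >= 0 & v <= 1))
  # monotone in P at fixed (x, t, D)
  vp <- robin_profile(100, 1800, 16, c(0.01, 0.1, 1, 10, 100))
  expect_true(all(diff(vp) > 0))
})

test_that("finite-difference solver matches both analytic oracles on a strip", {
  dom <- make_strip_domain(length_um = 2000, dx_um = 10)
  x <- strip_positions(dom)
  gel <- !dom$lumen[1, ]

  ser <- simulate_transport(dom, 16, 0.62, output_times_s = c(0, 900, 3600),
                            dt_s = 1)
  for (k in 2:3) {
    num <- ser$fields[[k]][1, gel]
    ana <- robin_profile(x, ser$times_s[k], 16, 0.62)
    expect_lt(sqrt(mean((num - ana)^2)), 0.01)   # RMS relative to C0 = 1
  }

  ser_inf <- simulate_transport(dom, 16, 1e5, output_times_s = c(0, 3600),
                                dt_s = 1)
  ana_inf <- erfc_profile(x, 3600, 16)
  expect_lt(sqrt(mean((ser_inf$fields[[2]][1, gel] - ana_inf)^2)), 0.01)
})

test_that("explicit FTCS agrees with the implicit default and enforces stability", {
  dom <- make_strip_domain(length_um = 600, dx_um = 20)
  dt_ok <- 0.25 * 20^2 / (4 * 16)
  imp <- simulate_transport(dom, 16, 0.62, output_times_s = c(0, 600),
                            dt_s = dt_ok)
  exp_ <- simulate_transport(dom, 16, 0.62, output_times_s = c(0, 600),
                             dt_s = dt_ok, method = "explicit")
  expect_lt(max(abs(imp$fields[[2]] - exp_$fields[[2]])), 1e-3)
  expect_error(simulate_transport(dom, 16, 0.62, output_times_s = c(0, 600),
                                  dt_s = 10 * dt_ok, method = "explicit"),
               "stability bound")
})

test_that("sealed barrier, boundedness, monotone traces and mass balance hold", {
  dom <- small_domain()
  # P = 0: gel identically zero
  s0 <- simulate_transport(dom, 16, 0, output_times_s = c(0, 600, 1800), dt_s = 10)
  for (f in s0$fields) expect_equal(sum(f[!dom$lumen]), 0)

  s <- simulate_transport(dom, 16, 0.62, output_times_s = seq(0, 1800, 300),
                          dt_s = 10)
  rng <- range(unlist(lapply(s$fields, range)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  expect_true(all(diff(s$roi_traces$central_polygon) > 0))
  mb <- s$mass_balance
  expect_lt(abs(mb$gel_mass - mb$influx_integral) / mb$influx_integral, 0.005)
})

test_that("halving the grid spacing changes the central-polygon trace by < 1% RMS", {
  net <- default_network()
  win <- c(2200, 3800, -800, 800)
  t_out <- seq(300, 1800, 300)
  tr <- lapply(c(25, 12.5), function(dx) {
    dom <- make_transport_domain(net, window = win, dx_um = dx)
    simulate_transport(dom, 16, 0.62, output_times_s = t_out,
                       dt_s = 5)$roi_traces$central_polygon
  })
  expect_lt(sqrt(mean((tr[[1]] - tr[[2]])^2)), 0.01)
})

test_that("roi sampling averages the covered cells and validates coverage", {
  dom <- small_domain()
  ser <- simulate_transport(dom, 16, 0.62, output_times_s = c(0, 300), dt_s = 10)
  # uniform synthetic fields -> trace equals the constant
  ser2 <- ser
  ser2$fields <- lapply(ser$fields, function(f) matrix(0.37, nrow(f), ncol(f)))
  expect_equal(sample_roi(ser2, dom$rois$central_polygon), c(0.37, 0.37))
  # an ROI covering only lumen cells reads the lumen concentration
  cc <- domain_coords(dom)
  lum <- which(dom$lumen, arr.ind = TRUE)[1, ]
  roi_lum <- rect_roi("lumen_probe", cc$x_um[lum["col"]] - 1,
                      cc$x_um[lum["col"]] + 1, cc$y_um[lum["row"]] - 1,
                      cc$y_um[lum["row"]] + 1)
  expect_equal(sample_roi(ser, roi_lum), c(1, 1))
  # ROI outside the grid errors
  far <- rect_roi("far", 1e6, 1e6 + 10, 1e6, 1e6 + 10)
  expect_error(sample_roi(ser, far), "covers no grid cells")
})

test_that("a dye with smaller D and smaller P stays below the faster dye at all times", {
  dom <- small_domain()
  t_out <- seq(300, 3600, 600)
  tr_small <- simulate_transport(dom, 16, 0.62,
                                 output_times_s = t_out)$roi_traces$central_polygon
  tr_large <- simulate_transport(dom, 8, 0.41,
                                 output_times_s = t_out)$roi_traces$central_polygon
  expect_true(all(tr_large < tr_small))
})
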