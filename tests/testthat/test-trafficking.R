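test_that("binarize rescales to 8-bit and thresholds by Otsu or fixed value", {
  zeros <- matrix(0, 20, 20)
  expect_equal(sum(binarize(zeros, "fixed", threshold = 1)), 0)
  expect_error(binarize(zeros, "otsu"), "fixed threshold")

  centers <- grid_centers(50, 200, 200, step = 24)
  frame <- disk_frame(200, 200, centers, radius_px = 4)
  mask <- binarize(frame, "otsu")
  true_area <- sum(frame > 100)
  expect_lt(abs(sum(mask) - true_area) / true_area, 0.05)

  # complementary mask under intensity inversion (threshold not attained)
  f <- matrix(runif(400) * 250, 20, 20)
  thr <- 117.5
  m1 <- binarize(f, "fixed", threshold = thr)
  m2 <- binarize(max(f) + min(f) - f, "fixed", threshold = 255 - thr)
  expect_equal(as.vector(m2), as.vector(!m1))
})

test_that("cell detection counts 8-connected components above the area floor", {
  expect_equal(detect_cells(matrix(FALSE, 10, 10), 10)$count, 0)

  centers <- grid_centers(50, 240, 240, step = 26)
  frame <- disk_frame(240, 240, centers, radius_px = 4)
  det <- detect_cells(binarize(frame, "fixed", threshold = 100), 10)
  expect_equal(det$count, 50)
  # centroids within 1 px of the generated centers
  got <- det$cells[order(det$cells$y_um, det$cells$x_um), ]
  want <- centers[order(centers[, 1], centers[, 2]), ]
  expect_lt(max(abs(got$y_um / 10 - (want[, 1] - 0.5))), 1)
  expect_lt(max(abs(got$x_um / 10 - (want[, 2] - 0.5))), 1)

  # diagonal-touching pixels are one component (8-connectivity)
  m <- matrix(FALSE, 6, 6); m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE
  expect_equal(detect_cells(m, 1, min_area_um2 = 1)$count, 1)

  # a single component below min_area is filtered out
  small <- matrix(FALSE, 10, 10); small[5, 5] <- TRUE
  expect_equal(detect_cells(small, 10, min_area_um2 = 400)$count, 0)
})

test_that("component labelling matches an independent flood fill on random masks", {
  # oracle: iterative neighbourhood dilation restricted to the mask
  flood_count <- function(mask) {
    lab <- matrix(0L, nrow(mask), ncol(mask)); n <- 0L
    while (any(mask & lab == 0L)) {
      n <- n + 1L
      seedpt <- which(mask & lab == 0L)[1]
      cur <- matrix(FALSE, nrow(mask), ncol(mask)); cur[seedpt] <- TRUE
      repeat {
        grown <- cur
        idx <- which(cur, arr.ind = TRUE)
        for (dr in -1:1) for (dc in -1:1) {
          r <- idx[, 1] + dr; c <- idx[, 2] + dc
          ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
          grown[cbind(r[ok], c[ok])] <- TRUE
        }
        grown <- grown & mask
        if (identical(grown, cur)) break
        cur <- grown
      }
      lab[cur] <- n
    }
    n
  }
  withr::with_seed(11, {
    for (i in 1:5) {
      m <- matrix(runif(32 * 32) < 0.25, 32, 32)
      expect_equal(detect_cells(m, 1, min_area_um2 = 0)$count, flood_count(m))
    }
  })
})

test_that("retention is the count ratio to the baseline frame", {
  centers <- grid_centers(30, 200, 200, step = 26)
  frame <- disk_frame(200, 200, centers, radius_px = 4) / 255
  stack <- image_stack(list(frame, frame, frame), c(0, 300, 600), 10)
  res <- retention_timeseries(stack)
  expect_equal(res$table$retention_pct, c(100, 100, 100))
  expect_equal(res$table$count, rep(30, 3))

  # ROI excluding all cells at baseline -> undefined denominator
  empty_roi <- rect_roi("empty", 1900, 1990, 1900, 1990)
  expect_error(retention_timeseries(stack, empty_roi), "no detections")

  # fixed perfused-cell denominator convention
  res2 <- retention_timeseries(stack, config = list(total_cells = 60))
  expect_equal(res2$table$retention_pct, rep(50, 3))
})

test_that("zone retention validates overlap and reports empty zones as undefined", {
  sc <- default_tcell_scene(seed = 21)
  zr <- zone_retention(sc$gen$stack, sc$zones)
  truth <- sc$gen$truth$details$counts
  for (z in rownames(truth)) {
    got <- zr$table$count[zr$table$zone == z]
    expect_equal(got, unname(truth[z, ]))
  }

  # single all-covering zone equals whole-device retention
  whole <- rect_roi("whole", 0, 3000, 0, 3000)
  zw <- zone_retention(sc$gen$stack, list(whole))
  rw <- retention_timeseries(sc$gen$stack)
  expect_equal(zw$table$retention_pct, rw$table$retention_pct)

  # overlapping zones are rejected, naming the pair
  z1 <- rect_roi("A", 0, 1000, 0, 1000); z2 <- rect_roi("B", 500, 1500, 0, 1000)
  expect_error(zone_retention(sc$gen$stack, list(z1, z2)), "'A' and 'B' overlap")

  # a zone with no baseline cells is undefined, others unaffected
  corner <- rect_roi("corner", 2900, 2995, 2900, 2995)
  z3 <- zone_retention(sc$gen$stack, list(sc$zones[[1]], corner))
  expect_true("corner" %in% z3$undefined_zones)
  expect_equal(z3$table$count[z3$table$zone == "LS"],
               unname(truth["LS", ]))
  expect_true(all(is.na(z3$table$retention_pct[z3$table$zone == "corner"])))
})

test_that("zone-dependent survival yields the expected retention ordering", {
  sc <- default_tcell_scene(n_per_zone = 40, seed = 33)
  zr <- zone_retention(sc$gen$stack, sc$zones)
  at5 <- with(zr$table, setNames(retention_pct[time_min == 5], zone[time_min == 5]))
  expect_gt(at5["LS"], at5["MS"])
  expect_gt(at5["MS"], at5["HS"])
})

test_that("relative decrease matches the printed worked examples", {
  expect_equal(relative_decrease(60, 45), 25)
  expect_equal(relative_decrease(55, 20), 100 * 35 / 55)  # 63.6, printed as 63%
  expect_equal(relative_decrease(80, 80), 0)
  expect_error(relative_decrease(0, 10), "strictly positive")
})

test_that("infiltration distances are measured from the vessel boundary", {
  vm <- straight_vessel_mask(200, 200, center_row = 20, half_width_px = 5)
  px <- 10
  # cells at exactly 100, 200, 300 um below the vessel edge
  rows <- 25 + c(100, 200, 300) / px + 1   # first gel row is 26 (distance 0)
  centers <- cbind(rows, c(50, 100, 150))
  mask <- disk_frame(200, 200, centers, radius_px = 3, bg = 0, fg = 1) > 0.5
  res <- infiltration_analysis(mask, vm, px)
  expect_equal(res$count, 3)
  expect_equal(sort(res$distances_um), c(100, 200, 300), tolerance = 1e-9)
  expect_lte(res$mean_um, res$max_um)

  # a cell in the first ring outside the lumen scores distance zero
  ring <- matrix(FALSE, 200, 200); ring[26, 120] <- TRUE
  r0 <- infiltration_analysis(ring, vm, px, config = list(min_area_um2 = 0))
  expect_equal(r0$distances_um, 0)

  # cells entirely inside the lumen are excluded
  inside <- disk_frame(200, 200, cbind(20, 60), radius_px = 3, bg = 0, fg = 1) > 0.5
  ri <- infiltration_analysis(inside, vm, px)
  expect_equal(ri$count, 0)
  expect_equal(ri$intravascular_count, 1)
  expect_length(ri$distances_um, 0)

  expect_error(infiltration_analysis(mask, matrix(FALSE, 200, 200), px),
               "vessel mask is empty")
})

test_that("distance transform agrees with brute-force nearest-vessel search", {
  withr::with_seed(5, {
    for (i in 1:4) {
      vm <- matrix(FALSE, 64, 64)
      blobs <- cbind(sample(5:60, 3), sample(5:60, 3))
      for (b in seq_len(3))
        vm[pmax(1, blobs[b, 1] - 2):pmin(64, blobs[b, 1] + 2),
           pmax(1, blobs[b, 2] - 2):pmin(64, blobs[b, 2] + 2)] <- TRUE
      cells <- cbind(sample(2:63, 10), sample(2:63, 10))
      mask <- matrix(FALSE, 64, 64); mask[cells] <- TRUE
      res <- infiltration_analysis(mask, vm, 1, config = list(min_area_um2 = 0))
      vpix <- which(vm, arr.ind = TRUE)
      brute <- apply(cells, 1, function(p)
        min(sqrt((vpix[, 1] - p[1])^2 + (vpix[, 2] - p[2])^2)))
      brute <- pmax(brute[brute > 0] - 1, 0)   # same boundary convention
      expect_lt(max(abs(sort(res$distances_um) - sort(brute))), sqrt(2) + 1e-9)
    }
  })
})

test_that("the quantification pipeline is deterministic", {
  sc <- default_tcell_scene(seed = 8)
  a <- zone_retention(sc$gen$stack, sc$zones)
  b <- zone_retention(sc$gen$stack, sc$zones)
  expect_identical(a, b)
})
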