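# shared fixtures; everything is built in code at test time

# minimal two-node, one-segment layout
single_segment_layout <- function(diameter_um = 500, length_um = 10000) {
  list(nodes = list(list(id = "a", x_um = 0, y_um = 0),
                    list(id = "b", x_um = length_um, y_um = 0)),
       segments = list(list(id = "s1", node_a = "a", node_b = "b",
                            diameter_um = diameter_um, length_um = length_um)),
       inlet = "a", outlet = "b")
}

# inlet -> two identical parallel branches -> outlet
parallel_layout <- function() {
  list(nodes = list(list(id = "in", x_um = 0, y_um = 0),
                    list(id = "t", x_um = 2500, y_um = 1000),
                    list(id = "b", x_um = 2500, y_um = -1000),
                    list(id = "out", x_um = 5000, y_um = 0)),
       segments = list(
         list(id = "t1", node_a = "in", node_b = "t", diameter_um = 400),
         list(id = "t2", node_a = "t", node_b = "out", diameter_um = 400),
         list(id = "b1", node_a = "in", node_b = "b", diameter_um = 400),
         list(id = "b2", node_a = "b", node_b = "out", diameter_um = 400)),
       inlet = "in", outlet = "out")
}

# independent hydraulic reference: resistance 128 mu L / (pi d^4), SI
hp_resistance <- function(d_um, L_um, mu_mpas) {
  128 * (mu_mpas * 1e-3) * (L_um * 1e-6) / (pi * (d_um * 1e-6)^4)
}

default_network <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_network(default_chip_layout())
    net
  }
})

# small 64x64 window on the bundled geometry, for fast permeability fits
small_domain <- local({
  dom <- NULL
  function() {
    if (is.null(dom)) dom <<- make_transport_domain(
      default_network(), window = c(2200, 3800, -800, 800), dx_um = 25)
    dom
  }
})

# strip domain with a gel ROI registered, for cheap inverse-crime fits
strip_with_roi <- function(length_um = 1500, dx_um = 20) {
  dom <- make_strip_domain(length_um = length_um, dx_um = dx_um)
  dom$rois$central_polygon <- rect_roi("central_polygon", 100, 400, 0, dx_um)
  dom
}

# noiseless central-polygon trace from the forward model
model_trace <- function(dom, D, P, times = seq(300, 3600, by = 300), dt_s = 5) {
  ser <- simulate_transport(dom, D, P, output_times_s = times, dt_s = dt_s)
  data.frame(time_s = times, value = ser$roi_traces$central_polygon)
}

# a frame of bright disks on a dark background, with recorded truth
disk_frame <- function(ny, nx, centers_px, radius_px = 4, bg = 20, fg = 220) {
  img <- matrix(bg, ny, nx)
  rr <- row(img); cc <- col(img)
  for (k in seq_len(nrow(centers_px)))
    img[(rr - centers_px[k, 1])^2 + (cc - centers_px[k, 2])^2 <= radius_px^2] <- fg
  img
}

# deterministic grid of n non-touching disk centers
grid_centers <- function(n, ny, nx, step = 22, margin = 12) {
  xs <- seq(margin, nx - margin, by = step)
  ys <- seq(margin, ny - margin, by = step)
  g <- expand.grid(row = ys, col = xs)
  stopifnot(nrow(g) >= n)
  as.matrix(g[seq_len(n), ])
}
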