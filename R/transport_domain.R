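#' Regions of interest
#'
#' An ROI is a simple polygon in device coordinates (µm, origin top-left,
#' x right, y increasing downward) with a label such as `"central_polygon"`,
#' `"HS"`, `"MS"`, `"LS"` or `"whole_device"`.
#'
#' @param label character label.
#' @param vertices numeric matrix (n x 2) of x/y vertices in µm, n >= 3.
#' @return an `roi` object.
#' @export
new_roi <- function(label, vertices) {
  vertices <- as.matrix(vertices)
  df_check(is.character(label) && length(label) == 1, "roi label must be a string")
  df_check(ncol(vertices) == 2 && nrow(vertices) >= 3,
           "roi '%s' needs an (n x 2) vertex matrix with n >= 3", label)
  df_check(all(is.finite(vertices)), "roi '%s' has non-finite vertices", label)
  df_check(!polygon_self_intersects(vertices),
           "roi '%s' polygon is self-intersecting", label)
  structure(list(label = label, vertices = vertices), class = "roi")
}

#' Axis-aligned rectangular ROI helper
#' @param label character label.
#' @param x0,x1,y0,y1 rectangle bounds in µm.
#' @return an `roi`.
#' @export
rect_roi <- function(label, x0, x1, y0, y1) {
  new_roi(label, cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}

# O(n^2) proper-crossing check; shared endpoints between adjacent edges allowed
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  e <- cbind(v, v[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2 per edge
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]              # skip adjacent (wrap) pair
    for (j in js) {
      p <- e[i, ]; q <- e[j, ]
      d1 <- cross(q[3] - q[1], q[4] - q[2], p[1] - q[1], p[2] - q[2])
      d2 <- cross(q[3] - q[1], q[4] - q[2], p[3] - q[1], p[4] - q[2])
      d3 <- cross(p[3] - p[1], p[4] - p[2], q[1] - p[1], q[2] - p[2])
      d4 <- cross(p[3] - p[1], p[4] - p[2], q[3] - p[1], q[4] - p[2])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
    }
  }
  FALSE
}

roi_contains <- function(roi, x_um, y_um) {
  mgcv::in.out(roi$vertices, cbind(x_um, y_um))
}

#' Build a 2D transport domain from a vascular network
#'
#' Rasterizes the channel graph onto a square plan-view grid: cells whose
#' centers lie within half a diameter of a segment axis form the lumen mask;
#' gel cells 4-adjacent to the lumen form the membrane band where the Robin
#' barrier flux acts. A `central_polygon` ROI covering the avascular gel
#' region enclosed by the two innermost channels is registered
#' automatically; further ROIs can be added via `rois`.
#'
#' The default window covers the central 3.2 mm of the plexus at 25 µm
#' spacing (128 x 128 cells), which resolves the membrane band while keeping
#' time-dependent simulations fast; the zero-flux outer boundary is far
#' enough from the lumen that it does not influence hour-scale transport at
#' dermal dextran diffusivities.
#'
#' @param network a `vascular_network`; default is the bundled chip layout.
#' @param window numeric `c(x0, x1, y0, y1)` region to grid, in µm.
#' @param dx_um grid spacing (µm), default 25.
#' @param rois optional list of extra [new_roi()] polygons.
#' @param central_polygon optional `roi` overriding the automatic central
#'   polygon.
#' @return a `transport_domain`: `dx_um`, `nx`, `ny`, `origin_um`, logical
#'   matrices `lumen` and `membrane` (rows = y, cols = x), and `rois`.
#' @export
make_transport_domain <- function(network = build_network(default_chip_layout()),
                                  window = c(1400, 4600, -1600, 1600),
                                  dx_um = 25, rois = list(),
                                  central_polygon = NULL) {
  df_check(dx_um > 0, "grid spacing must be positive")
  df_check(length(window) == 4 && window[1] < window[2] && window[3] < window[4],
           "window must be c(x0, x1, y0, y1) with x0 < x1 and y0 < y1")
  nx <- round((window[2] - window[1]) / dx_um)
  ny <- round((window[4] - window[3]) / dx_um)
  xc <- window[1] + (seq_len(nx) - 0.5) * dx_um
  yc <- window[3] + (seq_len(ny) - 0.5) * dx_um
  X <- matrix(xc, ny, nx, byrow = TRUE)
  Y <- matrix(yc, ny, nx)

  lumen <- matrix(FALSE, ny, nx)
  nd <- network$nodes
  for (k in seq_len(nrow(network$segments))) {
    s <- network$segments[k, ]
    a <- nd[nd$id == s$node_a, ]; b <- nd[nd$id == s$node_b, ]
    lumen <- lumen | (segment_dist2(X, Y, a$x_um, a$y_um, b$x_um, b$y_um) <=
                        (s$diameter_um / 2)^2)
  }
  df_check(any(lumen), "no lumen cells: window does not intersect the network")

  membrane <- adjacent_to(lumen) & !lumen

  roi_list <- list()
  if (is.null(central_polygon)) {
    # gap between the two innermost channels, inset 100 µm from the membrane
    # and 250 µm from the window edge
    inner <- inner_gap(network)
    if (!is.null(inner)) {
      central_polygon <- rect_roi("central_polygon",
                                  max(window[1] + 250, inner$x0),
                                  min(window[2] - 250, inner$x1),
                                  inner$y0 + 100, inner$y1 - 100)
    }
  }
  if (!is.null(central_polygon)) {
    df_check(inherits(central_polygon, "roi"), "central_polygon must be an roi")
    roi_list[[central_polygon$label]] <- central_polygon
  }
  for (r in rois) {
    df_check(inherits(r, "roi"), "rois must be a list of roi objects")
    roi_list[[r$label]] <- r
  }
  structure(list(dx_um = dx_um, nx = nx, ny = ny,
                 origin_um = c(window[1], window[3]),
                 lumen = lumen, membrane = membrane, rois = roi_list),
            class = "transport_domain")
}

segment_dist2 <- function(X, Y, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  tt <- pmin(1, pmax(0, ((X - ax) * vx + (Y - ay) * vy) / (vx^2 + vy^2)))
  (X - (ax + tt * vx))^2 + (Y - (ay + tt * vy))^2
}

adjacent_to <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  out[-1, ] <- out[-1, ] | mask[-ny, ]
  out[-ny, ] <- out[-ny, ] | mask[-1, ]
  out[, -1] <- out[, -1] | mask[, -nx]
  out[, -nx] <- out[, -nx] | mask[, -1]
  out
}

# y-extent of the avascular gap between the two innermost horizontal
# channels (hinted "high"), and the x-range they share; NULL if no hints
inner_gap <- function(network) {
  seg <- network$segments
  hi <- seg[!is.na(seg$zone_hint) & seg$zone_hint == "high", ]
  if (nrow(hi) == 0) return(NULL)
  nd <- network$nodes
  ya <- nd$y_um[match(hi$node_a, nd$id)]; yb <- nd$y_um[match(hi$node_b, nd$id)]
  xa <- nd$x_um[match(hi$node_a, nd$id)]; xb <- nd$x_um[match(hi$node_b, nd$id)]
  r <- max(hi$diameter_um) / 2
  ys <- (ya + yb) / 2
  top <- max(ys[ys < 0], na.rm = TRUE); bot <- min(ys[ys > 0], na.rm = TRUE)
  if (!is.finite(top) || !is.finite(bot)) return(NULL)
  list(y0 = top + r, y1 = bot - r, x0 = min(xa, xb), x1 = max(xa, xb))
}

#' Cell-center coordinates of a transport domain
#' @param domain a `transport_domain`.
#' @return list with vectors `x_um` (per column) and `y_um` (per row).
#' @export
domain_coords <- function(domain) {
  list(x_um = domain$origin_um[1] + (seq_len(domain$nx) - 0.5) * domain$dx_um,
       y_um = domain$origin_um[2] + (seq_len(domain$ny) - 0.5) * domain$dx_um)
}

#' One-dimensional strip domain for oracle comparisons
#'
#' A single row of cells with the lumen occupying the first `lumen_cells`
#' columns: the discrete analogue of a semi-infinite medium behind a planar
#' membrane, used to compare the finite-difference solver against the
#' closed-form [erfc_profile()] and [robin_profile()] solutions.
#'
#' @param length_um strip length (µm).
#' @param dx_um grid spacing (µm).
#' @param lumen_cells number of lumen columns at the left end.
#' @return a `transport_domain` with an ROI covering the whole gel.
#' @export
make_strip_domain <- function(length_um = 2000, dx_um = 10, lumen_cells = 2) {
  nx <- round(length_um / dx_um)
  lumen <- matrix(FALSE, 1, nx); lumen[1, seq_len(lumen_cells)] <- TRUE
  membrane <- adjacent_to(lumen) & !lumen
  structure(list(dx_um = dx_um, nx = nx, ny = 1L, origin_um = c(0, 0),
                 lumen = lumen, membrane = membrane, rois = list()),
            class = "transport_domain")
}

#' Distance of gel cell centers from the membrane face of a strip domain
#' @param domain a strip domain from [make_strip_domain()].
#' @return numeric vector: distance (µm) of each gel column center from the
#'   lumen/gel interface.
#' @export
strip_positions <- function(domain) {
  df_check(domain$ny == 1L, "strip_positions expects a 1-row strip domain")
  gel_cols <- which(!domain$lumen[1, ])
  (seq_along(gel_cols) - 0.5) * domain$dx_um
}
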