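#' Build a vascular channel network from a layout description
#'
#' The printed vascular plexus is represented as a graph of cylindrical
#' channel segments between positioned nodes. A layout is a plain list (or a
#' JSON/YAML file with the same shape) with elements:
#'
#' * `nodes`: list of `list(id, x_um, y_um)`
#' * `segments`: list of `list(id, node_a, node_b, diameter_um, length_um,
#'   zone_hint)` — `length_um` and `zone_hint` are optional; a missing length
#'   is taken as the Euclidean node distance, and `zone_hint`, when present,
#'   must be one of `"low"`, `"mid"`, `"high"` (segments without a hint are
#'   treated as feed lines outside the imaged shear zones)
#' * `inlet`, `outlet`: node ids
#' * `follicles` (optional): positions/diameters of the vertical hair-follicle
#'   channels, carried as metadata only (they are not perfused)
#'
#' @param layout a list as described above, or a path to a JSON or YAML file.
#' @return a `vascular_network` object: `nodes` (data.frame `id`, `x_um`,
#'   `y_um`), `segments` (data.frame `id`, `node_a`, `node_b`, `diameter_um`,
#'   `length_um`, `zone_hint`), `inlet`, `outlet`, `follicles`.
#' @seealso [default_chip_layout()] for the bundled plexus geometry,
#'   [solve_flow()] for the Poiseuille network solution.
#' @export
build_network <- function(layout) {
  if (is.character(layout)) layout <- read_layout_file(layout)
  df_check(is.list(layout), "layout must be a list or a path to JSON/YAML")
  for (f in c("nodes", "segments", "inlet", "outlet"))
    df_check(!is.null(layout[[f]]), "layout is missing the '%s' field", f)

  nodes <- do.call(rbind, lapply(layout$nodes, function(n) {
    df_check(!is.null(n$id) && !is.null(n$x_um) && !is.null(n$y_um),
             "node entry missing id/x_um/y_um")
    data.frame(id = as.character(n$id), x_um = as.numeric(n$x_um),
               y_um = as.numeric(n$y_um), stringsAsFactors = FALSE)
  }))
  df_check(!anyDuplicated(nodes$id), "duplicate node ids in layout")

  segments <- do.call(rbind, lapply(layout$segments, function(s) {
    df_check(!is.null(s$id), "segment entry missing id")
    for (f in c("node_a", "node_b", "diameter_um"))
      df_check(!is.null(s[[f]]), "segment '%s' missing field '%s'", s$id, f)
    a <- as.character(s$node_a); b <- as.character(s$node_b)
    df_check(a %in% nodes$id, "segment '%s' references unknown node '%s'", s$id, a)
    df_check(b %in% nodes$id, "segment '%s' references unknown node '%s'", s$id, b)
    df_check(a != b, "segment '%s' is a self-loop at node '%s'", s$id, a)
    len <- s$length_um
    if (is.null(len)) {
      pa <- nodes[nodes$id == a, ]; pb <- nodes[nodes$id == b, ]
      len <- sqrt((pa$x_um - pb$x_um)^2 + (pa$y_um - pb$y_um)^2)
    }
    df_check(as.numeric(s$diameter_um) > 0,
             "segment '%s' has non-positive diameter", s$id)
    df_check(as.numeric(len) > 0, "segment '%s' has non-positive length", s$id)
    hint <- if (is.null(s$zone_hint)) NA_character_ else as.character(s$zone_hint)
    if (!is.na(hint))
      df_check(hint %in% c("low", "mid", "high"),
               "segment '%s' has invalid zone_hint '%s'", s$id, hint)
    data.frame(id = as.character(s$id), node_a = a, node_b = b,
               diameter_um = as.numeric(s$diameter_um),
               length_um = as.numeric(len), zone_hint = hint,
               stringsAsFactors = FALSE)
  }))
  df_check(!anyDuplicated(segments$id), "duplicate segment ids in layout")

  inlet <- as.character(layout$inlet); outlet <- as.character(layout$outlet)
  df_check(inlet %in% nodes$id, "inlet node '%s' not declared", inlet)
  df_check(outlet %in% nodes$id, "outlet node '%s' not declared", outlet)
  df_check(inlet != outlet, "inlet and outlet must be distinct nodes")

  net <- structure(list(nodes = nodes, segments = segments, inlet = inlet,
                        outlet = outlet, follicles = layout$follicles),
                   class = "vascular_network")
  comp <- reachable_nodes(net, inlet)
  missing <- setdiff(nodes$id, comp)
  df_check(length(missing) == 0,
           "network is disconnected: node(s) %s unreachable from inlet",
           paste(missing, collapse = ", "))
  net
}

read_layout_file <- function(path) {
  df_check(file.exists(path), "layout file '%s' does not exist", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
}

# breadth-first reachability over the undirected segment graph
reachable_nodes <- function(net, from) {
  adj <- split(c(net$segments$node_b, net$segments$node_a),
               c(net$segments$node_a, net$segments$node_b))
  seen <- from; queue <- from
  while (length(queue)) {
    nb <- setdiff(unique(unlist(adj[queue], use.names = FALSE)), seen)
    seen <- c(seen, nb); queue <- nb
  }
  seen
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf("<vascular_network> %d nodes, %d segments, inlet '%s' -> outlet '%s'\n",
              nrow(x$nodes), nrow(x$segments), x$inlet, x$outlet))
  hints <- table(factor(x$segments$zone_hint, levels = c("low", "mid", "high")),
                 useNA = "ifany")
  cat("  zone hints:", paste(names(hints), hints, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Bundled approximation of the printed chip vasculature
#'
#' A 6 mm-footprint rectangular plexus of 0.5 mm-diameter channels matching
#' the published device concept: two innermost horizontal channels (the
#' high-shear zone), two outermost channels top and bottom (mid-shear), and
#' vertical interconnecting channels between them (low-shear). Short
#' unclassified feed stubs join the single inlet and outlet to the inner
#' channels. Seven 250 µm vertical hair-follicle channels sit in the central
#' avascular region and are carried as metadata. The exact CAD of the device
#' is not published; this layout is an explicit approximation that reproduces
#' the topology, the channel diameter, the footprint, and the relative
#' ordering of the three shear zones, and every dimension can be overridden
#' by supplying your own layout to [build_network()].
#'
#' @param diameter_um channel diameter (µm), applied to all segments.
#' @return a layout list accepted by [build_network()].
#' @export
default_chip_layout <- function(diameter_um = 500) {
  inner_y <- 750; outer_y <- 2250
  x0 <- 500; x1 <- 5500               # plexus span; feed stubs outside
  vx <- c(500, 2000, 4000, 5500)      # vertical interconnect positions
  nodes <- list(list(id = "inlet", x_um = 0, y_um = 0),
                list(id = "outlet", x_um = 6000, y_um = 0))
  segs <- list()
  add_node <- function(id, x, y) nodes[[length(nodes) + 1]] <<-
      list(id = id, x_um = x, y_um = y)
  add_seg <- function(id, a, b, hint = NA) segs[[length(segs) + 1]] <<-
      list(id = id, node_a = a, node_b = b, diameter_um = diameter_um,
           zone_hint = hint)

  for (side in c("t", "b")) {
    sgn <- if (side == "t") 1 else -1
    # junction nodes along the inner and outer horizontals
    for (i in seq_along(vx)) {
      add_node(sprintf("%si%d", side, i), vx[i], sgn * inner_y)
      add_node(sprintf("%so%d", side, i), vx[i], sgn * outer_y)
    }
    # inner horizontal channels (high shear)
    for (i in seq_len(length(vx) - 1))
      add_seg(sprintf("inner_%s%d", side, i), sprintf("%si%d", side, i),
              sprintf("%si%d", side, i + 1), "high")
    # outer horizontal channels (mid shear)
    for (i in seq_len(length(vx) - 1))
      add_seg(sprintf("outer_%s%d", side, i), sprintf("%so%d", side, i),
              sprintf("%so%d", side, i + 1), "mid")
    # vertical interconnects (low shear)
    for (i in seq_along(vx))
      add_seg(sprintf("vert_%s%d", side, i), sprintf("%si%d", side, i),
              sprintf("%so%d", side, i), "low")
    # feed stubs: inlet/outlet manifold reaches both inner and outer channel
    # ends directly (not part of a zone), so the vertical interconnects carry
    # only the inner<->outer exchange flow, as in the printed plexus
    add_seg(sprintf("feed_in_%si", side), "inlet", sprintf("%si1", side))
    add_seg(sprintf("feed_in_%so", side), "inlet", sprintf("%so1", side))
    add_seg(sprintf("feed_out_%si", side), sprintf("%si%d", side, length(vx)),
            "outlet")
    add_seg(sprintf("feed_out_%so", side), sprintf("%so%d", side, length(vx)),
            "outlet")
  }
  follicles <- lapply(seq(1500, 4500, length.out = 7), function(x)
    list(x_um = x, y_um = 0, diameter_um = 250, depth_um = 2000))
  list(nodes = nodes, segments = segs, inlet = "inlet", outlet = "outlet",
       follicles = follicles)
}
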