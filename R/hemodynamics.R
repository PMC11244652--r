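#' Steady Poiseuille flow on a vascular network
#'
#' Solves the linear nodal-pressure system for laminar, fully developed flow
#' in a channel graph. Each segment contributes a hydraulic conductance
#' \eqn{g = \pi d^4 / (128 \mu L)} (Hagen–Poiseuille); the inlet node
#' receives the prescribed volumetric flow, the outlet pressure is pinned to
#' zero (pressures are gauge), and mass is conserved at every node by
#' construction. This is a 1D network reduction of the device's 3D flow
#' field: channels are long relative to their diameter and the Reynolds
#' number at perfusion rates of a few mL/min is well inside the laminar
#' regime, so segment-average wall shear is captured while junction-local
#' effects are not.
#'
#' @param network a `vascular_network` from [build_network()].
#' @param inlet_flow_ml_min inlet volumetric flow (mL/min). Default 2.4, the
#'   perfusion rate used for the device.
#' @param viscosity_mpas dynamic viscosity of the perfusate (mPa·s). Default
#'   1.0 (culture medium, close to water at 37 °C).
#' @return a `flow_solution`: `node_pressure_pa` (named vector),
#'   `segments` data.frame with signed `flow_ml_min` (positive `node_a` →
#'   `node_b`), `shear_dyn_cm2`, `zone` (from the layout hints, `NA` for feed
#'   segments), plus the inputs echoed.
#' @export
solve_flow <- function(network, inlet_flow_ml_min = 2.4, viscosity_mpas = 1.0) {
  df_check(inherits(network, "vascular_network"), "network must be a vascular_network")
  df_check(inlet_flow_ml_min > 0, "inlet_flow_ml_min must be positive")
  df_check(viscosity_mpas > 0, "viscosity_mpas must be positive")

  nodes <- network$nodes$id
  seg <- network$segments
  mu <- mpas_to_pas(viscosity_mpas)                    # Pa.s
  d <- um_to_m(seg$diameter_um); L <- um_to_m(seg$length_um)
  g <- pi * d^4 / (128 * mu * L)                       # m^3/(s.Pa)

  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  A <- matrix(0, n, n)
  ia <- idx[seg$node_a]; ib <- idx[seg$node_b]
  for (k in seq_len(nrow(seg))) {
    A[ia[k], ia[k]] <- A[ia[k], ia[k]] + g[k]
    A[ib[k], ib[k]] <- A[ib[k], ib[k]] + g[k]
    A[ia[k], ib[k]] <- A[ia[k], ib[k]] - g[k]
    A[ib[k], ia[k]] <- A[ib[k], ia[k]] - g[k]
  }
  b <- numeric(n)
  b[idx[network$inlet]] <- ml_min_to_um3_s(inlet_flow_ml_min) * 1e-18  # m^3/s
  keep <- setdiff(seq_len(n), idx[network$outlet])     # gauge: p(outlet) = 0
  p <- numeric(n)
  sol <- tryCatch(solve(A[keep, keep, drop = FALSE], b[keep]),
                  error = function(e) stop(errorCondition(
                    paste0("flow system is singular (isolated subgraph?): ",
                           conditionMessage(e)),
                    class = c("dermaflux_solver_error", "error"))))
  p[keep] <- sol

  q_m3_s <- g * (p[ia] - p[ib])                        # signed, a -> b
  seg$flow_ml_min <- um3_s_to_ml_min(q_m3_s * 1e18)
  seg$shear_dyn_cm2 <- wall_shear(seg$diameter_um, seg$flow_ml_min, viscosity_mpas)
  seg$zone <- seg$zone_hint

  structure(list(node_pressure_pa = stats::setNames(p, nodes), segments = seg,
                 inlet_flow_ml_min = inlet_flow_ml_min,
                 viscosity_mpas = viscosity_mpas, network = network),
            class = "flow_solution")
}

#' Poiseuille wall shear stress of a cylindrical channel
#'
#' \eqn{\tau = 32 \mu |Q| / (\pi d^3)}, reported in dyn/cm² (1 dyn/cm² =
#' 0.1 Pa) as conventional for endothelial shear.
#'
#' @param diameter_um channel diameter (µm).
#' @param flow_ml_min volumetric flow (mL/min); the sign is ignored.
#' @param viscosity_mpas dynamic viscosity (mPa·s).
#' @return wall shear stress (dyn/cm²), vectorised over the inputs.
#' @export
wall_shear <- function(diameter_um, flow_ml_min, viscosity_mpas = 1.0) {
  df_check(all(diameter_um > 0), "diameter must be positive")
  df_check(all(viscosity_mpas > 0), "viscosity must be positive")
  mu <- mpas_to_pas(viscosity_mpas)
  q <- abs(ml_min_to_um3_s(flow_ml_min)) * 1e-18       # m^3/s
  d <- um_to_m(diameter_um)
  pa_to_dyn_cm2(32 * mu * q / (pi * d^3))
}

#' Classify channel segments into shear zones
#'
#' When the layout carries `zone_hint`s (as the bundled geometry does) the
#' zones are taken from the geometry and the solved shears are used to
#' *verify* the physiological ordering mean(low) < mean(mid) < mean(high);
#' violations are flagged in the result, not raised. Without hints the
#' segments are split by two shear cutoffs.
#'
#' @param solution a `flow_solution` from [solve_flow()].
#' @param thresholds optional increasing pair of shear cutoffs (dyn/cm²)
#'   splitting segments into low/mid/high; required when the geometry has no
#'   `zone_hint`s.
#' @return a `zone_classification`: `zones` data.frame (`segment`, `zone`,
#'   `shear_dyn_cm2`), `zone_means` named vector, `ordering_ok` flag and
#'   `violations` character vector describing any ordering breach.
#' @export
classify_zones <- function(solution, thresholds = NULL) {
  df_check(inherits(solution, "flow_solution"), "solution must be a flow_solution")
  seg <- solution$segments
  have_hints <- any(!is.na(seg$zone_hint))
  if (have_hints) {
    zones <- seg$zone_hint
  } else {
    df_check(!is.null(thresholds) && length(thresholds) == 2 &&
               thresholds[1] < thresholds[2],
             "geometry has no zone hints; supply two increasing shear thresholds")
    zones <- cut(seg$shear_dyn_cm2, c(-Inf, thresholds, Inf),
                 labels = c("low", "mid", "high"))
    zones <- as.character(zones)
  }
  keep <- !is.na(zones)
  tab <- data.frame(segment = seg$id[keep], zone = zones[keep],
                    shear_dyn_cm2 = seg$shear_dyn_cm2[keep],
                    stringsAsFactors = FALSE)
  means <- tapply(tab$shear_dyn_cm2, factor(tab$zone, c("low", "mid", "high")),
                  mean)
  violations <- character(0)
  pairs <- list(c("low", "mid"), c("mid", "high"))
  for (p in pairs) {
    if (!is.na(means[p[1]]) && !is.na(means[p[2]]) && means[p[1]] >= means[p[2]])
      violations <- c(violations, sprintf(
        "mean shear in '%s' zone (%.3g) is not below '%s' zone (%.3g)",
        p[1], means[p[1]], p[2], means[p[2]]))
  }
  structure(list(zones = tab, zone_means = means,
                 ordering_ok = length(violations) == 0, violations = violations,
                 source = if (have_hints) "geometry_hints" else "thresholds"),
            class = "zone_classification")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> Q_in = %.3g mL/min, mu = %.3g mPa.s\n",
              x$inlet_flow_ml_min, x$viscosity_mpas))
  cat(sprintf("  pressure drop inlet->outlet: %.4g Pa\n",
              x$node_pressure_pa[x$network$inlet] -
                x$node_pressure_pa[x$network$outlet]))
  z <- classify_zones(x)
  print(round(z$zone_means, 3))
  invisible(x)
}

#' Net flow imbalance at interior nodes
#'
#' Diagnostic used by the conservation checks: the sum of signed segment
#' flows at each node other than the inlet/outlet, relative to inlet flow.
#'
#' @param solution a `flow_solution`.
#' @return named numeric vector of relative imbalances.
#' @export
node_imbalance <- function(solution) {
  seg <- solution$segments
  nodes <- solution$network$nodes$id
  net <- stats::setNames(numeric(length(nodes)), nodes)
  for (k in seq_len(nrow(seg))) {
    net[seg$node_a[k]] <- net[seg$node_a[k]] - seg$flow_ml_min[k]
    net[seg$node_b[k]] <- net[seg$node_b[k]] + seg$flow_ml_min[k]
  }
  interior <- setdiff(nodes, c(solution$network$inlet, solution$network$outlet))
  net[interior] / solution$inlet_flow_ml_min
}
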