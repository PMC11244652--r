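#' Run a pipeline stage from command-line style arguments
#'
#' The programmatic core of the `dermaflux` command-line tool
#' (`inst/cli/dermaflux.R`). The first argument selects the stage:
#' `hemodynamics`, `simulate-transport`, `fit-permeability`,
#' `fit-diffusivity`, `quantify-retention`, `quantify-infiltration`, or
#' `synth`; the rest are that stage's options (see `--help` per stage).
#' Each run writes its outputs plus a `*_provenance.json` record of the
#' configuration, package version and seed. Inputs are never mutated.
#'
#' @param args character vector of arguments, e.g.
#'   `c("hemodynamics", "--geometry", "default", "--out", "shear.csv")`.
#' @return exit status, invisibly: 0 on success, 2 on validation/config
#'   errors, 1 on runtime errors.
#' @export
run_pipeline <- function(args) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    message("usage: dermaflux <stage> [options]\n",
            "stages: hemodynamics | simulate-transport | fit-permeability | ",
            "fit-diffusivity | quantify-retention | quantify-infiltration | synth")
    return(invisible(0L))
  }
  stage <- args[1]; rest <- args[-1]
  handler <- switch(stage,
                    "hemodynamics" = cli_hemodynamics,
                    "simulate-transport" = cli_simulate_transport,
                    "fit-permeability" = cli_fit_permeability,
                    "fit-diffusivity" = cli_fit_diffusivity,
                    "quantify-retention" = cli_quantify_retention,
                    "quantify-infiltration" = cli_quantify_infiltration,
                    "synth" = cli_synth,
                    NULL)
  if (is.null(handler)) {
    message("unknown stage '", stage, "'")
    return(invisible(2L))
  }
  tryCatch({
    handler(rest)
    invisible(0L)
  }, dermaflux_validation_error = function(e) {
    message("validation error: ", conditionMessage(e))
    invisible(2L)
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    invisible(1L)
  })
}

cli_parse <- function(args, option_list, usage) {
  parser <- optparse::OptionParser(option_list = option_list, usage = usage)
  optparse::parse_args(parser, args = args)
}

load_geometry <- function(spec) {
  if (identical(spec, "default")) build_network(default_chip_layout())
  else build_network(spec)
}

cli_hemodynamics <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--geometry", default = "default",
                          help = "layout JSON/YAML path, or 'default'"),
    optparse::make_option("--flow-ml-min", type = "double", default = 2.4,
                          dest = "flow"),
    optparse::make_option("--viscosity-mpas", type = "double", default = 1.0,
                          dest = "visc"),
    optparse::make_option("--out", default = "shear.csv")),
    "dermaflux hemodynamics [options]")
  net <- load_geometry(opt$geometry)
  fs <- solve_flow(net, opt$flow, opt$visc)
  z <- classify_zones(fs)
  tab <- fs$segments[, c("id", "node_a", "node_b", "diameter_um", "length_um",
                         "flow_ml_min", "shear_dyn_cm2", "zone")]
  utils::write.csv(tab, opt$out, row.names = FALSE)
  if (!z$ordering_ok)
    message("warning: ", paste(z$violations, collapse = "; "))
  write_provenance(prov_path(opt$out), "hemodynamics",
                   opt[setdiff(names(opt), "help")])
  message(sprintf("hemodynamics: %d segments -> %s (zone means low/mid/high = %s dyn/cm2)",
                  nrow(tab), opt$out,
                  paste(signif(z$zone_means, 3), collapse = "/")))
}

cli_simulate_transport <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--geometry", default = "default"),
    optparse::make_option("--d-um2-s", type = "double", default = 16, dest = "D"),
    optparse::make_option("--p-um-s", type = "double", default = 0.62, dest = "P"),
    optparse::make_option("--duration-min", type = "double", default = 60,
                          dest = "duration"),
    optparse::make_option("--interval-min", type = "double", default = 5,
                          dest = "interval"),
    optparse::make_option("--out-prefix", default = "transport", dest = "prefix")),
    "dermaflux simulate-transport [options]")
  dom <- make_transport_domain(load_geometry(opt$geometry))
  times <- seq(0, opt$duration * 60, by = opt$interval * 60)
  ser <- simulate_transport(dom, opt$D, opt$P, output_times_s = times)
  stack <- image_stack(ser$fields, times, dom$dx_um, channel = "dextran")
  write_image_stack(stack, paste0(opt$prefix, ".tif"))
  tr <- ser$roi_traces
  long <- do.call(rbind, lapply(names(tr)[-1], function(nm)
    data.frame(time_s = tr$time_s, roi = nm, mean = tr[[nm]])))
  utils::write.csv(long, paste0(opt$prefix, "_traces.csv"), row.names = FALSE)
  write_provenance(paste0(opt$prefix, "_provenance.json"), "simulate-transport",
                   opt[setdiff(names(opt), "help")])
  message(sprintf("simulate-transport: %d frames -> %s.tif", length(times),
                  opt$prefix))
}

cli_fit_permeability <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--trace", default = NULL),
    optparse::make_option("--geometry", default = "default"),
    optparse::make_option("--diffusivity", type = "double", default = NULL,
                          dest = "D"),
    optparse::make_option("--out", default = "fit.json")),
    "dermaflux fit-permeability --trace trace.csv --diffusivity D [options]")
  df_check(!is.null(opt$trace), "--trace is required")
  df_check(!is.null(opt$D), "--diffusivity is required")
  obs <- read_trace_csv(opt$trace)
  dom <- make_transport_domain(load_geometry(opt$geometry))
  fit <- fit_permeability(obs, dom, opt$D)
  write_fit_result(fit, opt$out)
  utils::write.csv(fit$residuals, sub("\\.json$", "_residuals.csv", opt$out),
                   row.names = FALSE)
  write_provenance(prov_path(opt$out), "fit-permeability",
                   opt[setdiff(names(opt), "help")])
  message(sprintf("fit-permeability: P = %.4g um/s (%s) -> %s", fit$estimate,
                  if (fit$converged) "converged" else "NOT converged", opt$out))
}

cli_fit_diffusivity <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--obs", default = NULL),
    optparse::make_option("--out", default = "fit.json")),
    "dermaflux fit-diffusivity --obs obs.csv [options]")
  df_check(!is.null(opt$obs), "--obs is required")
  obs <- read_trace_csv(opt$obs)
  df_check("distance_um" %in% names(obs),
           "diffusivity fitting needs a distance_um column")
  fit <- fit_diffusivity(obs)
  write_fit_result(fit, opt$out)
  write_provenance(prov_path(opt$out), "fit-diffusivity",
                   opt[setdiff(names(opt), "help")])
  message(sprintf("fit-diffusivity: D = %.4g um2/s (%s) -> %s", fit$estimate,
                  if (fit$converged) "converged" else "NOT converged", opt$out))
}

cli_quantify_retention <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--stack", default = NULL),
    optparse::make_option("--rois", default = NULL,
                          help = "zone ROI JSON (optional; whole device if absent)"),
    optparse::make_option("--baseline-index", type = "integer", default = 1,
                          dest = "baseline"),
    optparse::make_option("--out", default = "retention.csv")),
    "dermaflux quantify-retention --stack stack.tif [options]")
  df_check(!is.null(opt$stack), "--stack is required")
  stack <- read_image_stack(opt$stack)
  if (is.null(opt$rois)) {
    res <- retention_timeseries(stack, baseline_index = opt$baseline)
    tab <- res$table; tab$zone <- "whole_device"
  } else {
    zones <- read_rois(opt$rois)
    tab <- zone_retention(stack, zones, baseline_index = opt$baseline)$table
  }
  utils::write.csv(tab, opt$out, row.names = FALSE)
  write_provenance(prov_path(opt$out), "quantify-retention",
                   opt[setdiff(names(opt), "help")])
  message(sprintf("quantify-retention: %d rows -> %s", nrow(tab), opt$out))
}

cli_quantify_infiltration <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--cells", default = NULL,
                          help = "endpoint cell image TIFF"),
    optparse::make_option("--vessels", default = NULL, help = "vessel mask TIFF"),
    optparse::make_option("--pixel-size-um", type = "double", default = NULL,
                          dest = "px"),
    optparse::make_option("--out", default = "infiltration.csv")),
    "dermaflux quantify-infiltration --cells c.tif --vessels v.tif --pixel-size-um PX")
  for (f in c("cells", "vessels", "px"))
    df_check(!is.null(opt[[f]]), "--%s is required",
             c(cells = "cells", vessels = "vessels", px = "pixel-size-um")[f])
  img <- tiff::readTIFF(opt$cells)
  if (length(dim(img)) == 3) img <- img[, , 1]
  vm <- read_mask(opt$vessels)
  res <- infiltration_analysis(binarize(img), vm, opt$px)
  utils::write.csv(data.frame(distance_um = res$distances_um), opt$out,
                   row.names = FALSE)
  jsonlite::write_json(list(count = res$count, mean_um = res$mean_um,
                            max_um = res$max_um,
                            intravascular_count = res$intravascular_count),
                       sub("\\.csv$", "_summary.json", opt$out),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(prov_path(opt$out), "quantify-infiltration",
                   opt[setdiff(names(opt), "help")])
  message(sprintf("quantify-infiltration: %d cells, mean %.1f um -> %s",
                  res$count, res$mean_um, opt$out))
}

cli_synth <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--scenario", default = "dextran",
                          help = "dextran | tcell | infiltration"),
    optparse::make_option("--seed", type = "integer", default = 1),
    optparse::make_option("--noise-sd", type = "double", default = 0.05,
                          dest = "noise"),
    optparse::make_option("--out", default = "synth_out")),
    "dermaflux synth --scenario S --seed N --out dir/")
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(opt$out, ...)
  if (opt$scenario == "dextran") {
    dom <- make_transport_domain()
    g <- gen_dextran_timelapse(dom, noise_sd = opt$noise, seed = opt$seed)
    for (nm in names(g$stacks))
      write_image_stack(g$stacks[[nm]], p(paste0("dextran_", nm, ".tif")))
    write_rois(dom$rois, p("rois.json"))
    truth_json(g$truth, p("truth.json"))
  } else if (opt$scenario == "tcell") {
    sc <- default_tcell_scene(seed = opt$seed, noise_sd = opt$noise)
    write_image_stack(sc$gen$stack, p("tcell_stack.tif"))
    write_mask(sc$gen$vessel_mask, p("vessel_mask.tif"))
    write_rois(sc$zones, p("zones.json"))
    truth_json(sc$gen$truth, p("truth.json"))
  } else if (opt$scenario == "infiltration") {
    vm <- straight_vessel_mask(256, 256, center_row = 24, half_width_px = 6)
    g <- gen_infiltration_endpoint(vm, 10, n_cells = 22,
                                   infiltration_model("with_epidermis"),
                                   noise_sd = opt$noise, seed = opt$seed)
    write_image_stack(image_stack(list(g$image), 0, 10, "th1_endpoint"),
                      p("infiltration.tif"))
    write_mask(vm, p("vessel_mask.tif"))
    truth_json(g$truth, p("truth.json"))
  } else df_validation_error("unknown scenario '%s'", opt$scenario)
  write_provenance(p("provenance.json"), "synth",
                   opt[setdiff(names(opt), "help")], seed = opt$seed)
  message(sprintf("synth: scenario '%s' (seed %d) -> %s", opt$scenario,
                  opt$seed, opt$out))
}

truth_json <- function(truth, path) {
  jsonlite::write_json(list(scenario_id = truth$scenario_id, seed = truth$seed,
                            parameters = as.list(truth$parameters),
                            details = truth$details),
                       path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

prov_path <- function(out) {
  sub("\\.[A-Za-z0-9]+$", "_provenance.json", out)
}

#' Ready-made three-zone T-cell perfusion scene
#'
#' Three parallel vessel bands labelled LS/MS/HS with the zone-dependent
#' early survival probabilities of the reference scenario (5-min survival
#' 0.8 / 0.55 / 0.45, zone-independent 0.5 thereafter).
#'
#' @param ny,nx image size (px).
#' @param pixel_size_um µm per pixel.
#' @param n_per_zone baseline cells per zone.
#' @param survival5 named per-zone 5-min survival.
#' @param survival10 shared second-interval survival.
#' @param noise_sd,seed passed to [gen_tcell_perfusion()].
#' @return list with `gen` (generator output), `zones`, `vessel_mask`.
#' @export
default_tcell_scene <- function(ny = 300, nx = 300, pixel_size_um = 10,
                                n_per_zone = 30,
                                survival5 = c(LS = 0.8, MS = 0.55, HS = 0.45),
                                survival10 = 0.5, noise_sd = 0, seed = 1) {
  third <- floor(ny / 3)
  rows <- list(LS = round(third * 0.5), MS = round(third * 1.5),
               HS = round(third * 2.5))
  vm <- matrix(FALSE, ny, nx)
  for (r in rows) vm[(r - 14):(r + 14), ] <- TRUE
  zones <- lapply(names(rows), function(z)
    rect_roi(z, 0, nx * pixel_size_um,
             (rows[[z]] - third / 2 + 1) * pixel_size_um,
             (rows[[z]] + third / 2 - 1) * pixel_size_um))
  surv <- lapply(names(rows), function(z) c(survival5[[z]], survival10))
  names(surv) <- names(rows)
  gen <- gen_tcell_perfusion(zones, vm, pixel_size_um,
                             attach_counts = stats::setNames(
                               rep(n_per_zone, 3), names(rows)),
                             survival = surv, noise_sd = noise_sd, seed = seed)
  list(gen = gen, zones = zones, vessel_mask = vm)
}
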