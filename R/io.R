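#' Write an image stack as multi-frame TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages; timestamps, pixel size and
#' channel go to a sidecar JSON (`<path>.json`) rather than TIFF tags, for
#' portability across readers. Intensities must lie in `[0, 1]` (the
#' package-wide convention for rendered images and normalised
#' concentrations).
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param sidecar sidecar JSON path; default `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, sidecar = paste0(path, ".json")) {
  df_check(inherits(stack, "image_stack"), "stack must be an image_stack")
  rng <- range(unlist(lapply(stack$frames, range)))
  df_check(rng[1] >= 0 && rng[2] <= 1,
           "frame intensities must lie in [0, 1] for TIFF output (found %g..%g)",
           rng[1], rng[2])
  tiff::writeTIFF(stack$frames, path, bits.per.sample = 32L)
  jsonlite::write_json(list(timestamps_s = stack$timestamps_s,
                            pixel_size_um = stack$pixel_size_um,
                            channel = stack$channel,
                            origin_um = stack$origin_um),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#' @param path TIFF path; sidecar is `paste0(path, ".json")` unless given.
#' @param sidecar sidecar JSON path.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, sidecar = paste0(path, ".json")) {
  df_check(file.exists(path), "TIFF '%s' does not exist", path)
  df_check(file.exists(sidecar), "sidecar '%s' does not exist", sidecar)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df_check(length(meta$timestamps_s) == length(frames),
           "TIFF has %d frames but sidecar lists %d timestamps",
           length(frames), length(meta$timestamps_s))
  image_stack(frames, meta$timestamps_s, meta$pixel_size_um,
              channel = if (is.null(meta$channel)) "unknown" else meta$channel,
              origin_um = if (is.null(meta$origin_um)) c(0, 0) else meta$origin_um)
}

#' Write / read a single-frame mask TIFF
#' @param mask logical or 0/1 matrix.
#' @param path TIFF path.
#' @return `path` / logical matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)),
                  path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  df_check(file.exists(path), "mask TIFF '%s' does not exist", path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Write / read ROI polygons as JSON
#'
#' Format: an array of `{"label": ..., "vertices_um": [[x, y], ...]}`
#' objects, coordinates in µm with the origin top-left and y downward.
#'
#' @param rois list of [new_roi()] objects.
#' @param path JSON path.
#' @return `path` / list of `roi`.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(lapply(rois, function(r)
    list(label = r$label, vertices_um = unname(apply(r$vertices, 1, as.list)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df_check(file.exists(path), "ROI JSON '%s' does not exist", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    v <- do.call(rbind, lapply(r$vertices_um, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    new_roi(r$label, v)
  })
}

#' Read an ROI intensity trace or distance-resolved observation CSV
#'
#' Accepts `time_s,value` (ROI traces) or `time_s,distance_um,value`
#' (distance-resolved concentrations). Times must be sorted within each
#' distance.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_trace_csv <- function(path) {
  df_check(file.exists(path), "trace CSV '%s' does not exist", path)
  tab <- utils::read.csv(path)
  df_check(all(c("time_s", "value") %in% names(tab)),
           "trace CSV must have columns time_s, value")
  key <- if ("distance_um" %in% names(tab)) tab$distance_um else rep(1, nrow(tab))
  sorted <- all(unlist(tapply(tab$time_s, key, function(t) !is.unsorted(t, strictly = TRUE))))
  df_check(sorted,
           "trace times are not strictly increasing: sort the CSV by time_s first")
  tab
}

#' Write a provenance record alongside pipeline outputs
#'
#' Every CLI run emits a JSON record of the subcommand, its parameters, the
#' seed, and the package version, sufficient to reproduce the run.
#'
#' @param path output JSON path.
#' @param subcommand character.
#' @param params named list of parameters.
#' @param seed integer or NULL.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, subcommand, params, seed = NULL) {
  jsonlite::write_json(list(
    tool = "dermaflux",
    version = as.character(utils::packageVersion("dermaflux")),
    subcommand = subcommand, parameters = params, seed = seed,
    units = list(length = "um", time = "s", flow = "mL/min",
                 viscosity = "mPa.s", shear = "dyn/cm2",
                 permeability = "um/s", diffusivity = "um2/s")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Serialise a fit result to JSON
#' @param fit a `fit_result`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  df_check(inherits(fit, "fit_result"), "fit must be a fit_result")
  jsonlite::write_json(list(parameter = fit$parameter, estimate = fit$estimate,
                            sse = fit$sse, bounds = fit$bounds,
                            iterations = fit$iterations,
                            converged = fit$converged,
                            flat_objective = fit$flat_objective),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
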