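#' Time-lapse image stack
#'
#' Container for a fluorescence time-lapse: frames as numeric matrices
#' (rows = y, cols = x, intensities in any consistent scale), strictly
#' increasing timestamps, and the pixel size.
#'
#' @param frames list of numeric matrices, all the same shape.
#' @param timestamps_s numeric vector, one per frame, strictly increasing.
#' @param pixel_size_um pixel edge length (µm/px), > 0.
#' @param channel free-text channel label.
#' @param origin_um device coordinates (µm) of the image's top-left corner,
#'   so ROIs drawn in device coordinates can be sampled on the stack.
#' @return an `image_stack`.
#' @export
image_stack <- function(frames, timestamps_s, pixel_size_um,
                        channel = "unknown", origin_um = c(0, 0)) {
  df_check(is.list(frames) && length(frames) >= 1, "frames must be a non-empty list")
  dims <- vapply(frames, dim, integer(2))
  df_check(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
           "all frames must have the same dimensions")
  df_check(length(timestamps_s) == length(frames),
           "need one timestamp per frame (%d frames, %d timestamps)",
           length(frames), length(timestamps_s))
  df_check(all(diff(timestamps_s) > 0) || length(timestamps_s) == 1,
           "timestamps must be strictly increasing")
  df_check(pixel_size_um > 0, "pixel size must be positive")
  df_check(length(origin_um) == 2 && all(is.finite(origin_um)),
           "origin_um must be a length-2 numeric")
  structure(list(frames = frames, timestamps_s = as.numeric(timestamps_s),
                 pixel_size_um = pixel_size_um, channel = channel,
                 origin_um = as.numeric(origin_um)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px (%.3g um/px), t = %s s, channel '%s'\n",
              length(x$frames), d[1], d[2], x$pixel_size_um,
              paste(x$timestamps_s, collapse = ", "), x$channel))
  invisible(x)
}

#' Binarize an intensity frame
#'
#' Rescales the frame to the 8-bit range (min -> 0, max -> 255) to
#' standardise exposure, then thresholds: Otsu's method on the rescaled
#' histogram by default, or a fixed cutoff on the 0-255 scale. Pixels
#' strictly above the threshold become foreground.
#'
#' @param frame numeric matrix.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold cutoff on the 0-255 scale, required for
#'   `method = "fixed"`.
#' @return logical mask with attribute `threshold_8bit` (the cutoff used).
#' @export
binarize <- function(frame, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  df_check(is.matrix(frame) && length(frame) > 0, "frame must be a non-empty matrix")
  rng <- range(frame)
  if (rng[1] == rng[2]) {
    df_check(method == "fixed",
             "constant-intensity frame: Otsu is undefined, supply a fixed threshold")
    f8 <- matrix(0, nrow(frame), ncol(frame))
  } else {
    f8 <- round(255 * (frame - rng[1]) / (rng[2] - rng[1]))
  }
  thr <- if (method == "otsu") {
    255 * EBImage::otsu(EBImage::Image(f8 / 255), range = c(0, 1), levels = 256)
  } else {
    df_check(!is.null(threshold), "method 'fixed' requires a threshold")
    threshold
  }
  mask <- f8 > thr
  attr(mask, "threshold_8bit") <- thr
  attr(mask, "method") <- method
  mask
}

# 8-connected component labelling restricted to foreground pixels
label_components_8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  nextlab <- 0L
  offs <- c(-1L, 1L, -ny, ny, -ny - 1L, -ny + 1L, ny - 1L, ny + 1L)
  for (p in fg) {
    if (lab[p] != 0L) next
    nextlab <- nextlab + 1L
    stack <- p; lab[p] <- nextlab
    while (length(stack)) {
      q <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- ((q - 1L) %% ny) + 1L
      nb <- q + offs
      ok <- nb >= 1L & nb <= ny * nx
      if (r == 1L) ok <- ok & !(offs %in% c(-1L, -ny - 1L, ny - 1L))
      if (r == ny) ok <- ok & !(offs %in% c(1L, -ny + 1L, ny + 1L))
      nb <- nb[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Detect cells in a binary mask
#'
#' Connected components (8-connectivity) at or above a minimum area become
#' detections; touching cells count as one component, matching plain
#' ImageJ-style mask counting. Centroids are reported in µm with the pixel
#' center convention (pixel `[r, c]` center at `((c-0.5)px, (r-0.5)px)`).
#'
#' @param mask logical matrix (e.g. from [binarize()]).
#' @param pixel_size_um µm per pixel.
#' @param min_area_um2 minimum component area; default the equivalent of
#'   4 px².
#' @return a `cell_detections`: data.frame `cells` (`x_um`, `y_um`,
#'   `area_um2`, `n_px`) and `count`.
#' @export
detect_cells <- function(mask, pixel_size_um,
                         min_area_um2 = 4 * pixel_size_um^2) {
  df_check(is.matrix(mask), "mask must be a matrix")
  df_check(pixel_size_um > 0, "pixel size must be positive")
  lab <- label_components_8(mask != 0)
  if (max(lab) == 0) {
    cells <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        area_um2 = numeric(0), n_px = integer(0))
    return(structure(list(cells = cells, count = 0L,
                          pixel_size_um = pixel_size_um), class = "cell_detections"))
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  rr <- ((idx - 1) %% nrow(mask)) + 1
  cc <- ((idx - 1) %/% nrow(mask)) + 1
  n_px <- as.integer(tabulate(l))
  x_um <- (tapply(cc, l, mean) - 0.5) * pixel_size_um
  y_um <- (tapply(rr, l, mean) - 0.5) * pixel_size_um
  cells <- data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                      area_um2 = n_px * pixel_size_um^2, n_px = n_px)
  cells <- cells[cells$area_um2 >= min_area_um2, , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(cells = cells, count = nrow(cells),
                 pixel_size_um = pixel_size_um), class = "cell_detections")
}

#' Mean ROI intensity trace of an image stack
#'
#' Per-frame mean intensity of pixels whose centers fall inside the
#' polygon: the measurement applied to dextran time-lapses before
#' permeability fitting (pixel-level imaging noise is averaged down by the
#' ROI, as in the real assay).
#'
#' @param stack an [image_stack()].
#' @param roi an [new_roi()] polygon (µm coordinates).
#' @return data.frame with `time_s` and `value` columns.
#' @export
stack_roi_trace <- function(stack, roi) {
  df_check(inherits(stack, "image_stack"), "stack must be an image_stack")
  df_check(inherits(roi, "roi"), "roi must be an roi object")
  d <- dim(stack$frames[[1]]); px <- stack$pixel_size_um
  xc <- stack$origin_um[1] + (seq_len(d[2]) - 0.5) * px
  yc <- stack$origin_um[2] + (seq_len(d[1]) - 0.5) * px
  X <- matrix(xc, d[1], d[2], byrow = TRUE)
  Y <- matrix(yc, d[1], d[2])
  inside <- matrix(roi_contains(roi, as.vector(X), as.vector(Y)), d[1], d[2])
  df_check(any(inside), "roi '%s' covers no pixels", roi$label)
  data.frame(time_s = stack$timestamps_s,
             value = vapply(stack$frames, function(f) mean(f[inside]),
                            numeric(1)))
}

count_in_roi <- function(det, roi) {
  if (is.null(roi)) return(det$count)
  if (det$count == 0) return(0L)
  sum(roi_contains(roi, det$cells$x_um, det$cells$y_um))
}

#' Cell retention over time within a region
#'
#' Counts detected cells inside the ROI in every frame and expresses each
#' count relative to the baseline frame:
#' `retention_pct(t) = 100 * N(t) / N(t_baseline)`. Cell identity is not
#' tracked across frames — a detaching cell and a newly arriving one trade
#' off, exactly as in interval-counting workflows. With
#' `config$total_cells` set, the denominator is that fixed perfused-cell
#' number instead of the baseline count.
#'
#' @param stack an [image_stack()].
#' @param roi an [new_roi()] polygon, or `NULL` for the whole frame.
#' @param baseline_index 1-based frame index of the baseline (default 1).
#' @param config detection options: `method`/`threshold` for [binarize()],
#'   `min_area_um2` for [detect_cells()], optional `total_cells`.
#' @return a `retention_result`: data.frame `time_s`, `time_min`, `count`,
#'   `retention_pct`.
#' @export
retention_timeseries <- function(stack, roi = NULL, baseline_index = 1,
                                 config = list()) {
  df_check(inherits(stack, "image_stack"), "stack must be an image_stack")
  df_check(baseline_index >= 1 && baseline_index <= length(stack$frames),
           "baseline_index out of range")
  counts <- vapply(stack$frames, function(f) {
    det <- detect_frame(f, stack$pixel_size_um, config)
    as.integer(count_in_roi(det, roi))
  }, integer(1))
  denom <- if (!is.null(config$total_cells)) config$total_cells
           else counts[baseline_index]
  df_check(denom >= 1,
           "baseline frame contains no detections inside the ROI: retention undefined")
  structure(list(table = data.frame(time_s = stack$timestamps_s,
                                    time_min = stack$timestamps_s / 60,
                                    count = counts,
                                    retention_pct = 100 * counts / denom),
                 baseline_index = baseline_index, denominator = denom,
                 roi_label = if (is.null(roi)) "whole_device" else roi$label),
            class = "retention_result")
}

detect_frame <- function(frame, pixel_size_um, config) {
  mask <- binarize(frame,
                   method = if (is.null(config$method)) "otsu" else config$method,
                   threshold = config$threshold)
  min_area <- if (is.null(config$min_area_um2)) 4 * pixel_size_um^2
              else config$min_area_um2
  detect_cells(mask, pixel_size_um, min_area)
}

#' @export
print.retention_result <- function(x, ...) {
  cat(sprintf("<retention_result> roi '%s', baseline N = %d\n",
              x$roi_label, x$denominator))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-shear-zone retention
#'
#' Applies [retention_timeseries()] to each zone polygon after validating
#' that no two zones overlap on the pixel grid (zero-pixel tolerance). A
#' zone with no baseline detections is reported as undefined (`NA`
#' retention) without affecting the others.
#'
#' @param stack an [image_stack()].
#' @param zones list of [new_roi()] polygons (e.g. labels `LS`, `MS`, `HS`).
#' @param baseline_index baseline frame index.
#' @param config as in [retention_timeseries()].
#' @return a `zone_retention_result`: combined data.frame `table` with a
#'   `zone` column, plus `undefined_zones`.
#' @export
zone_retention <- function(stack, zones, baseline_index = 1, config = list()) {
  df_check(inherits(stack, "image_stack"), "stack must be an image_stack")
  df_check(length(zones) >= 1, "need at least one zone")
  labels <- vapply(zones, function(z) z$label, character(1))
  df_check(!anyDuplicated(labels), "zone labels must be unique")
  check_zone_overlap(stack, zones)

  rows <- list(); undefined <- character(0)
  for (z in zones) {
    res <- tryCatch(retention_timeseries(stack, z, baseline_index, config),
                    dermaflux_validation_error = function(e) NULL)
    if (is.null(res)) {
      undefined <- c(undefined, z$label)
      tab <- data.frame(time_s = stack$timestamps_s,
                        time_min = stack$timestamps_s / 60,
                        count = NA_integer_, retention_pct = NA_real_)
    } else tab <- res$table
    tab$zone <- z$label
    rows[[z$label]] <- tab
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 undefined_zones = undefined, baseline_index = baseline_index),
            class = "zone_retention_result")
}

check_zone_overlap <- function(stack, zones) {
  d <- dim(stack$frames[[1]]); px <- stack$pixel_size_um
  xs <- (seq_len(d[2]) - 0.5) * px
  ys <- (seq_len(d[1]) - 0.5) * px
  pts <- cbind(rep(xs, each = d[1]), rep(ys, d[2]))
  claimed <- matrix(FALSE, nrow(pts), length(zones))
  for (i in seq_along(zones))
    claimed[, i] <- roi_contains(zones[[i]], pts[, 1], pts[, 2])
  multi <- which(rowSums(claimed) > 1)
  if (length(multi)) {
    pair <- which(claimed[multi[1], ])[1:2]
    df_validation_error("zones '%s' and '%s' overlap on the pixel grid",
                        zones[[pair[1]]]$label, zones[[pair[2]]]$label)
  }
  invisible(TRUE)
}

#' Relative decrease between two retention percentages
#'
#' `100 * (p_early - p_late) / p_early`: the drop from an early time point
#' expressed as a percentage of the early value (e.g. 60% retained at 5 min
#' falling to 45% at 10 min is a 25% decrease).
#'
#' @param p_early retention at the earlier time (%), > 0.
#' @param p_late retention at the later time (%).
#' @return percentage decrease.
#' @export
relative_decrease <- function(p_early, p_late) {
  df_check(all(p_early > 0), "p_early must be strictly positive")
  100 * (p_early - p_late) / p_early
}

#' Infiltration distance of cells from the nearest vessel
#'
#' Computes the Euclidean distance transform of the vessel mask and reads it
#' at each detected cell centroid. Distances are measured from the vessel
#' boundary (the first pixel ring outside the lumen has distance zero);
#' cells whose centroid lies inside the vessel mask have not extravasated
#' and are excluded from the infiltrated count.
#'
#' @param cell_mask logical matrix of cell foreground (e.g. [binarize()]).
#' @param vessel_mask logical matrix of lumen pixels, same shape, non-empty.
#' @param pixel_size_um µm per pixel.
#' @param config detection options (`min_area_um2`).
#' @return an `infiltration_result`: `distances_um` (per infiltrated cell),
#'   `count`, `mean_um`, `max_um`, and the excluded `intravascular_count`.
#' @export
infiltration_analysis <- function(cell_mask, vessel_mask, pixel_size_um,
                                  config = list()) {
  df_check(is.matrix(vessel_mask) && any(vessel_mask != 0),
           "vessel mask is empty")
  df_check(all(dim(cell_mask) == dim(vessel_mask)),
           "cell and vessel masks must have the same shape")
  min_area <- if (is.null(config$min_area_um2)) 4 * pixel_size_um^2
              else config$min_area_um2
  det <- detect_cells(cell_mask, pixel_size_um, min_area)
  dist_px <- vessel_distance_px(vessel_mask)
  if (det$count == 0) {
    return(structure(list(distances_um = numeric(0), count = 0L,
                          mean_um = NaN, max_um = NaN,
                          intravascular_count = 0L),
                     class = "infiltration_result"))
  }
  rr <- pmin(pmax(round(det$cells$y_um / pixel_size_um + 0.5), 1), nrow(vessel_mask))
  cc <- pmin(pmax(round(det$cells$x_um / pixel_size_um + 0.5), 1), ncol(vessel_mask))
  dpx <- dist_px[cbind(rr, cc)]
  outside <- dpx > 0
  d_um <- pmax(dpx[outside] - 1, 0) * pixel_size_um
  structure(list(distances_um = d_um, count = sum(outside),
                 mean_um = if (any(outside)) mean(d_um) else NaN,
                 max_um = if (any(outside)) max(d_um) else NaN,
                 intravascular_count = sum(!outside)),
            class = "infiltration_result")
}

# Euclidean distance (px) of every pixel to the nearest vessel pixel;
# vessel pixels themselves get 0
vessel_distance_px <- function(vessel_mask) {
  inv <- matrix(1, nrow(vessel_mask), ncol(vessel_mask))
  inv[vessel_mask != 0] <- 0
  as.matrix(EBImage::distmap(inv, metric = "euclidean"))
}

#' @export
print.infiltration_result <- function(x, ...) {
  cat(sprintf("<infiltration_result> %d infiltrated cells (mean %.1f um, max %.1f um); %d intravascular\n",
              x$count, x$mean_um, x$max_um, x$intravascular_count))
  invisible(x)
}
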