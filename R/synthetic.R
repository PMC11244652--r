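#' Ground truth record for a synthetic scenario
#'
#' Every generator returns (alongside its images) a `ground_truth` carrying
#' the exact parameters and latent variables used, sufficient to score every
#' downstream pipeline output: recovery tests compare against this record,
#' never against re-measured values.
#'
#' @param scenario_id character scenario identifier.
#' @param seed integer RNG seed used.
#' @param parameters named numeric vector of scalar truths (e.g. `P_um_s`,
#'   `D_um2_s`).
#' @param details list of richer truths (per-frame counts, placed
#'   distances, positions, noise model).
#' @return a `ground_truth`.
#' @export
ground_truth <- function(scenario_id, seed, parameters = numeric(0),
                         details = list()) {
  df_check(is.character(scenario_id) && length(scenario_id) == 1,
           "scenario_id must be a string")
  structure(list(scenario_id = scenario_id, seed = as.integer(seed),
                 parameters = parameters, details = details),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> scenario '%s', seed %d\n", x$scenario_id, x$seed))
  if (length(x$parameters)) print(x$parameters)
  invisible(x)
}

#' Default dye panel for the permeability assay
#'
#' The two dextran tracers perfused through the device, with the
#' dermal-gel diffusivities and endothelial permeabilities reported for
#' them: 20 kDa (D = 16 µm²/s, P = 0.62 µm/s) and 40 kDa (D = 53 µm²/s,
#' P = 0.41 µm/s). Used as generator ground truth for recovery studies.
#'
#' @return named list of `list(D_um2_s, P_um_s)` per dye.
#' @export
default_dye_panel <- function() {
  list("20kDa" = list(D_um2_s = 16, P_um_s = 0.62),
       "40kDa" = list(D_um2_s = 53, P_um_s = 0.41))
}

#' Synthetic dextran leakage time-lapse
#'
#' Runs the barrier transport forward model per dye, maps concentration
#' linearly to fluorescence intensity, applies multiplicative Gaussian
#' imaging noise, and emits a frame every 5 simulated minutes for an hour
#' (the acquisition cadence of the permeability assay).
#'
#' @param domain a `transport_domain`.
#' @param dyes named list of `list(D_um2_s, P_um_s)`; default
#'   [default_dye_panel()].
#' @param C_lumen lumen concentration / intensity (a.u.).
#' @param noise_sd relative s.d. of multiplicative Gaussian noise
#'   (default 0.05; 0 for noiseless).
#' @param output_times_s frame times (s).
#' @param dt_s forward-model time step.
#' @param seed integer seed.
#' @return list with `stacks` (named list of [image_stack()] per dye),
#'   `series` (the noiseless `concentration_series` per dye) and `truth`
#'   (a [ground_truth()] with parameters `P_<dye>`, `D_<dye>`).
#' @export
gen_dextran_timelapse <- function(domain, dyes = default_dye_panel(),
                                  C_lumen = 1, noise_sd = 0.05,
                                  output_times_s = seq(0, 3600, by = 300),
                                  dt_s = 5, seed = 1) {
  df_check(noise_sd >= 0, "noise_sd must be non-negative")
  df_check(length(dyes) >= 1 && !is.null(names(dyes)), "dyes must be a named list")
  stacks <- list(); series <- list(); pars <- numeric(0)
  withr::with_seed(seed, {
    for (nm in names(dyes)) {
      dy <- dyes[[nm]]
      ser <- simulate_transport(domain, dy$D_um2_s, dy$P_um_s,
                                C_lumen = C_lumen,
                                output_times_s = output_times_s, dt_s = dt_s)
      frames <- lapply(ser$fields, function(f) {
        if (noise_sd > 0) {
          f <- f * (1 + noise_sd * matrix(stats::rnorm(length(f)),
                                          nrow(f), ncol(f)))
          # detector-style clamp: noise cannot push below zero or above the
          # source brightness (only saturated lumen pixels ever clip)
          f <- pmin(pmax(f, 0), C_lumen)
        }
        f
      })
      # timestamps must strictly increase; t = 0 is the pre-perfusion frame
      stacks[[nm]] <- image_stack(frames, output_times_s, domain$dx_um,
                                  channel = nm, origin_um = domain$origin_um)
      series[[nm]] <- ser
      pars[[paste0("P_", nm)]] <- dy$P_um_s
      pars[[paste0("D_", nm)]] <- dy$D_um2_s
    }
  })
  truth <- ground_truth("dextran_timelapse", seed, parameters = pars,
                        details = list(C_lumen = C_lumen, noise_sd = noise_sd,
                                       dyes = dyes))
  list(stacks = stacks, series = series, truth = truth)
}

# non-touching placement: sample pixel indices from `candidates`
# (matrix-ordered indices) keeping centers >= min_sep_px apart. A random
# greedy pass keeps placement close to uniform; if random packing saturates
# before n cells are placed, a deterministic raster-order packing (near the
# maximum achievable density) is sampled instead.
place_cells <- function(candidates, n, ny, min_sep_px, what) {
  df_check(length(candidates) >= n,
           "requested %d cells but only %d candidate pixels (%s)",
           n, length(candidates), what)
  greedy <- function(ordered, cap) {
    acc_r <- numeric(0); acc_c <- numeric(0); acc <- integer(0)
    for (p in ordered) {
      r <- ((p - 1) %% ny) + 1; cl <- ((p - 1) %/% ny) + 1
      if (length(acc) == 0 ||
          min((acc_r - r)^2 + (acc_c - cl)^2) >= min_sep_px^2) {
        acc <- c(acc, p); acc_r <- c(acc_r, r); acc_c <- c(acc_c, cl)
        if (length(acc) == cap) break
      }
    }
    cbind(row = acc_r, col = acc_c, idx = acc)
  }
  got <- greedy(sample(candidates), n)
  if (nrow(got) < n) {
    slots <- greedy(sort(candidates), Inf)
    df_check(nrow(slots) >= n,
             "could not place %d non-touching cells (%s); reduce counts or radius",
             n, what)
    got <- slots[sample(nrow(slots), n), , drop = FALSE]
  }
  got[, c("row", "col"), drop = FALSE]
}

render_cell_frame <- function(dim_px, centers, radius_px = 3, blur_sigma_px = 1,
                              bg = 0.05, fg = 0.9, noise_sd = 0) {
  img <- matrix(bg, dim_px[1], dim_px[2])
  if (nrow(centers) > 0) {
    rr <- row(img); cc <- col(img)
    for (k in seq_len(nrow(centers))) {
      disk <- (rr - centers[k, 1])^2 + (cc - centers[k, 2])^2 <= radius_px^2
      img[disk] <- fg
    }
  }
  if (blur_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = blur_sigma_px))
  if (noise_sd > 0)
    img <- img * (1 + noise_sd * matrix(stats::rnorm(length(img)),
                                        nrow(img), ncol(img)))
  pmin(pmax(img, 0), 1)
}

#' Synthetic T-cell perfusion time-lapse with zone-dependent detachment
#'
#' Places cells uniformly on vessel pixels within each shear-zone polygon at
#' baseline; across each frame interval every cell persists independently
#' with its zone's survival probability (detached cells disappear). Frames
#' render the surviving cells as bright blurred disks. Exact per-frame,
#' per-zone survivor counts and positions are recorded as ground truth, so
#' zone-dependent early retention and zone-independent late retention can
#' both be expressed by choosing the per-interval probabilities.
#'
#' @param zones list of [new_roi()] polygons (e.g. `LS`, `MS`, `HS`).
#' @param vessel_mask logical matrix of vessel pixels.
#' @param pixel_size_um µm per pixel.
#' @param attach_counts named integer vector: baseline cells per zone label.
#' @param survival named list: per zone, a vector of per-interval survival
#'   probabilities (length = number of frames - 1).
#' @param frame_times_s frame times (s); default 0, 5 and 10 min.
#' @param cell_radius_px rendered disk radius (px), default 3.
#' @param blur_sigma_px Gaussian blur s.d. (px), default 1.
#' @param noise_sd multiplicative noise s.d., default 0.
#' @param seed integer seed.
#' @return list with `stack` ([image_stack()]), `vessel_mask`, and `truth`
#'   (`details$counts`: zone x frame survivor matrix; `details$positions`:
#'   per-frame list of pixel centers with zone labels).
#' @export
gen_tcell_perfusion <- function(zones, vessel_mask, pixel_size_um,
                                attach_counts, survival,
                                frame_times_s = c(0, 300, 600),
                                cell_radius_px = 3, blur_sigma_px = 1,
                                noise_sd = 0, seed = 1) {
  labels <- vapply(zones, function(z) z$label, character(1))
  df_check(all(labels %in% names(attach_counts)),
           "attach_counts must name every zone")
  df_check(all(labels %in% names(survival)), "survival must name every zone")
  nf <- length(frame_times_s)
  for (z in labels) {
    df_check(length(survival[[z]]) == nf - 1,
             "survival[['%s']] must have %d per-interval probabilities", z, nf - 1)
    df_check(all(survival[[z]] >= 0 & survival[[z]] <= 1),
             "survival probabilities must lie in [0, 1]")
  }
  ny <- nrow(vessel_mask); nx <- ncol(vessel_mask)
  min_sep <- 2 * cell_radius_px + 4 * blur_sigma_px + 3

  out <- withr::with_seed(seed, {
    placed <- list()
    for (z in zones) {
      idx <- which(vessel_mask != 0)
      rr <- ((idx - 1) %% ny) + 1; cc <- ((idx - 1) %/% ny) + 1
      xs <- (cc - 0.5) * pixel_size_um; ys <- (rr - 0.5) * pixel_size_um
      inz <- roi_contains(z, xs, ys) &
        rr > cell_radius_px + 3 & rr < ny - cell_radius_px - 3 &
        cc > cell_radius_px + 3 & cc < nx - cell_radius_px - 3
      placed[[z$label]] <- place_cells(idx[inz], attach_counts[[z$label]],
                                       ny, min_sep, paste("zone", z$label))
    }
    alive <- lapply(placed, function(p) rep(TRUE, nrow(p)))
    frames <- list(); counts <- matrix(0L, length(zones), nf,
                                       dimnames = list(labels, NULL))
    positions <- list()
    for (k in seq_len(nf)) {
      if (k > 1) {
        for (z in labels) {
          s <- survival[[z]][k - 1]
          alive[[z]] <- alive[[z]] & (stats::runif(length(alive[[z]])) < s)
        }
      }
      centers <- do.call(rbind, lapply(labels, function(z)
        placed[[z]][alive[[z]], , drop = FALSE]))
      zlab <- rep(labels, vapply(labels, function(z) sum(alive[[z]]), integer(1)))
      counts[, k] <- vapply(labels, function(z) sum(alive[[z]]), integer(1))
      frames[[k]] <- render_cell_frame(c(ny, nx), centers, cell_radius_px,
                                       blur_sigma_px, noise_sd = noise_sd)
      positions[[k]] <- data.frame(
        row = centers[, 1], col = centers[, 2], zone = zlab,
        x_um = (centers[, 2] - 0.5) * pixel_size_um,
        y_um = (centers[, 1] - 0.5) * pixel_size_um)
    }
    list(frames = frames, counts = counts, positions = positions)
  })
  stack <- image_stack(out$frames, frame_times_s, pixel_size_um,
                       channel = "tcell")
  truth <- ground_truth("tcell_perfusion", seed,
                        details = list(counts = out$counts,
                                       positions = out$positions,
                                       attach_counts = attach_counts,
                                       survival = survival,
                                       noise_sd = noise_sd))
  list(stack = stack, vessel_mask = vessel_mask, truth = truth)
}

#' Cumulative whole-device retention scenarios for the two T-cell types
#'
#' Per-interval survival probabilities reproducing the reported
#' whole-device retention of circulating cells: naive cells 55% attached at
#' 5 min and 20% at 10 min of flow (so interval survivals 0.55 then
#' 0.20/0.55); Th1 cells 60% then 45%.
#'
#' @param type `"naive"` or `"th1"`.
#' @return numeric vector of two per-interval survival probabilities.
#' @export
tcell_survival_scenario <- function(type = c("naive", "th1")) {
  type <- match.arg(type)
  cum <- switch(type, naive = c(0.55, 0.20), th1 = c(0.60, 0.45))
  c(cum[1], cum[2] / cum[1])
}

#' Synthetic endpoint infiltration image
#'
#' Samples per-cell migration distances from a distance model (half-normal
#' with a given mean by default — only the mean and maximum of the real
#' distance distribution are known, so the shape is a declared assumption),
#' then places each cell at a gel pixel whose distance-transform value
#' matches the sampled distance to within half a pixel. Placed distances
#' are recorded exactly in the truth.
#'
#' @param vessel_mask logical matrix of vessel pixels.
#' @param pixel_size_um µm per pixel.
#' @param n_cells number of infiltrated cells to place.
#' @param distance_model `list(type = "half_normal", mean_um = ...)` or
#'   `list(type = "custom", distances_um = ...)`. Helpers:
#'   [infiltration_model()].
#' @param cell_radius_px,blur_sigma_px,noise_sd rendering options.
#' @param max_resample resampling cap when a sampled distance is not
#'   representable inside the image (default 50 per cell).
#' @param seed integer seed.
#' @return list with `image` (intensity matrix), `vessel_mask` and `truth`
#'   (`details$distances_um`: the sampled/placed distances;
#'   `details$achieved_um`: the distance-transform value at each placed
#'   pixel).
#' @export
gen_infiltration_endpoint <- function(vessel_mask, pixel_size_um, n_cells,
                                      distance_model = infiltration_model("with_epidermis"),
                                      cell_radius_px = 3, blur_sigma_px = 1,
                                      noise_sd = 0, max_resample = 50,
                                      seed = 1) {
  df_check(n_cells >= 0, "n_cells must be non-negative")
  df_check(any(vessel_mask != 0), "vessel mask is empty")
  ny <- nrow(vessel_mask); nx <- ncol(vessel_mask)
  dist_px <- vessel_distance_px(vessel_mask)
  dist_um <- pmax(dist_px - 1, 0) * pixel_size_um   # vessel-boundary convention
  interior <- row(dist_px) > cell_radius_px + 3 & row(dist_px) < ny - cell_radius_px - 3 &
    col(dist_px) > cell_radius_px + 3 & col(dist_px) < nx - cell_radius_px - 3
  min_sep <- 2 * cell_radius_px + 4 * blur_sigma_px + 3

  out <- withr::with_seed(seed, {
    sample_distance <- function() {
      if (distance_model$type == "half_normal") {
        abs(stats::rnorm(1, 0, distance_model$mean_um * sqrt(pi / 2)))
      } else if (distance_model$type == "custom") {
        NA_real_  # custom distances are consumed in order, not sampled
      } else df_validation_error("unknown distance model '%s'", distance_model$type)
    }
    custom <- identical(distance_model$type, "custom")
    if (custom)
      df_check(length(distance_model$distances_um) == n_cells,
               "custom model must supply exactly n_cells distances")
    centers <- matrix(numeric(0), 0, 2); placed_d <- numeric(0); achieved <- numeric(0)
    for (i in seq_len(n_cells)) {
      ok <- FALSE
      for (try in seq_len(max_resample)) {
        d <- if (custom) distance_model$distances_um[i] else sample_distance()
        cand <- which(abs(dist_um - d) <= 0.5 * pixel_size_um & dist_px > 0 &
                        interior)
        if (length(cand) == 0) { if (custom) break else next }
        cand <- sample(cand)
        for (p in cand) {
          r <- ((p - 1) %% ny) + 1; cl <- ((p - 1) %/% ny) + 1
          if (nrow(centers) == 0 ||
              min((centers[, 1] - r)^2 + (centers[, 2] - cl)^2) >= min_sep^2) {
            centers <- rbind(centers, c(r, cl))
            placed_d <- c(placed_d, d); achieved <- c(achieved, dist_um[p])
            ok <- TRUE; break
          }
        }
        if (ok) break
      }
      df_check(ok, paste0("could not place cell %d: sampled distance exceeds ",
                          "the image extent (after %d resamples)"), i, max_resample)
    }
    img <- render_cell_frame(c(ny, nx), centers, cell_radius_px, blur_sigma_px,
                             noise_sd = noise_sd)
    list(img = img, centers = centers, placed_d = placed_d, achieved = achieved)
  })
  truth <- ground_truth("infiltration_endpoint", seed,
                        details = list(distances_um = out$placed_d,
                                       achieved_um = out$achieved,
                                       centers_px = out$centers,
                                       model = distance_model,
                                       n_cells = n_cells))
  list(image = out$img, vessel_mask = vessel_mask, truth = truth)
}

#' Infiltration distance models
#'
#' Half-normal distance models parameterised by the mean migration distance
#' of transmigrated Th1 cells: 233 µm with the epidermis present, 68 µm
#' without (epidermal chemokine signals drive migration toward the
#' interfollicular epidermis).
#'
#' @param which `"with_epidermis"`, `"without_epidermis"`, or `"custom"`.
#' @param distances_um explicit distances for `"custom"`.
#' @return a distance-model list for [gen_infiltration_endpoint()].
#' @export
infiltration_model <- function(which = c("with_epidermis", "without_epidermis",
                                         "custom"),
                               distances_um = NULL) {
  which <- match.arg(which)
  switch(which,
         with_epidermis = list(type = "half_normal", mean_um = 233,
                               epidermis = TRUE),
         without_epidermis = list(type = "half_normal", mean_um = 68,
                                  epidermis = FALSE),
         custom = {
           df_check(!is.null(distances_um), "custom model needs distances_um")
           list(type = "custom", distances_um = distances_um)
         })
}

#' Simple straight-channel vessel mask
#'
#' A horizontal vessel band spanning the image width: the minimal geometry
#' for infiltration-distance tests, where the distance transform is exact.
#'
#' @param ny,nx image size (px).
#' @param center_row,half_width_px band position and half-width (px).
#' @return logical matrix.
#' @export
straight_vessel_mask <- function(ny, nx, center_row = round(ny / 8),
                                 half_width_px = 5) {
  m <- matrix(FALSE, ny, nx)
  rows <- max(1, center_row - half_width_px):min(ny, center_row + half_width_px)
  m[rows, ] <- TRUE
  m
}
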