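#' Closed-form diffusion profile: constant-concentration surface
#'
#' Solution of Fick's second law in a semi-infinite medium whose surface is
#' held at concentration `C0` from t = 0 (the acellular-channel limit, where
#' no barrier separates the perfused lumen from the gel):
#' \deqn{C(x,t) = C_0\,\mathrm{erfc}\!\left(\frac{x}{2\sqrt{Dt}}\right)}
#'
#' @param x_um distance from the surface (µm), >= 0.
#' @param t_s time since the source was switched on (s), > 0.
#' @param D_um2_s diffusivity (µm²/s), > 0.
#' @param C0 surface concentration (arbitrary units).
#' @return concentration, vectorised over `x_um` and `t_s`.
#' @export
erfc_profile <- function(x_um, t_s, D_um2_s, C0 = 1) {
  df_check(all(t_s > 0), "erfc_profile requires t > 0")
  df_check(D_um2_s > 0, "diffusivity must be positive")
  df_check(all(x_um >= 0), "distances must be non-negative")
  C0 * pracma::erfc(x_um / (2 * sqrt(D_um2_s * t_s)))
}

#' Closed-form diffusion profile behind a semi-permeable barrier
#'
#' Surface-conductance (Robin) solution for a semi-infinite medium whose
#' surface admits flux \eqn{J = P(C_0 - C_{wall})}: with \eqn{h = P/D},
#' \deqn{C = C_0\left[\mathrm{erfc}(u) - e^{hx + h^2 D t}\,
#'   \mathrm{erfc}(u + h\sqrt{Dt})\right], \quad u = \frac{x}{2\sqrt{Dt}}.}
#' The exponential-times-erfc product overflows in the diffusion-limited
#' regime, so it is evaluated as
#' \eqn{e^{-u^2}\,\mathrm{erfcx}(u + h\sqrt{Dt})} using the scaled
#' complementary error function, which is finite for all valid inputs.
#' As \eqn{P \to \infty} this reduces to [erfc_profile()]; at P = 0 it is
#' identically zero.
#'
#' @inheritParams erfc_profile
#' @param P_um_s barrier permeability (µm/s), >= 0.
#' @return concentration, vectorised over `x_um` and `t_s`.
#' @export
robin_profile <- function(x_um, t_s, D_um2_s, P_um_s, C0 = 1) {
  df_check(all(t_s > 0), "robin_profile requires t > 0")
  df_check(all(D_um2_s > 0), "diffusivity must be positive")
  df_check(all(P_um_s >= 0), "permeability must be non-negative")
  df_check(all(x_um >= 0), "distances must be non-negative")
  h <- P_um_s / D_um2_s
  sdt <- sqrt(D_um2_s * t_s)
  u <- x_um / (2 * sdt)
  val <- C0 * (pracma::erfc(u) - exp(-u^2) * erfcx_safe(u + h * sdt))
  pmin(pmax(val, 0), C0)   # clamp roundoff at the boundaries of [0, C0]
}

# scaled complementary error function, finite for any non-negative argument
# (pracma's implementation overflows past z ~ 27; the asymptotic expansion
# 1/(z sqrt(pi)) * (1 - 1/(2 z^2) + 3/(4 z^4)) is accurate to < 1e-7 there)
erfcx_safe <- function(z) {
  out <- numeric(length(z))
  big <- z >= 20
  if (any(!big)) out[!big] <- pracma::erfcx(z[!big])
  if (any(big)) {
    zb <- z[big]
    out[big] <- (1 - 1 / (2 * zb^2) + 3 / (4 * zb^4)) / (zb * sqrt(pi))
  }
  out
}

#' Forward-simulate barrier-limited dextran transport into the gel
#'
#' Solves the 2D diffusion equation \eqn{\partial C/\partial t = D \nabla^2 C}
#' over the gel cells of a [make_transport_domain()] grid. The perfused lumen
#' is a fixed-concentration reservoir at `C_lumen`; the endothelial barrier
#' is a Robin membrane condition applied as a flux source on the first gel
#' cells adjacent to the lumen, \eqn{dC/dt \mathrel{+}= P(C_{lumen}-C)/\Delta x};
#' the outer grid boundary is zero-flux.
#'
#' Time stepping is backward Euler on the 5-point Laplacian (sparse Cholesky
#' factorisation reused across steps), unconditionally stable so the step can
#' be chosen for accuracy alone; an explicit FTCS scheme (`method =
#' "explicit"`) with the usual stability bound is provided for
#' cross-checking. Fluorescence intensity is assumed proportional to
#' concentration, so fields are in the same arbitrary units as `C_lumen`.
#'
#' @param domain a `transport_domain`.
#' @param D_um2_s gel diffusivity (µm²/s).
#' @param P_um_s barrier permeability (µm/s); use `Inf` (or a large value)
#'   for acellular channels.
#' @param C_lumen lumen concentration (a.u.), default 1.
#' @param output_times_s sorted times (s) at which fields/traces are
#'   recorded; 0 returns the initial (zero) field.
#' @param dt_s target time step (s); each output interval is subdivided into
#'   equal steps no longer than this. Default 5.
#' @param method `"implicit"` (default) or `"explicit"`.
#' @return a `concentration_series`: `times_s`, `fields` (list of ny x nx
#'   matrices with lumen cells at `C_lumen`), `roi_traces` (data.frame
#'   `time_s`, one column per registered ROI), and `mass_balance` with the
#'   final gel mass and time-integrated membrane influx.
#' @export
simulate_transport <- function(domain, D_um2_s, P_um_s, C_lumen = 1,
                               output_times_s = seq(0, 3600, by = 300),
                               dt_s = 5, method = c("implicit", "explicit")) {
  method <- match.arg(method)
  df_check(inherits(domain, "transport_domain"), "domain must be a transport_domain")
  df_check(D_um2_s > 0, "diffusivity must be positive")
  df_check(P_um_s >= 0, "permeability must be non-negative")
  df_check(dt_s > 0, "time step must be positive")
  output_times_s <- sort(unique(output_times_s))
  df_check(all(output_times_s >= 0), "output times must be non-negative")
  df_check(length(output_times_s) >= 1, "need at least one output time")

  dx <- domain$dx_um
  gel <- !domain$lumen
  ng <- sum(gel)
  gid <- matrix(0L, domain$ny, domain$nx)
  gid[gel] <- seq_len(ng)

  # membrane conductance in series with half-cell diffusion: the flux from
  # the lumen surface to the first gel cell center passes the barrier (P)
  # and then dx/2 of gel (2D/dx), so g = 1/(1/P + dx/(2D)); this places the
  # Robin surface exactly at the lumen/gel face and handles P -> Inf as a
  # clamped surface
  Peff <- if (is.finite(P_um_s) && P_um_s > 0) {
    1 / (1 / P_um_s + dx / (2 * D_um2_s))
  } else if (P_um_s == 0) 0 else 2 * D_um2_s / dx

  op <- gel_operator(gid, gel, domain$membrane, dx, D_um2_s, Peff)
  mem_idx <- op$mem_idx
  src <- numeric(ng)
  src[mem_idx] <- Peff / dx * C_lumen

  if (method == "explicit") {
    dt_max <- 0.25 * dx^2 / (4 * D_um2_s)
    df_check(dt_s <= dt_max || length(output_times_s) == 1,
             paste0("explicit scheme unstable: dt = %g s exceeds the ",
                    "stability bound 0.25*dx^2/(4D) = %g s"), dt_s, dt_max)
  }

  C <- numeric(ng)
  fields <- vector("list", length(output_times_s))
  influx <- 0
  t_now <- 0
  chol_cache <- list()
  for (k in seq_along(output_times_s)) {
    t_target <- output_times_s[k]
    if (t_target > t_now) {
      nstep <- ceiling((t_target - t_now) / dt_s - 1e-9)
      dt <- (t_target - t_now) / nstep
      if (method == "implicit") {
        key <- sprintf("%.12g", dt)
        if (is.null(chol_cache[[key]])) {
          M <- Matrix::Diagonal(ng) + dt * op$A
          chol_cache[[key]] <- Matrix::Cholesky(M, LDL = FALSE)
        }
        ch <- chol_cache[[key]]
        for (s in seq_len(nstep)) {
          C <- as.numeric(Matrix::solve(ch, C + dt * src, system = "A"))
          influx <- influx + Peff * dx * dt * sum(C_lumen - C[mem_idx])
        }
      } else {
        for (s in seq_len(nstep)) {
          C <- C + dt * (src - as.numeric(op$A %*% C))
          influx <- influx + Peff * dx * dt * sum(C_lumen - C[mem_idx])
        }
      }
      t_now <- t_target
    }
    f <- matrix(C_lumen, domain$ny, domain$nx)
    f[gel] <- C
    fields[[k]] <- f
  }

  series <- structure(list(times_s = output_times_s, fields = fields,
                           domain = domain, C_lumen = C_lumen,
                           params = list(D_um2_s = D_um2_s, P_um_s = P_um_s,
                                         dt_s = dt_s, method = method),
                           mass_balance = list(
                             gel_mass = sum(C) * dx^2,
                             influx_integral = influx)),
                      class = "concentration_series")
  series$roi_traces <- roi_trace_table(series)
  series
}

# sparse operator A such that dC/dt = -A C + src over gel cells:
# A = -D * Laplacian (zero-flux at gel boundary) + (P/dx) on membrane cells
gel_operator <- function(gid, gel, membrane, dx, D, P) {
  ny <- nrow(gid); nx <- ncol(gid)
  ii <- integer(0); jj <- integer(0)
  pair <- function(ma, mb) {
    sel <- ma > 0 & mb > 0
    ii <<- c(ii, ma[sel]); jj <<- c(jj, mb[sel])
  }
  pair(gid[-ny, , drop = FALSE], gid[-1, , drop = FALSE])   # vertical faces
  pair(gid[, -nx, drop = FALSE], gid[, -1, drop = FALSE])   # horizontal faces
  w <- D / dx^2
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                            x = rep(-w, 2 * length(ii)),
                            dims = c(max(gid), max(gid)))
  deg <- -Matrix::rowSums(A) / w
  mem_idx <- gid[membrane & gel]
  diag_x <- deg * w
  diag_x[mem_idx] <- diag_x[mem_idx] + P / dx
  A <- A + Matrix::Diagonal(x = diag_x)
  list(A = A, mem_idx = sort(mem_idx))
}

roi_trace_table <- function(series) {
  out <- data.frame(time_s = series$times_s)
  for (r in series$domain$rois)
    out[[r$label]] <- sample_roi(series, r)
  out
}

#' Mean concentration inside an ROI over time
#'
#' Averages grid cells whose centers fall inside the polygon, per output
#' time (the digital analogue of measuring mean fluorescence intensity in a
#' drawn region).
#'
#' @param series a `concentration_series`.
#' @param roi an [new_roi()] polygon.
#' @return numeric vector, one mean per output time.
#' @export
sample_roi <- function(series, roi) {
  df_check(inherits(series, "concentration_series"),
           "series must be a concentration_series")
  df_check(inherits(roi, "roi"), "roi must be an roi object")
  dom <- series$domain
  cc <- domain_coords(dom)
  X <- matrix(cc$x_um, dom$ny, dom$nx, byrow = TRUE)
  Y <- matrix(cc$y_um, dom$ny, dom$nx)
  inside <- matrix(roi_contains(roi, as.vector(X), as.vector(Y)), dom$ny, dom$nx)
  df_check(any(inside), "roi '%s' covers no grid cells", roi$label)
  vapply(series$fields, function(f) mean(f[inside]), numeric(1))
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series> %d frames over %.0f s, D = %.3g um^2/s, P = %.3g um/s\n",
              length(x$times_s), max(x$times_s), x$params$D_um2_s, x$params$P_um_s))
  if (!is.null(x$roi_traces) && ncol(x$roi_traces) > 1)
    cat("  final ROI means:",
        paste(sprintf("%s = %.4g", names(x$roi_traces)[-1],
                      unlist(x$roi_traces[nrow(x$roi_traces), -1])),
              collapse = ", "), "\n")
  invisible(x)
}
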