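#' Unit conversions used throughout the package
#'
#' All geometric quantities are carried in micrometres, time in seconds,
#' pressure in pascal and dynamic viscosity in Pa.s internally. User-facing
#' arguments use the units conventional in the organ-on-chip literature
#' (channel dimensions in µm, perfusion rates in mL/min, viscosity in mPa.s,
#' wall shear stress in dyn/cm²); every conversion between the two lives
#' here so no factor is repeated elsewhere.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
ml_min_to_um3_s <- function(x) x * 1e12 / 60

#' @rdname units
#' @export
um3_s_to_ml_min <- function(x) x * 60 / 1e12

#' @rdname units
#' @export
mpas_to_pas <- function(x) x * 1e-3

#' @rdname units
#' @export
pa_to_dyn_cm2 <- function(x) x * 10

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

# internal: stop with a classed validation error so callers (and the CLI)
# can distinguish bad input from runtime failure
df_validation_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dermaflux_validation_error", "error")))
}

df_check <- function(cond, msg, ...) {
  if (!isTRUE(cond)) df_validation_error(msg, ...)
  invisible(TRUE)
}
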