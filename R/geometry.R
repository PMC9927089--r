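#' Rotating-disc coupon geometry
#'
#' The detachment assay spins a biofilm-coated coupon immersed in water while
#' recording resistive torque. Defaults describe a 40 mm diameter coupon with
#' a 3.5 cm gap to the container floor.
#'
#' @param radius coupon radius in metres (default 0.020, i.e. 40 mm diameter).
#' @param gap distance between coupon face and container floor in metres.
#' @return an object of class `disc_geometry`.
#' @export
disc_geometry <- function(radius = 0.020, gap = 0.035) {
  stopifnot_scalar(radius, "radius")
  stopifnot_scalar(gap, "gap")
  structure(list(radius = radius, gap = gap), class = "disc_geometry")
}

#' Immersion-fluid properties
#'
#' Density and kinematic viscosity of the fluid the disc spins in. Defaults
#' are reverse-osmosis water at room temperature.
#'
#' @param density kg/m^3.
#' @param kinematic_viscosity m^2/s.
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 998, kinematic_viscosity = 1.0e-6) {
  stopifnot_scalar(density, "density")
  stopifnot_scalar(kinematic_viscosity, "kinematic_viscosity")
  structure(list(density = density, kinematic_viscosity = kinematic_viscosity),
            class = "fluid_properties")
}

#' Flat indentation-probe geometry
#'
#' An 8 mm flat cylindrical probe compresses the biofilm at constant rate;
#' the biofilm is treated as incompressible (Poisson ratio 0.5).
#'
#' @param radius probe radius in metres (default 0.004).
#' @param poisson assumed Poisson's ratio of the biofilm, in `[0, 1)`.
#' @return an object of class `probe_geometry`.
#' @export
probe_geometry <- function(radius = 0.004, poisson = 0.5) {
  stopifnot_scalar(radius, "radius")
  if (!is.numeric(poisson) || length(poisson) != 1L || !is.finite(poisson) ||
      poisson < 0 || poisson >= 1)
    stop("'poisson' must be in [0, 1)", call. = FALSE)
  structure(list(radius = radius, poisson = poisson), class = "probe_geometry")
}

#' @export
print.disc_geometry <- function(x, ...) {
  cat(sprintf("Disc geometry: radius %.4g m (diameter %.3g mm), gap %.4g m\n",
              x$radius, 2000 * x$radius, x$gap))
  invisible(x)
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: density %.4g kg/m^3, kinematic viscosity %.3g m^2/s\n",
              x$density, x$kinematic_viscosity))
  invisible(x)
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("Flat probe: radius %.4g m, Poisson ratio %.3g\n",
              x$radius, x$poisson))
  invisible(x)
}
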