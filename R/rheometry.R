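# Rotating-disc detachment analysis.
#
# A biofilm-coated coupon spun through an angular-velocity ramp experiences
# drag beyond that of a smooth disc; the excess is the biofilm momentum
# coefficient. Step reductions in torque mark detachment of biofilm
# aggregates; the wall shear stress at the first such event is the critical
# detachment shear stress.

#' Smooth-disc moment coefficient
#'
#' Theoretical one-sided moment coefficient of a smooth rotating disc, the
#' clean-coupon baseline that biofilm drag is measured against. Uses the von
#' Karman similarity results: laminar `1.935 Re^(-1/2)` up to
#' `Re = 3e5` (boundary inclusive) and turbulent `0.0365 Re^(-1/5)` above,
#' with rotational Reynolds number `Re = omega R^2 / nu`.
#'
#' @param omega angular velocity, rad/s, > 0 (vectorised).
#' @param geometry a [disc_geometry()].
#' @param fluid a [fluid_properties()].
#' @return dimensionless moment coefficient, same length as `omega`.
#' @examples
#' smooth_disc_moment_coefficient(25, disc_geometry(), fluid_properties())
#' @export
smooth_disc_moment_coefficient <- function(omega, geometry = disc_geometry(),
                                           fluid = fluid_properties()) {
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("angular velocity must be > 0", call. = FALSE)
  re <- omega * geometry$radius^2 / fluid$kinematic_viscosity
  ifelse(re <= 3e5, 1.935 * re^(-1 / 2), 0.0365 * re^(-1 / 5))
}

#' Per-sample moment coefficient of a measured curve
#'
#' `Cm(omega) = T / (0.5 rho omega^2 R^5)`: measured torque nondimensionalised
#' by the rotational dynamic pressure scale of the disc.
#'
#' @param curve a [torque_velocity_curve()].
#' @inheritParams smooth_disc_moment_coefficient
#' @return dimensionless series, one value per sample.
#' @export
momentum_coefficient_curve <- function(curve, geometry = disc_geometry(),
                                       fluid = fluid_properties()) {
  if (any(curve$omega <= 0))
    stop("angular velocity must be > 0", call. = FALSE)
  curve$torque / (0.5 * fluid$density * curve$omega^2 * geometry$radius^5)
}

#' Biofilm momentum coefficient
#'
#' Mean excess of the measured moment coefficient over the smooth-disc
#' baseline across a velocity window, by default the top decade of the ramp
#' (30-300 rad/s) where biofilm drag dominates measurement noise. Higher
#' values indicate a more adherent, higher-drag biofilm.
#'
#' @param curve a [torque_velocity_curve()].
#' @inheritParams smooth_disc_moment_coefficient
#' @param window `c(min, max)` angular-velocity window, rad/s.
#' @return dimensionless scalar.
#' @export
biofilm_momentum_coefficient <- function(curve, geometry = disc_geometry(),
                                         fluid = fluid_properties(),
                                         window = c(30, 300)) {
  sel <- curve$omega >= window[1] & curve$omega <= window[2]
  if (!any(sel))
    stop("no samples inside the window [", window[1], ", ", window[2],
         "] rad/s", call. = FALSE)
  cm <- momentum_coefficient_curve(curve, geometry, fluid)[sel]
  cms <- smooth_disc_moment_coefficient(curve$omega[sel], geometry, fluid)
  mean(cm - cms)
}

#' Linearised slope transform of a torque curve
#'
#' Baseline-corrects the torque record by subtracting its full-run
#' least-squares line, then takes the first difference of the corrected
#' torque over the first difference of angular velocity. The transform
#' approximates the first derivative and turns step drops in torque
#' (detachment events) into isolated strongly negative slope values.
#'
#' @param curve a [torque_velocity_curve()] with at least 3 samples.
#' @return object of class `slope_series`: list with `omega_mid` (interval
#'   midpoints, rad/s) and `slope` (N.m per rad/s).
#' @export
linearized_slope_transform <- function(curve) {
  if (length(curve$omega) < 3L)
    stop("need at least 3 samples", call. = FALSE)
  if (diff(range(curve$omega)) == 0)
    stop("degenerate curve: all angular velocities equal", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, curve$omega), curve$torque)
  resid <- fit$residuals
  structure(list(
    omega_mid = (curve$omega[-1] + curve$omega[-length(curve$omega)]) / 2,
    slope = diff(resid) / diff(curve$omega)
  ), class = "slope_series")
}

#' @export
print.slope_series <- function(x, ...) {
  cat(sprintf("Slope series: %d intervals, slope range [%.3g, %.3g] N.m/(rad/s)\n",
              length(x$slope), min(x$slope), max(x$slope)))
  invisible(x)
}

#' Detect detachment events in a slope series
#'
#' Flags slope values below `median - threshold_sd * robust SD`, where the
#' robust SD is 1.4826 times the median absolute deviation, then merges runs
#' of consecutive flagged intervals into single events placed at the most
#' negative slope. Robust statistics keep the threshold stable under
#' heavy-tailed torque noise.
#'
#' @param slopes a `slope_series` from [linearized_slope_transform()].
#' @param threshold_sd detection threshold in robust SD units (> 0).
#' @inheritParams smooth_disc_moment_coefficient
#' @return data frame with one row per event: `omega` (rad/s), `slope`
#'   (N.m/(rad/s), negative) and `tau` (wall shear stress at the event, Pa).
#'   Zero rows when no event is found.
#' @export
detect_detachment_events <- function(slopes, threshold_sd = 3,
                                     geometry = disc_geometry(),
                                     fluid = fluid_properties()) {
  if (threshold_sd <= 0) stop("'threshold_sd' must be > 0", call. = FALSE)
  s <- slopes$slope
  cutoff <- stats::median(s) - threshold_sd * stats::mad(s)
  flagged <- s < cutoff
  if (!any(flagged)) {
    return(data.frame(omega = numeric(0), slope = numeric(0),
                      tau = numeric(0)))
  }
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  idx <- vapply(keep, function(k) {
    span <- starts[k]:ends[k]
    span[which.min(s[span])]
  }, integer(1))
  data.frame(omega = slopes$omega_mid[idx],
             slope = s[idx],
             tau = wall_shear_stress(slopes$omega_mid[idx], geometry, fluid))
}

#' Laminar rotating-disc wall shear stress
#'
#' Magnitude of the wall shear stress at the coupon edge under von Karman
#' laminar similarity, `tau = 0.800 rho R sqrt(nu omega^3)`; the coefficient
#' combines the radial and tangential components
#' (`sqrt(0.616^2 + 0.510^2) ~= 0.800`). The full ramp stays laminar
#' (`Re <= 1.2e5` at 300 rad/s for a 20 mm coupon in water).
#'
#' @param omega angular velocity, rad/s, >= 0 (vectorised).
#' @inheritParams smooth_disc_moment_coefficient
#' @return wall shear stress, Pa.
#' @export
wall_shear_stress <- function(omega, geometry = disc_geometry(),
                              fluid = fluid_properties()) {
  if (any(!is.finite(omega)) || any(omega < 0))
    stop("angular velocity must be >= 0", call. = FALSE)
  0.800 * fluid$density * geometry$radius *
    sqrt(fluid$kinematic_viscosity * omega^3)
}

#' Critical detachment shear stress
#'
#' Wall shear stress at the lowest-velocity detected detachment event — the
#' stress at which the biofilm first begins to shed. `NA` (reported missing,
#' never zero) when no event was detected.
#'
#' @param events event table from [detect_detachment_events()].
#' @inheritParams smooth_disc_moment_coefficient
#' @return Pa, or `NA_real_` when `events` is empty.
#' @export
critical_detachment_shear_stress <- function(events,
                                             geometry = disc_geometry(),
                                             fluid = fluid_properties()) {
  if (nrow(events) == 0L) return(NA_real_)
  wall_shear_stress(min(events$omega), geometry, fluid)
}

#' Area under the torque-velocity curve
#'
#' Trapezoidal integral of torque over the recorded angular-velocity range —
#' a proxy for the energy needed to spin the coupon across the ramp.
#'
#' @param curve a [torque_velocity_curve()] with at least 2 samples.
#' @return N.m rad/s.
#' @export
torque_auc <- function(curve) {
  if (length(curve$omega) < 2L) stop("need at least 2 samples", call. = FALSE)
  pracma::trapz(curve$omega, curve$torque)
}

#' Fit the full detachment analysis to one torque curve
#'
#' Runs the whole rotating-disc analysis: biofilm momentum coefficient,
#' torque-curve area, linearised slope transform, detachment-event detection
#' and the critical detachment shear stress.
#'
#' @param curve a [torque_velocity_curve()].
#' @inheritParams smooth_disc_moment_coefficient
#' @param window velocity window for the momentum coefficient, rad/s.
#' @param threshold_sd event-detection threshold in robust SD units.
#' @return object of class `rheology_fit` with components `cf`, `auc`,
#'   `tau_star`, `events`, `slopes`, `curve`, `geometry`, `fluid`.
#' @seealso [coef.rheology_fit()], [plot.rheology_fit()]
#' @examples
#' g <- generate_torque_curve(cf0 = 0.05, seed = 1)
#' fit <- rheology_fit(g$curve)
#' coef(fit)
#' @export
rheology_fit <- function(curve, geometry = disc_geometry(),
                         fluid = fluid_properties(), window = c(30, 300),
                         threshold_sd = 3) {
  slopes <- linearized_slope_transform(curve)
  events <- detect_detachment_events(slopes, threshold_sd, geometry, fluid)
  structure(list(
    cf = biofilm_momentum_coefficient(curve, geometry, fluid, window),
    auc = torque_auc(curve),
    tau_star = critical_detachment_shear_stress(events, geometry, fluid),
    events = events,
    slopes = slopes,
    curve = curve,
    geometry = geometry,
    fluid = fluid,
    window = window,
    threshold_sd = threshold_sd
  ), class = "rheology_fit")
}

#' @export
print.rheology_fit <- function(x, ...) {
  cat("Rotating-disc detachment analysis\n")
  if (!is.na(x$curve$meta$treatment))
    cat("  treatment:", x$curve$meta$treatment, "\n")
  cat(sprintf("  biofilm momentum coefficient: %.4g\n", x$cf))
  cat(sprintf("  torque AUC: %.4g N.m rad/s\n", x$auc))
  if (is.na(x$tau_star)) {
    cat("  no detachment events detected\n")
  } else {
    cat(sprintf("  %d detachment event(s); critical shear stress %.4g Pa (first event at %.3g rad/s)\n",
                nrow(x$events), x$tau_star, min(x$events$omega)))
  }
  invisible(x)
}

#' @export
coef.rheology_fit <- function(object, ...) {
  c(cf = object$cf, auc = object$auc, tau_star = object$tau_star,
    n_events = nrow(object$events))
}

#' @export
summary.rheology_fit <- function(object, ...) {
  print(object)
  if (nrow(object$events)) {
    cat("  events:\n")
    print(object$events, row.names = FALSE)
  }
  invisible(object)
}

#' Plot a detachment analysis
#'
#' Two panels: the raw torque-velocity curve (log-x) and the linearised slope
#' series with detected events marked.
#'
#' @param x a `rheology_fit`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rheology_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$curve$omega, x$curve$torque, type = "l", log = "x",
                 xlab = "angular velocity (rad/s)", ylab = "torque (N.m)", ...)
  graphics::plot(x$slopes$omega_mid, x$slopes$slope, type = "h", log = "x",
                 xlab = "angular velocity (rad/s)",
                 ylab = "corrected slope (N.m/(rad/s))")
  if (nrow(x$events))
    graphics::points(x$events$omega, x$events$slope, col = "red", pch = 19)
  invisible(x)
}
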