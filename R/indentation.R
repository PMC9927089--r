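# Uniaxial flat-probe indentation analysis.
#
# The probe approaches at constant rate; force stays at instrument baseline
# until biofilm contact, rises linearly while the biofilm compresses, then
# rises much more steeply once the probe reaches the substratum. Contact and
# substratum displacements bracket the biofilm thickness, and the
# force-displacement slope over the first 20% of strain gives the Young's
# modulus via E = slope (1 - v^2) / (2 r) for a flat circular punch.

#' Detect the biofilm contact point
#'
#' The contact displacement is the first sample whose force exceeds the
#' pre-contact baseline by `k_sd` baseline SDs and stays above that level for
#' `m_run` consecutive samples (a sustained rise, not a noise spike). The
#' baseline is estimated from the first `baseline_frac` of samples.
#'
#' @param curve a [force_displacement_curve()].
#' @param k_sd threshold in baseline SD units (> 0).
#' @param m_run run length required above threshold (>= 3).
#' @param baseline_frac fraction of leading samples treated as pre-contact.
#' @return contact displacement `delta_c` in metres, with the sample index as
#'   attribute `"index"`.
#' @export
detect_contact_point <- function(curve, k_sd = 5, m_run = 10,
                                 baseline_frac = 0.10) {
  if (k_sd <= 0) stop("'k_sd' must be > 0", call. = FALSE)
  if (m_run < 3) stop("'m_run' must be >= 3", call. = FALSE)
  f <- curve$force
  n <- length(f)
  nb <- max(2L, floor(baseline_frac * n))
  base <- f[seq_len(nb)]
  thr <- mean(base) + k_sd * stats::sd(base)

  above <- f > thr
  # first index starting a run of >= m_run consecutive above-threshold samples
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & run$lengths >= m_run)
  if (length(ok) == 0L)
    stop("contact not found: force never rises ", k_sd,
         " SD above baseline for ", m_run, " consecutive samples",
         call. = FALSE)
  idx <- starts[ok[1L]]
  structure(curve$displacement[idx], index = idx)
}

#' Detect the substratum displacement
#'
#' Tracks the local force-displacement slope (windowed least squares) past the
#' contact point and reports the displacement where it first exceeds
#' `stiffening_factor` times the initial post-contact slope — the hard
#' substratum under the soft biofilm. When no such stiffening is seen the
#' termination displacement (last sample) is returned and a warning logged,
#' so every curve remains analysable.
#'
#' @param curve a [force_displacement_curve()].
#' @param delta_c contact displacement from [detect_contact_point()].
#' @param stiffening_factor slope ratio that marks the substratum (> 1).
#' @param slope_window samples per local least-squares slope (odd, >= 5).
#' @return substratum displacement `delta_s` in metres; attribute
#'   `"fallback"` is `TRUE` when the termination point was used.
#' @export
detect_substratum <- function(curve, delta_c, stiffening_factor = 20,
                              slope_window = 11) {
  if (stiffening_factor <= 1)
    stop("'stiffening_factor' must be > 1", call. = FALSE)
  w <- as.integer(slope_window)
  if (w < 5L) stop("'slope_window' must be >= 5", call. = FALSE)
  d <- curve$displacement; f <- curve$force
  i0 <- which(d >= delta_c)[1L]
  n <- length(d)
  if (is.na(i0) || n - i0 + 1L < 2L * w)
    return(structure(d[n], fallback = TRUE))

  local_slope <- function(idx) {
    x <- d[idx]; y <- f[idx]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) return(0)
    sum((x - mean(x)) * (y - mean(y))) / sxx
  }
  k0 <- local_slope(i0:(i0 + w - 1L))
  centers <- seq(i0 + w, n - w + 1L)
  for (i in centers) {
    if (local_slope(i:(i + w - 1L)) > stiffening_factor * k0) {
      return(structure(d[i], fallback = FALSE))
    }
  }
  log_event("substratum stiffening never exceeded factor ", stiffening_factor,
            "; falling back to termination displacement")
  structure(d[n], fallback = TRUE)
}

#' Contact geometry of one indentation
#'
#' @param delta_c contact displacement, m.
#' @param delta_s substratum displacement, m; must exceed `delta_c`.
#' @return object of class `contact_result` with `delta_c`, `delta_s` and
#'   biofilm thickness `h = delta_s - delta_c`.
#' @export
contact_result <- function(delta_c, delta_s) {
  if (delta_s <= delta_c)
    stop("substratum displacement must exceed contact displacement",
         call. = FALSE)
  structure(list(delta_c = as.numeric(delta_c), delta_s = as.numeric(delta_s),
                 h = as.numeric(delta_s) - as.numeric(delta_c)),
            class = "contact_result")
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf("Contact at %.4g um, substratum at %.4g um, thickness %.4g um\n",
              1e6 * x$delta_c, 1e6 * x$delta_s, 1e6 * x$h))
  invisible(x)
}

#' Stress-strain transformation of an indentation curve
#'
#' Engineering strain `(delta - delta_c) / h` against nominal stress
#' `F / (pi r^2)` over the biofilm region. The full flat-probe area is used
#' because the 8 mm probe is far wider than the biofilm is thick, so full
#' contact is assumed.
#'
#' @param curve a [force_displacement_curve()].
#' @param contact a [contact_result()].
#' @param probe a [probe_geometry()].
#' @return object of class `stress_strain_curve`: list with `strain`
#'   (dimensionless, 0 at contact, 1 at substratum) and `stress` (Pa).
#' @export
stress_strain <- function(curve, contact, probe = probe_geometry()) {
  if (contact$h <= 0) stop("non-positive biofilm thickness", call. = FALSE)
  sel <- curve$displacement >= contact$delta_c &
    curve$displacement <= contact$delta_s
  structure(list(
    strain = (curve$displacement[sel] - contact$delta_c) / contact$h,
    stress = curve$force[sel] / (pi * probe$radius^2)
  ), class = "stress_strain_curve")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("Stress-strain curve: %d samples, strain up to %.3g, stress up to %.4g Pa\n",
              length(x$strain), max(x$strain), max(x$stress)))
  invisible(x)
}

#' Force-displacement slope over the low-strain linear region
#'
#' Least-squares slope of force against displacement restricted to strains in
#' `[0, strain_max]` (default the 0-20% window). The fit is on
#' force-displacement, not stress-strain, because the modulus formula
#' consumes a slope in N/m.
#'
#' @param curve a [force_displacement_curve()].
#' @param contact a [contact_result()].
#' @param strain_max upper strain bound of the fit window (> 0).
#' @return list with `slope` (N/m), `r_squared`, and `n` (samples fitted).
#' @export
linear_region_slope <- function(curve, contact, strain_max = 0.20) {
  if (strain_max <= 0) stop("'strain_max' must be > 0", call. = FALSE)
  hi <- contact$delta_c + strain_max * contact$h
  sel <- curve$displacement >= contact$delta_c & curve$displacement <= hi
  if (sum(sel) < 5L)
    stop("fit window too small: ", sum(sel), " sample(s) with strain in [0, ",
         strain_max, "]; need at least 5", call. = FALSE)
  x <- curve$displacement[sel]; y <- curve$force[sel]
  fit <- stats::lm.fit(cbind(1, x), y)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2L]),
       r_squared = if (sst > 0) 1 - ssr / sst else 1,
       n = length(x))
}

#' Young's modulus from the force-displacement slope
#'
#' Flat circular punch on an elastic layer: `E = slope (1 - v^2) / (2 r)`,
#' with the slope in N/m, probe radius `r` in m and Poisson ratio `v`
#' dimensionless, giving `E` in Pa.
#'
#' @param slope force-displacement slope, N/m.
#' @param probe a [probe_geometry()].
#' @return Young's modulus, Pa.
#' @examples
#' youngs_modulus(1, probe_geometry())  # 93.75 Pa
#' @export
youngs_modulus <- function(slope, probe = probe_geometry()) {
  if (any(!is.finite(slope))) stop("'slope' must be finite", call. = FALSE)
  slope * (1 - probe$poisson^2) / (2 * probe$radius)
}

#' Fit the full indentation analysis to one curve
#'
#' Chains contact detection, substratum detection, the low-strain linear fit
#' and the flat-punch modulus formula.
#'
#' @param curve a [force_displacement_curve()].
#' @param probe a [probe_geometry()].
#' @param k_sd,m_run contact-detection parameters, see
#'   [detect_contact_point()].
#' @param stiffening_factor substratum-detection slope ratio, see
#'   [detect_substratum()].
#' @param strain_max upper strain bound of the modulus fit window.
#' @return object of class `indentation_fit` with `contact` (a
#'   [contact_result()]), `slope` (N/m), `r_squared`, `E` (Pa), `curve`,
#'   `probe`.
#' @examples
#' g <- generate_indentation_curve(E = 10e3, seed = 1)
#' fit <- indentation_fit(g$curve)
#' coef(fit)
#' @export
indentation_fit <- function(curve, probe = probe_geometry(), k_sd = 5,
                            m_run = 10, stiffening_factor = 20,
                            strain_max = 0.20) {
  delta_c <- detect_contact_point(curve, k_sd = k_sd, m_run = m_run)
  delta_s <- detect_substratum(curve, delta_c,
                               stiffening_factor = stiffening_factor)
  contact <- contact_result(delta_c, delta_s)
  fit <- linear_region_slope(curve, contact, strain_max = strain_max)
  structure(list(
    contact = contact,
    slope = fit$slope,
    r_squared = fit$r_squared,
    E = youngs_modulus(fit$slope, probe),
    substratum_fallback = isTRUE(attr(delta_s, "fallback")),
    curve = curve,
    probe = probe,
    strain_max = strain_max
  ), class = "indentation_fit")
}

#' @export
print.indentation_fit <- function(x, ...) {
  cat("Uniaxial indentation analysis\n")
  if (!is.na(x$curve$meta$treatment))
    cat("  treatment:", x$curve$meta$treatment, "\n")
  cat(sprintf("  contact %.4g um, thickness %.4g um%s\n",
              1e6 * x$contact$delta_c, 1e6 * x$contact$h,
              if (x$substratum_fallback) " (termination fallback)" else ""))
  cat(sprintf("  slope %.4g N/m over 0-%.0f%% strain (R^2 = %.4f)\n",
              x$slope, 100 * x$strain_max, x$r_squared))
  cat(sprintf("  Young's modulus %.4g Pa (%.4g kPa)\n", x$E, x$E / 1e3))
  invisible(x)
}

#' @export
coef.indentation_fit <- function(object, ...) {
  c(delta_c = object$contact$delta_c, thickness = object$contact$h,
    slope = object$slope, E = object$E)
}

#' @export
summary.indentation_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  curve: %d samples, peak force %.3g N\n",
              length(object$curve$displacement), max(object$curve$force)))
  invisible(object)
}

#' Plot an indentation analysis
#'
#' Force-displacement record with the detected contact and substratum marked
#' and the fitted low-strain line overlaid.
#'
#' @param x an `indentation_fit`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.indentation_fit <- function(x, ...) {
  d <- x$curve$displacement; f <- x$curve$force
  graphics::plot(1e6 * d, f, type = "l", xlab = "displacement (um)",
                 ylab = "force (N)", ...)
  graphics::abline(v = 1e6 * c(x$contact$delta_c, x$contact$delta_s),
                   lty = 2, col = "grey40")
  hi <- x$contact$delta_c + x$strain_max * x$contact$h
  sel <- d >= x$contact$delta_c & d <= hi
  if (any(sel)) {
    i <- stats::lm.fit(cbind(1, d[sel]), f[sel])$coefficients
    graphics::lines(1e6 * d[sel], i[1] + i[2] * d[sel], col = "red", lwd = 2)
  }
  invisible(x)
}
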