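# Curve containers and their CSV dialects.

#' Torque versus angular-velocity curve
#'
#' One rotating-disc run: resistive torque sampled over an increasing
#' angular-velocity ramp. Samples are sorted by angular velocity and duplicate
#' velocities are collapsed to their mean torque (logged), so the stored
#' velocity grid is strictly increasing.
#'
#' @param omega angular velocity per sample, rad/s, all > 0.
#' @param torque torque per sample, N.m, finite.
#' @param time optional time per sample, s.
#' @param coupon_id,treatment optional labels carried in `meta`.
#' @return object of class `torque_velocity_curve` with elements `omega`,
#'   `torque`, `time`, `meta`.
#' @export
torque_velocity_curve <- function(omega, torque, time = NULL,
                                  coupon_id = NA_character_,
                                  treatment = NA_character_) {
  if (length(omega) != length(torque))
    stop("'omega' and 'torque' must have the same length", call. = FALSE)
  if (!is.null(time) && length(time) != length(omega))
    stop("'time' must match the sample count", call. = FALSE)
  if (!all(is.finite(omega)) || !all(is.finite(torque)))
    stop("'omega' and 'torque' must be finite", call. = FALSE)
  if (any(omega < 0))
    stop("angular velocity must be >= 0 rad/s", call. = FALSE)

  ord <- order(omega)
  omega <- omega[ord]; torque <- torque[ord]
  if (!is.null(time)) time <- time[ord]
  if (anyDuplicated(omega)) {
    ndup <- sum(duplicated(omega))
    grp <- match(omega, unique(omega))
    torque <- as.numeric(tapply(torque, grp, mean))
    if (!is.null(time)) time <- as.numeric(tapply(time, grp, mean))
    omega <- unique(omega)
    log_event("collapsed ", ndup, " duplicate angular-velocity sample(s) by mean")
  }
  if (length(omega) < 3L)
    stop("a torque-velocity curve needs at least 3 distinct samples", call. = FALSE)

  structure(list(omega = omega, torque = torque, time = time,
                 meta = list(coupon_id = coupon_id, treatment = treatment)),
            class = "torque_velocity_curve")
}

#' @export
print.torque_velocity_curve <- function(x, ...) {
  cat(sprintf("Torque-velocity curve: %d samples, omega %.3g-%.4g rad/s, torque %.3g-%.3g N.m\n",
              length(x$omega), min(x$omega), max(x$omega),
              min(x$torque), max(x$torque)))
  if (!is.na(x$meta$treatment)) cat("  treatment:", x$meta$treatment, "\n")
  invisible(x)
}

#' @export
length.torque_velocity_curve <- function(x) length(x$omega)

#' Force versus displacement indentation curve
#'
#' One uniaxial indentation approach: normal force sampled while the probe
#' advances toward the substratum. Displacement increases toward the
#' substratum and must be monotone non-decreasing.
#'
#' @param displacement m per sample, monotone non-decreasing.
#' @param force N per sample, finite.
#' @param disc_id,treatment optional labels carried in `meta`.
#' @return object of class `force_displacement_curve`.
#' @export
force_displacement_curve <- function(displacement, force,
                                     disc_id = NA_character_,
                                     treatment = NA_character_) {
  if (length(displacement) != length(force))
    stop("'displacement' and 'force' must have the same length", call. = FALSE)
  if (!all(is.finite(displacement)) || !all(is.finite(force)))
    stop("'displacement' and 'force' must be finite", call. = FALSE)
  if (is.unsorted(displacement))
    stop("'displacement' must be monotone non-decreasing", call. = FALSE)
  structure(list(displacement = displacement, force = force,
                 meta = list(disc_id = disc_id, treatment = treatment)),
            class = "force_displacement_curve")
}

#' @export
print.force_displacement_curve <- function(x, ...) {
  cat(sprintf("Force-displacement curve: %d samples, span %.3g um, peak force %.3g N\n",
              length(x$displacement),
              1e6 * diff(range(x$displacement)), max(x$force)))
  invisible(x)
}

#' @export
length.force_displacement_curve <- function(x) length(x$displacement)

#' Read a rheometer torque export
#'
#' Comma-separated with a header row; column names are configurable because
#' rheometer exports vary. Torque may be recorded in N.m (canonical) or
#' micro/milli multiples; values are converted to N.m. Rows are sorted by
#' angular velocity and duplicate velocities averaged.
#'
#' @param path CSV file path.
#' @param geometry,fluid [disc_geometry()] and [fluid_properties()] recorded
#'   alongside the curve for downstream analysis.
#' @param omega_col,torque_col,time_col column names in the file.
#' @param torque_unit unit of the torque column: `"N.m"`, `"mN.m"` or `"uN.m"`.
#' @param coupon_id,treatment labels stored in `meta`.
#' @return a [torque_velocity_curve()] with `geometry` and `fluid` attached
#'   to `meta`.
#' @export
read_rheometry_csv <- function(path, geometry = disc_geometry(),
                               fluid = fluid_properties(),
                               omega_col = "omega", torque_col = "torque",
                               time_col = "time", torque_unit = "N.m",
                               coupon_id = NA_character_,
                               treatment = NA_character_) {
  df <- read_curve_table(path, c(omega_col, torque_col))
  torque <- convert_units(df[[torque_col]], torque_unit, "N.m")
  time <- if (time_col %in% names(df)) df[[time_col]] else NULL
  curve <- torque_velocity_curve(df[[omega_col]], torque, time = time,
                                 coupon_id = coupon_id, treatment = treatment)
  curve$meta$geometry <- geometry
  curve$meta$fluid <- fluid
  curve
}

#' Write a torque-velocity curve as CSV
#'
#' @param curve a [torque_velocity_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rheometry_csv <- function(curve, path) {
  df <- data.frame(omega = curve$omega, torque = curve$torque)
  if (!is.null(curve$time)) df$time <- curve$time
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an indentation force export
#'
#' Comma-separated with a header; extra columns (e.g. time) are ignored.
#' Retraction samples — everything after the global displacement maximum —
#' are discarded with a logged warning, and the remaining approach samples
#' are put in displacement order by a stable sort.
#'
#' @param path CSV file path.
#' @param displacement_col,force_col column names.
#' @param displacement_unit `"m"` (canonical), `"mm"` or `"um"`.
#' @param force_unit `"N"` (canonical), `"mN"` or `"uN"`.
#' @param disc_id,treatment labels stored in `meta`.
#' @return a [force_displacement_curve()].
#' @export
read_indentation_csv <- function(path, displacement_col = "displacement",
                                 force_col = "force",
                                 displacement_unit = "m", force_unit = "N",
                                 disc_id = NA_character_,
                                 treatment = NA_character_) {
  df <- read_curve_table(path, c(displacement_col, force_col))
  d <- convert_units(df[[displacement_col]], displacement_unit, "m")
  f <- convert_units(df[[force_col]], force_unit, "N")
  if (length(d) >= 2L && d[length(d)] < d[1L] && all(diff(d) <= 0))
    stop("negative displacement span in '", path,
         "': displacement decreases over the whole record", call. = FALSE)

  imax <- which.max(d)
  if (imax < length(d)) {
    ndrop <- length(d) - imax
    log_event("discarded ", ndrop, " retraction sample(s) after the ",
              "displacement maximum in ", basename(path))
    d <- d[seq_len(imax)]; f <- f[seq_len(imax)]
  }
  if (length(d) < 10L)
    stop("too few samples (", length(d), ") in '", path,
         "': at least 10 approach samples required", call. = FALSE)
  ord <- order(d)  # radix sort, stable
  force_displacement_curve(d[ord], f[ord], disc_id = disc_id,
                           treatment = treatment)
}

#' Write an indentation curve as CSV
#'
#' @param curve a [force_displacement_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_indentation_csv <- function(curve, path) {
  utils::write.csv(data.frame(displacement = curve$displacement,
                              force = curve$force),
                   path, row.names = FALSE)
  invisible(path)
}

read_curve_table <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (file.size(path) == 0L)
    stop("empty input file: '", path, "'", call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L)
    stop("empty input file: '", path, "' (header only)", call. = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("missing column(s) ", paste0("'", missing, "'", collapse = ", "),
         " in '", path, "'", call. = FALSE)
  df
}
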