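# Seeded synthetic-data generators.
#
# Every generator returns the object plus a `truth` list holding each
# injected parameter, so analysis code can be tested for parameter recovery.
# All randomness is controlled by an explicit seed and global RNG state is
# restored afterwards.

#' Generate a rotating-disc torque curve
#'
#' Angular velocity is log-spaced over the ramp (default 0.1-300 rad/s, 72
#' points across 360 s). Torque follows the moment-coefficient model
#' `T = 0.5 rho omega^2 R^5 (Cm_s(Re) + Cf(omega)) (1 + eps)`: smooth-disc
#' baseline plus a biofilm excess `Cf` that is piecewise constant and drops
#' by a stated fraction at each detachment event, with multiplicative
#' Gaussian noise `eps` (torque ripple scales with load).
#'
#' @param cf0 initial biofilm momentum coefficient (>= 0).
#' @param events `NULL` or data frame with columns `omega` (strictly inside
#'   the ramp) and `drop` (fractional Cf drop in `(0, 1]`).
#' @param noise_sd relative SD of the multiplicative torque noise.
#' @param geometry,fluid disc and fluid models.
#' @param n_points samples across the ramp.
#' @param omega_range `c(min, max)` of the ramp, rad/s.
#' @param duration ramp duration, s.
#' @param seed integer seed; the draw is deterministic given it.
#' @param coupon_id,treatment labels for the curve `meta`.
#' @return list with `curve` (a [torque_velocity_curve()]) and `truth`
#'   (injected `cf0`, `events`, per-sample `cf`, `noise_sd`, `seed`).
#' @export
generate_torque_curve <- function(cf0, events = NULL, noise_sd = 0,
                                  geometry = disc_geometry(),
                                  fluid = fluid_properties(),
                                  n_points = 72, omega_range = c(0.1, 300),
                                  duration = 360, seed = NULL,
                                  coupon_id = NA_character_,
                                  treatment = NA_character_) {
  if (cf0 < 0) stop("'cf0' must be >= 0", call. = FALSE)
  if (!is.null(events) && nrow(events)) {
    if (any(events$omega <= omega_range[1]) || any(events$omega >= omega_range[2]))
      stop("event velocities must lie strictly inside the ramp", call. = FALSE)
    if (any(events$drop <= 0) || any(events$drop > 1))
      stop("event drops must be in (0, 1]", call. = FALSE)
  }
  omega <- exp(seq(log(omega_range[1]), log(omega_range[2]),
                   length.out = n_points))
  cf <- rep(cf0, n_points)
  if (!is.null(events) && nrow(events)) {
    for (j in seq_len(nrow(events))) {
      after <- omega >= events$omega[j]
      cf[after] <- cf[after] * (1 - events$drop[j])
    }
  }
  cms <- smooth_disc_moment_coefficient(omega, geometry, fluid)
  torque_clean <- 0.5 * fluid$density * omega^2 * geometry$radius^5 * (cms + cf)
  eps <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  } else rep(0, n_points)
  curve <- torque_velocity_curve(omega, torque_clean * (1 + eps),
                                 time = seq(0, duration, length.out = n_points),
                                 coupon_id = coupon_id, treatment = treatment)
  list(curve = curve,
       truth = list(cf0 = cf0, events = events, cf = cf,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate a uniaxial indentation curve
#'
#' Emulates a flat probe approaching at constant rate with termination at a
#' force limit: baseline noise before contact, linear biofilm compression of
#' stiffness `k = 2 r E / (1 - v^2)` (the modulus formula inverted), then a
#' much stiffer substratum response. Noise is additive on force with SD
#' expressed relative to the force at 20% strain.
#'
#' @param E biofilm Young's modulus, Pa (> 0).
#' @param h biofilm thickness, m (> 0).
#' @param delta_c contact displacement, m.
#' @param substratum_ratio substratum-to-biofilm stiffness ratio (> 1).
#' @param noise_sd noise SD relative to the force at 20% strain.
#' @param probe a [probe_geometry()].
#' @param n_points samples over the approach.
#' @param overtravel extra travel past the substratum, as a fraction of `h`.
#' @param termination force limit, N; samples beyond it are discarded.
#' @param seed integer seed.
#' @param disc_id,treatment labels for the curve `meta`.
#' @return list with `curve` (a [force_displacement_curve()]) and `truth`
#'   (injected `E`, `h`, `delta_c`, biofilm stiffness `k`, `seed`).
#' @export
generate_indentation_curve <- function(E, h = 200e-6, delta_c = 50e-6,
                                       substratum_ratio = 200,
                                       noise_sd = 0.02,
                                       probe = probe_geometry(),
                                       n_points = 600, overtravel = 0.5,
                                       termination = 15, seed = NULL,
                                       disc_id = NA_character_,
                                       treatment = NA_character_) {
  stopifnot_scalar(E, "E"); stopifnot_scalar(h, "h")
  if (substratum_ratio <= 1)
    stop("'substratum_ratio' must be > 1", call. = FALSE)
  k <- 2 * probe$radius * E / (1 - probe$poisson^2)
  d <- seq(0, delta_c + h * (1 + overtravel), length.out = n_points)
  f <- numeric(n_points)
  in_film <- d >= delta_c & d < delta_c + h
  past <- d >= delta_c + h
  f[in_film] <- k * (d[in_film] - delta_c)
  f[past] <- k * h + substratum_ratio * k * (d[past] - delta_c - h)
  sigma <- noise_sd * k * 0.2 * h
  if (noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(n_points, 0, sigma))
  keep <- f <= termination
  curve <- force_displacement_curve(d[keep], f[keep], disc_id = disc_id,
                                    treatment = treatment)
  list(curve = curve,
       truth = list(E = E, h = h, delta_c = delta_c, k = k,
                    substratum_ratio = substratum_ratio,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate a two-channel biofilm image stack
#'
#' The cells channel fills each (y, x) column from the substratum to a height
#' drawn from a lognormal distribution (columnar biofilm with controllable
#' heterogeneity). The EPS channel is either a uniform layer (`"layer"`, the
#' untreated phenotype) or the same total volume redistributed into a random
#' subset of columns (`"punctate"`, the treated phenotype): fewer, taller
#' columns at the stated coverage.
#'
#' @param shape `c(nz, ny, nx)` voxels.
#' @param voxel_size `c(dz, dy, dx)` um.
#' @param height_meanlog,height_sdlog lognormal parameters of the cell-column
#'   height in um.
#' @param eps_style `"layer"` or `"punctate"`.
#' @param eps_thickness EPS layer thickness, um (sets total EPS volume for
#'   both styles).
#' @param coverage fraction of columns carrying EPS in the punctate style.
#' @param seed integer seed.
#' @return list with `stack` (logical [image_stack()]) and `truth`
#'   (per-channel voxel counts, the drawn column heights, style parameters).
#' @export
generate_image_stack <- function(shape = c(40, 48, 48),
                                 voxel_size = c(1, 0.5, 0.5),
                                 height_meanlog = log(20), height_sdlog = 0.3,
                                 eps_style = c("layer", "punctate"),
                                 eps_thickness = 8, coverage = 0.3,
                                 seed = NULL) {
  eps_style <- match.arg(eps_style)
  if (coverage <= 0 || coverage > 1)
    stop("'coverage' must be in (0, 1]", call. = FALSE)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  dz <- voxel_size[1]
  ncol_total <- ny * nx

  out <- with_seed(seed, {
    hts_um <- stats::rlnorm(ncol_total, height_meanlog, height_sdlog)
    hts_vox <- pmin(pmax(round(hts_um / dz), 0L), nz)

    layer_vox <- min(nz, max(1L, round(eps_thickness / dz)))
    v_total <- layer_vox * ncol_total
    if (eps_style == "layer") {
      eps_vox <- rep(layer_vox, ncol_total)
    } else {
      m <- max(1L, round(coverage * ncol_total))
      chosen <- sample.int(ncol_total, m)
      base <- v_total %/% m
      extra <- v_total %% m
      if (base >= nz) {            # cannot stack higher than the volume
        base <- nz; extra <- 0L
      }
      eps_vox <- integer(ncol_total)
      eps_vox[chosen] <- base
      if (extra > 0L) {
        bump <- chosen[seq_len(extra)]
        eps_vox[bump] <- pmin(eps_vox[bump] + 1L, nz)
      }
    }
    list(hts_vox = hts_vox, eps_vox = eps_vox)
  })

  fill_columns <- function(vox) {
    a <- array(FALSE, dim = c(nz, ny, nx))
    zmat <- matrix(seq_len(nz), nrow = nz, ncol = ncol_total)
    a[] <- zmat <= rep(vox, each = nz)
    a
  }
  cells <- fill_columns(out$hts_vox)
  eps <- fill_columns(out$eps_vox)
  stack <- image_stack(list(cells = cells, eps = eps), voxel_size)
  list(stack = stack,
       truth = list(cell_heights_vox = out$hts_vox,
                    eps_heights_vox = out$eps_vox,
                    cell_voxels = sum(out$hts_vox),
                    eps_voxels = sum(out$eps_vox),
                    eps_style = eps_style, eps_thickness = eps_thickness,
                    coverage = coverage, seed = seed))
}

#' Specification of a synthetic treatment study
#'
#' Defaults reproduce the published study conditions: four treatment groups
#' whose Young's moduli (kPa) are drawn from the printed group means and SDs
#' (untreated 27.28 +/- 8.68, arginine 15.38 +/- 7.97, zinc 11.14 +/- 5.02,
#' dza 9.29 +/- 2.87, truncated below at 0.5 kPa); rotating-disc momentum
#' coefficients for the three groups the disc assay covered (untreated
#' 0.063 +/- 0.021, zinc 0.053 +/- 0.023, dza 0.037 +/- 0.023; the arginine
#' arm was not run on the rheometer and gets `NA`); detachment events whose
#' typical velocity decreases with treatment (treated biofilms shed at lower
#' shear); and EPS architecture that shifts from a homogeneous layer
#' (untreated) to punctate coverage (treated). Replicate counts are per
#' assay, matching the published designs: 3 biological x 2 coupons for
#' rheometry, 4 biological x 3 technical for indentation, 3 biological x 4
#' images for confocal quantification.
#'
#' @param groups data frame with columns `label`, `e_mean`, `e_sd` (kPa),
#'   `cf_mean`, `cf_sd`, `event_omega` (typical detachment velocity, rad/s),
#'   `eps_style`.
#' @param rheo_biological,rheo_coupons rheometry replicate structure.
#' @param indent_biological,indent_technical indentation replicate structure.
#' @param image_biological,image_fields imaging replicate structure.
#' @param torque_noise_sd,indent_noise_sd instrument noise levels.
#' @param event_drop fractional Cf drop at each detachment event.
#' @param e_floor_kpa lower truncation of drawn moduli, kPa.
#' @param seed study-level seed.
#' @return object of class `study_spec` (a list of the above).
#' @export
study_spec <- function(groups = default_study_groups(),
                       rheo_biological = 3, rheo_coupons = 2,
                       indent_biological = 4, indent_technical = 3,
                       image_biological = 3, image_fields = 4,
                       torque_noise_sd = 0.01, indent_noise_sd = 0.02,
                       event_drop = 0.5, e_floor_kpa = 0.5, seed = 1) {
  stopifnot(all(c("label", "e_mean", "e_sd", "cf_mean", "cf_sd",
                  "event_omega", "eps_style") %in% names(groups)))
  if (any(groups$e_sd < 0) || any(groups$cf_sd < 0, na.rm = TRUE))
    stop("SDs must be >= 0", call. = FALSE)
  if (min(rheo_biological, rheo_coupons, indent_biological,
          indent_technical, image_biological, image_fields) < 1)
    stop("replicate counts must be >= 1", call. = FALSE)
  structure(list(groups = groups,
                 rheo_biological = rheo_biological,
                 rheo_coupons = rheo_coupons,
                 indent_biological = indent_biological,
                 indent_technical = indent_technical,
                 image_biological = image_biological,
                 image_fields = image_fields,
                 torque_noise_sd = torque_noise_sd,
                 indent_noise_sd = indent_noise_sd,
                 event_drop = event_drop,
                 e_floor_kpa = e_floor_kpa,
                 seed = seed),
            class = "study_spec")
}

#' Default treatment groups of the synthetic study
#'
#' @return data frame of the four groups with published means and SDs.
#' @export
default_study_groups <- function() {
  data.frame(
    label = c("untreated", "arginine", "zinc", "dza"),
    e_mean = c(27.28, 15.38, 11.14, 9.29),      # kPa
    e_sd = c(8.68, 7.97, 5.02, 2.87),
    cf_mean = c(0.063, NA, 0.053, 0.037),
    cf_sd = c(0.021, NA, 0.023, 0.023),
    event_omega = c(180, NA, 120, 60),          # rad/s
    eps_style = c("layer", "punctate", "punctate", "punctate")
  )
}

#' @export
print.study_spec <- function(x, ...) {
  cat("Synthetic study specification (seed ", x$seed, ")\n", sep = "")
  print(x$groups, row.names = FALSE)
  cat(sprintf("  rheometry %d bio x %d coupons; indentation %d bio x %d tech; imaging %d bio x %d fields\n",
              x$rheo_biological, x$rheo_coupons, x$indent_biological,
              x$indent_technical, x$image_biological, x$image_fields))
  invisible(x)
}

#' Generate a full synthetic study in memory
#'
#' Draws per-replicate parameters from the group distributions and generates
#' every instrument record: torque curves (groups with a rheometry arm),
#' indentation curves and two-channel stacks. Fully deterministic given the
#' spec seed. Use [write_study()] to materialise it as CSV/TIFF files with a
#' manifest and truth sidecar.
#'
#' @param spec a [study_spec()].
#' @param with_images generate image stacks (set `FALSE` to speed up studies
#'   that only need mechanics).
#' @return object of class `synthetic_study`: lists `torque`, `indentation`,
#'   `images` of generated objects (each with its truth), plus `manifest`
#'   (data frame) and `spec`.
#' @export
generate_study <- function(spec = study_spec(), with_images = TRUE) {
  groups <- spec$groups
  # independent sub-seeds per record, derived once from the study seed
  n_max <- nrow(groups) * (spec$rheo_biological * spec$rheo_coupons +
                             spec$indent_biological * spec$indent_technical +
                             spec$image_biological * spec$image_fields)
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, n_max))
  draws <- with_seed(spec$seed + 1L, {
    list(cf = stats::rnorm(n_max), e = stats::rnorm(n_max),
         ev = stats::rlnorm(n_max, 0, 0.15))
  })
  ctr <- 0L
  nxt <- function() { ctr <<- ctr + 1L; ctr }

  torque <- list(); indentation <- list(); images <- list()
  manifest <- list()

  for (g in seq_len(nrow(groups))) {
    lab <- groups$label[g]

    if (!is.na(groups$cf_mean[g])) {
      for (b in seq_len(spec$rheo_biological)) for (cpn in seq_len(spec$rheo_coupons)) {
        i <- nxt()
        cf_i <- max(groups$cf_mean[g] + groups$cf_sd[g] * draws$cf[i], 1e-4)
        ev_omega <- groups$event_omega[g] * draws$ev[i]
        ev_omega <- min(max(ev_omega, 1), 280)
        ev <- data.frame(omega = ev_omega, drop = spec$event_drop)
        id <- sprintf("%s_b%d_c%d", lab, b, cpn)
        gen <- generate_torque_curve(cf_i, events = ev,
                                     noise_sd = spec$torque_noise_sd,
                                     seed = seeds[i], coupon_id = id,
                                     treatment = lab)
        torque[[id]] <- gen
        manifest[[length(manifest) + 1L]] <-
          data.frame(id = id, group = lab, biological = b, technical = cpn,
                     kind = "torque")
      }
    }

    for (b in seq_len(spec$indent_biological)) for (tch in seq_len(spec$indent_technical)) {
      i <- nxt()
      e_kpa <- max(groups$e_mean[g] + groups$e_sd[g] * draws$e[i],
                   spec$e_floor_kpa)
      id <- sprintf("%s_b%d_t%d", lab, b, tch)
      gen <- generate_indentation_curve(E = e_kpa * 1e3,
                                        noise_sd = spec$indent_noise_sd,
                                        seed = seeds[i], disc_id = id,
                                        treatment = lab)
      indentation[[id]] <- gen
      manifest[[length(manifest) + 1L]] <-
        data.frame(id = id, group = lab, biological = b, technical = tch,
                   kind = "indentation")
    }

    if (with_images) {
      for (b in seq_len(spec$image_biological)) for (fl in seq_len(spec$image_fields)) {
        i <- nxt()
        id <- sprintf("%s_b%d_f%d", lab, b, fl)
        gen <- generate_image_stack(eps_style = groups$eps_style[g],
                                    seed = seeds[i])
        images[[id]] <- gen
        manifest[[length(manifest) + 1L]] <-
          data.frame(id = id, group = lab, biological = b, technical = fl,
                     kind = "image")
      }
    }
  }

  structure(list(torque = torque, indentation = indentation, images = images,
                 manifest = do.call(rbind, manifest), spec = spec),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d torque curve(s), %d indentation curve(s), %d image stack(s)\n",
              length(x$torque), length(x$indentation), length(x$images)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Materialises a [generate_study()] result as the file dialects the readers
#' consume: one CSV per curve, one pair of single-channel TIFFs per stack, a
#' `manifest.csv` mapping files to group/replicate, and a `truth.json`
#' sidecar with every injected parameter.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- study$manifest
  manifest$file <- NA_character_
  manifest$voxel_dz <- NA_real_
  manifest$voxel_dy <- NA_real_
  manifest$voxel_dx <- NA_real_

  set_file <- function(id, path) {
    manifest$file[manifest$id == id] <<- path
  }
  for (id in names(study$torque)) {
    p <- file.path(dir, paste0("torque_", id, ".csv"))
    write_rheometry_csv(study$torque[[id]]$curve, p)
    set_file(id, basename(p))
  }
  for (id in names(study$indentation)) {
    p <- file.path(dir, paste0("indent_", id, ".csv"))
    write_indentation_csv(study$indentation[[id]]$curve, p)
    set_file(id, basename(p))
  }
  for (id in names(study$images)) {
    stk <- study$images[[id]]$stack
    paths <- c(cells = file.path(dir, paste0("stack_", id, "_cells.tif")),
               eps = file.path(dir, paste0("stack_", id, "_eps.tif")))
    write_image_stack(stk, paths)
    set_file(id, paste(basename(paths), collapse = ";"))
    sel <- manifest$id == id
    manifest$voxel_dz[sel] <- stk$voxel_size[1]
    manifest$voxel_dy[sel] <- stk$voxel_size[2]
    manifest$voxel_dx[sel] <- stk$voxel_size[3]
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)

  truth <- list(
    spec = unclass(study$spec),
    torque = lapply(study$torque, `[[`, "truth"),
    indentation = lapply(study$indentation, `[[`, "truth"),
    images = lapply(study$images, function(g)
      g$truth[c("cell_voxels", "eps_voxels", "eps_style", "coverage")])
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
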