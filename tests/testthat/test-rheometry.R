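test_that("smooth-disc moment coefficient follows both similarity branches", {
  geo <- disc_geometry(); fl <- fluid_properties()
  # Re = 25 * 0.02^2 / 1e-6 = 1e4 -> laminar 1.935/sqrt(1e4)
  expect_equal(smooth_disc_moment_coefficient(25, geo, fl), 0.01935)
  # Re = 1 at omega = nu/R^2
  expect_equal(smooth_disc_moment_coefficient(1e-6 / 0.02^2, geo, fl), 1.935)
  # branch boundary Re = 3e5 uses the laminar value
  om_b <- 3e5 * 1e-6 / 0.02^2
  expect_equal(smooth_disc_moment_coefficient(om_b, geo, fl),
               1.935 / sqrt(3e5))
  # just above the boundary: turbulent branch
  expect_equal(smooth_disc_moment_coefficient(om_b * 1.001, geo, fl),
               0.0365 * (3e5 * 1.001)^(-1 / 5))
  expect_error(smooth_disc_moment_coefficient(0, geo, fl), "> 0")
})

test_that("moment-coefficient curve matches hand substitution and scaling law", {
  geo <- disc_geometry(); fl <- fluid_properties()
  curve <- torque_velocity_curve(c(5, 10, 20), c(5e-5, 1e-4, 2e-4))
  cm <- momentum_coefficient_curve(curve, geo, fl)
  expect_equal(cm[2], 1e-4 / (0.5 * 998 * 100 * 0.02^5))  # 0.6263
  expect_equal(cm[2], 0.6263, tolerance = 1e-4)

  zero <- torque_velocity_curve(c(5, 10, 20), c(0, 0, 0))
  expect_equal(momentum_coefficient_curve(zero, geo, fl), c(0, 0, 0))

  big <- disc_geometry(radius = 0.04)
  expect_equal(momentum_coefficient_curve(curve, big, fl), cm / 32)
})

test_that("biofilm momentum coefficient inverts the generator exactly", {
  geo <- disc_geometry(); fl <- fluid_properties()
  omega <- ramp_grid()
  build <- function(excess) {
    cms <- smooth_disc_moment_coefficient(omega, geo, fl)
    torque_velocity_curve(omega, 0.5 * 998 * omega^2 * 0.02^5 * (cms + excess))
  }
  expect_equal(biofilm_momentum_coefficient(build(0.05), geo, fl), 0.05,
               tolerance = 1e-10)
  expect_lt(abs(biofilm_momentum_coefficient(build(0), geo, fl)), 1e-10)
  expect_equal(biofilm_momentum_coefficient(build(0.063), geo, fl), 0.063,
               tolerance = 1e-10)
  expect_error(biofilm_momentum_coefficient(build(0.05), geo, fl,
                                            window = c(400, 500)), "window")
})

test_that("linearised slope transform removes linear trend and isolates steps", {
  omega <- seq(1, 100, length.out = 50)
  linear <- torque_velocity_curve(omega, 2e-6 + 3e-7 * omega)
  s <- linearized_slope_transform(linear)
  expect_length(s$slope, 49)
  expect_true(all(abs(s$slope) < 1e-12))

  # single step drop: one strongly negative slope at the step interval
  torque <- 2e-6 + 3e-7 * omega
  torque[omega >= 60] <- torque[omega >= 60] - 5e-6
  s2 <- linearized_slope_transform(torque_velocity_curve(omega, torque))
  k <- which.min(s2$slope)
  j <- which(omega >= 60)[1]
  expect_equal(s2$omega_mid[k], mean(omega[c(j - 1, j)]))
  expect_lt(s2$slope[k], -1e-6)

  # smooth quadratic: slope series monotone in omega (no spurious spikes)
  quad <- torque_velocity_curve(omega, 1e-8 * omega^2)
  s3 <- linearized_slope_transform(quad)
  expect_true(all(diff(s3$slope) > 0))
  expect_error(linearized_slope_transform(
    torque_velocity_curve(c(1, 2), c(1, 2))), "at least 3")
})

test_that("event detection flags injected spikes and nothing else", {
  mk <- function(slope) structure(list(omega_mid = seq_along(slope),
                                       slope = slope), class = "slope_series")
  expect_equal(nrow(detect_detachment_events(mk(rep(0, 40)))), 0)

  # bounded deterministic baseline with one -10 robust-SD spike
  base <- sin(seq_len(60)) * 1e-7
  spike <- base; spike[25] <- -15e-7
  ev <- detect_detachment_events(mk(spike))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$omega, 25)
  expect_lt(ev$slope, 0)

  two <- base
  two[c(20, 45)] <- -15e-7
  ev2 <- detect_detachment_events(mk(two))
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$omega, c(20, 45))
})

test_that("wall shear stress matches hand values and is monotone", {
  geo <- disc_geometry(); fl <- fluid_properties()
  expect_equal(wall_shear_stress(0, geo, fl), 0)
  expect_equal(wall_shear_stress(100, geo, fl),
               0.8 * 998 * 0.02 * sqrt(1e-6 * 1e6))   # 15.968 Pa
  expect_equal(wall_shear_stress(100, geo, fl), 15.97, tolerance = 1e-3)
  expect_equal(wall_shear_stress(1, geo, fl), 0.01597, tolerance = 1e-3)
  om <- seq(1, 300, length.out = 40)
  expect_true(all(diff(wall_shear_stress(om, geo, fl)) > 0))
  radii <- seq(0.01, 0.05, length.out = 10)
  taus <- vapply(radii, function(r)
    wall_shear_stress(50, disc_geometry(radius = r), fl), numeric(1))
  expect_true(all(diff(taus) > 0))
  expect_error(wall_shear_stress(-1, geo, fl), ">= 0")
})

test_that("critical detachment shear stress uses the first event or is missing", {
  geo <- disc_geometry(); fl <- fluid_properties()
  ev <- data.frame(omega = c(120, 50), slope = c(-1, -2), tau = c(0, 0))
  expect_equal(critical_detachment_shear_stress(ev, geo, fl),
               wall_shear_stress(50, geo, fl))
  none <- data.frame(omega = numeric(0), slope = numeric(0), tau = numeric(0))
  expect_true(is.na(critical_detachment_shear_stress(none, geo, fl)))
})

test_that("torque AUC is the trapezoidal integral", {
  tri <- torque_velocity_curve(c(0, 1, 2), c(0, 1, 2))
  expect_equal(torque_auc(tri), 2)
  const <- torque_velocity_curve(c(0.1, 100, 300), rep(3e-4, 3))
  expect_equal(torque_auc(const), 3e-4 * 299.9)
  om <- seq(0, 2, length.out = 512)
  sq <- torque_velocity_curve(om, om^2)
  expect_equal(torque_auc(sq), 8 / 3, tolerance = 1e-3)
  # pointwise domination implies AUC ordering
  lo <- torque_velocity_curve(om, om^2 * 0.5)
  expect_lte(torque_auc(lo), torque_auc(sq))
})

test_that("detachment events injected by the generator are recovered at the right velocity", {
  gen <- generate_torque_curve(cf0 = 0.05,
                               events = data.frame(omega = 50, drop = 0.5),
                               noise_sd = 0, seed = 1)
  fit <- rheology_fit(gen$curve)
  expect_gte(nrow(fit$events), 1)
  grid <- ramp_grid()
  step_idx <- which(grid >= 50)[1]
  # event reported at the interval midpoint bracketing the injected velocity
  expect_lt(abs(fit$events$omega[1] - 50), diff(grid[step_idx + c(-1, 1)]))
  expect_equal(fit$tau_star,
               wall_shear_stress(fit$events$omega[1], disc_geometry(),
                                 fluid_properties()))
})
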