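test_that("torque generator is deterministic and faithful to injected truth", {
  a <- generate_torque_curve(cf0 = 0.05, noise_sd = 0.01, seed = 4)
  b <- generate_torque_curve(cf0 = 0.05, noise_sd = 0.01, seed = 4)
  expect_identical(a$curve$torque, b$curve$torque)
  c2 <- generate_torque_curve(cf0 = 0.05, noise_sd = 0.01, seed = 5)
  expect_false(identical(a$curve$torque, c2$curve$torque))

  clean <- generate_torque_curve(cf0 = 0.063, noise_sd = 0, seed = 1)
  expect_equal(biofilm_momentum_coefficient(clean$curve), 0.063,
               tolerance = 1e-9)

  expect_error(generate_torque_curve(0.05,
                                     events = data.frame(omega = 400,
                                                         drop = 0.5)),
               "inside the ramp")
  expect_error(generate_torque_curve(0.05,
                                     events = data.frame(omega = 50,
                                                         drop = 1.5)),
               "drops")
})

test_that("torque generator injects a step discontinuity at each event", {
  gen <- generate_torque_curve(cf0 = 0.05,
                               events = data.frame(omega = 50, drop = 0.5),
                               noise_sd = 0, seed = 1)
  grid <- gen$curve$omega
  j <- which(grid >= 50)[1]
  expect_equal(gen$truth$cf[j], 0.025)
  expect_equal(gen$truth$cf[j - 1], 0.05)
  # the torque step is visible as the most negative linearised slope
  s <- linearized_slope_transform(gen$curve)
  expect_equal(which.min(s$slope), j - 1L)
})

test_that("indentation generator inverts the modulus formula and is deterministic", {
  gen <- generate_indentation_curve(E = 93.75, noise_sd = 0, seed = 1)
  expect_equal(gen$truth$k, 1.0)
  a <- generate_indentation_curve(E = 10e3, seed = 2)
  b <- generate_indentation_curve(E = 10e3, seed = 2)
  expect_identical(a$curve$force, b$curve$force)
  expect_true(all(a$curve$force <= 15))

  # noise-free analyzable quantities match truth
  fit <- indentation_fit(generate_indentation_curve(E = 12e3, noise_sd = 0,
                                                    seed = 3)$curve)
  expect_equal(fit$E, 12e3, tolerance = 1e-9)
})

test_that("image generator matches its truth sidecar and styles differ as designed", {
  gen <- generate_image_stack(shape = c(16, 12, 12), seed = 7)
  q <- quantify_stack(gen$stack)
  area <- 12 * 0.5 * 12 * 0.5
  expect_equal(q$biomass[q$channel == "cells"],
               gen$truth$cell_voxels * prod(gen$stack$voxel_size) / area)

  lay <- generate_image_stack(eps_style = "layer", seed = 9)
  pun <- generate_image_stack(eps_style = "punctate", seed = 9)
  # matched total EPS volume, different architecture
  expect_equal(pun$truth$eps_voxels, lay$truth$eps_voxels)
  q_lay <- quantify_stack(lay$stack); q_pun <- quantify_stack(pun$stack)
  expect_equal(q_lay$roughness[q_lay$channel == "eps"], 0)
  expect_gt(q_pun$roughness[q_pun$channel == "eps"],
            q_lay$roughness[q_lay$channel == "eps"])

  d1 <- generate_image_stack(seed = 10)
  d2 <- generate_image_stack(seed = 10)
  expect_identical(d1$stack$channels$cells, d2$stack$channels$cells)
})

test_that("study generator is deterministic with the published replicate structure", {
  spec <- study_spec(seed = 3)
  st <- generate_study(spec)
  # rheometry: 3 groups with a disc arm x 3 bio x 2 coupons
  expect_length(st$torque, 3 * 3 * 2)
  # indentation: 4 groups x 4 bio x 3 technical
  expect_length(st$indentation, 4 * 4 * 3)
  # imaging: 4 groups x 3 bio x 4 fields
  expect_length(st$images, 4 * 3 * 4)
  expect_equal(nrow(st$manifest),
               length(st$torque) + length(st$indentation) + length(st$images))

  st2 <- generate_study(spec)
  expect_identical(st$indentation[[5]]$curve$force,
                   st2$indentation[[5]]$curve$force)
  st3 <- generate_study(study_spec(seed = 4))
  expect_false(identical(st$indentation[[5]]$curve$force,
                         st3$indentation[[5]]$curve$force))
  expect_equal(dim(st3$manifest), dim(st$manifest))
})

test_that("zero-SD study recovers every group mean within analyzer tolerance", {
  groups <- default_study_groups()
  groups$e_sd <- 0; groups$cf_sd[!is.na(groups$cf_sd)] <- 0
  st <- generate_study(study_spec(groups = groups, seed = 6),
                       with_images = FALSE)
  rep <- run_pipeline(st)
  em <- rep$comparisons$E$groups
  for (g in seq_len(nrow(groups))) {
    got <- em$mean[em$group == groups$label[g]] / 1e3   # Pa -> kPa
    expect_lt(abs(got / groups$e_mean[g] - 1), 0.03)
  }
})

test_that("a written study reads back and analyses identically", {
  spec <- study_spec(groups = default_study_groups()[c(1, 4), ],
                     rheo_biological = 2, rheo_coupons = 1,
                     indent_biological = 2, indent_technical = 2,
                     image_biological = 1, image_fields = 1, seed = 12)
  st <- generate_study(spec)
  dir <- file.path(tempdir(), "study-roundtrip")
  unlink(dir, recursive = TRUE)
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))

  back <- read_study(dir)
  expect_equal(back$torque[[1]]$curve$torque, st$torque[[1]]$curve$torque,
               tolerance = 1e-12)
  id <- names(st$images)[1]
  expect_identical(back$images[[id]]$stack$channels$cells,
                   st$images[[id]]$stack$channels$cells)

  rep_mem <- run_pipeline(st)
  rep_dsk <- run_pipeline(dir)
  expect_equal(rep_dsk$rheometry$cf, rep_mem$rheometry$cf, tolerance = 1e-9)
  expect_equal(rep_dsk$indentation$E, rep_mem$indentation$E, tolerance = 1e-9)
  expect_equal(rep_dsk$imaging$biomass, rep_mem$imaging$biomass)
})
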