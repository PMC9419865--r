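# Synthetic-data generators: determinism, truth consistency, physical ranges

test_that("zero-noise force curve equals the forward model on the same grid", {
  p <- contact_params(E = 118.1, w = 0, K_m = 0, R = PROBE_R)
  cv <- gen_force_curve(p, z_range = 1, n_points = 200, noise_sd = 0,
                        drift_slope = 0, contact_offset = 0, seed = 1)
  z <- seq(0, 1, length.out = 200)
  expect_equal(cv$force[cv$segment == "approach"], composite_forward(z, p))
  # contact-regime force matches the Hertz closed form (w = 0, K_m = 0)
  app <- cv$force[cv$segment == "approach"]
  fh <- hertz_force(z * 1e-6, 118.1, 0.5, PROBE_R) * 1e9
  expect_equal(app, fh, tolerance = 1e-12)
})

test_that("every generator is bit-reproducible under its seed", {
  p <- contact_params(E = 100, w = 1e-5, K_m = 1e-4, R = PROBE_R)
  c1 <- gen_force_curve(p, noise_sd = 0.01, seed = 7)
  c2 <- gen_force_curve(p, noise_sd = 0.01, seed = 7)
  c3 <- gen_force_curve(p, noise_sd = 0.01, seed = 8)
  expect_identical(c1$force, c2$force)
  expect_false(identical(c1$force, c3$force))

  f1 <- gen_fiber_image(20, image_size = 128, seed = 3)
  f2 <- gen_fiber_image(20, image_size = 128, seed = 3)
  f3 <- gen_fiber_image(20, image_size = 128, seed = 4)
  expect_identical(f1$image, f2$image)
  expect_false(identical(f1$image, f3$image))

  m1 <- gen_monolayer_image(5, seed = 5)
  m2 <- gen_monolayer_image(5, seed = 5)
  expect_identical(m1$cell_channel, m2$cell_channel)

  h1 <- gen_height_map("gaussian_field", seed = 9)
  h2 <- gen_height_map("gaussian_field", seed = 9)
  expect_identical(h1$heights, h2$heights)

  w1 <- gen_wound_series(seed = 2, timepoints = c(0, 6))
  w2 <- gen_wound_series(seed = 2, timepoints = c(0, 6))
  expect_identical(w1$images, w2$images)
})

test_that("generators never leave the global RNG state disturbed", {
  set.seed(123); before <- .Random.seed
  invisible(gen_fiber_image(10, image_size = 64, seed = 1))
  invisible(gen_force_curve(contact_params(E = 100, R = PROBE_R), seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("single horizontal fiber renders at its nominal width", {
  img <- ribbon_image(64, 32, 32.5, 0, 10)
  mask <- img >= 0.5
  # width at mid-span
  expect_equal(sum(mask[, 32]), 10)
})

test_that("per-fiber truth reproduces the requested diameter distribution", {
  fb <- gen_fiber_image(400, diameter_mean = 622, diameter_sd = 31,
                        pixel_size = 50, image_size = 256, seed = 21)
  tr <- fb$ground_truth$per_object_truth
  expect_equal(mean(tr$diameter_nm), 622, tolerance = 31 / sqrt(400) * 4 / 622)
  expect_true(all(tr$diameter_nm > 0))
})

test_that("kappa = 0 orientations are circular-uniform (Monte-Carlo oracle)", {
  fb <- gen_fiber_image(10000, image_size = 8, pixel_size = 50,
                        diameter_mean = 622, seed = 31)
  th <- fb$ground_truth$per_object_truth$angle_rad
  resultant <- sqrt(mean(cos(2 * th))^2 + mean(sin(2 * th))^2)
  expect_lt(resultant, 3 / sqrt(10000) * 3)    # ~3 sigma of the null
})

test_that("monolayer truth carries exact analytic shape values", {
  m0 <- gen_monolayer_image(1, eccentricity_target = 0, seed = 1)
  expect_equal(m0$ground_truth$per_object_truth$eccentricity, 0)
  m1 <- gen_monolayer_image(4, eccentricity_target = 0.866, seed = 2)
  expect_equal(unique(m1$ground_truth$per_object_truth$eccentricity), 0.866)
  # axis ratio 2:1 gives e = sqrt(1 - 1/4)
  tr <- m1$ground_truth$per_object_truth
  expect_equal(tr$minor_um / tr$major_um, rep(sqrt(1 - 0.866^2), 4),
               tolerance = 1e-12)
})

test_that("two-group monolayer truth intensities hit the requested ratio", {
  m <- gen_monolayer_image(20, intensity_mean = c(0.68, 0.1),
                           intensity_cv = 0, seed = 3)
  tr <- m$ground_truth$per_object_truth
  r <- mean(tr$intensity[tr$group == 1]) / mean(tr$intensity[tr$group == 2])
  expect_equal(r, 6.8, tolerance = 1e-12)
})

test_that("monolayer packing failure raises a capacity error", {
  expect_error(gen_monolayer_image(50, mean_area = 400, image_size = 60,
                                   pixel_size = 0.5, seed = 1,
                                   max_tries = 200),
               "capacity")
})

test_that("height-map kinds have the advertised intrinsic roughness", {
  expect_equal(rq_roughness(gen_height_map("plane", tilt = c(0.2, -0.1))), 0,
               tolerance = 1e-12)
  hs <- gen_height_map("sinusoid", amplitude = 1, correlation_length = 2,
                       pixel_size = 0.1, map_size = 400)
  expect_equal(rq_roughness(hs), 1 / sqrt(2), tolerance = 0.01)
  # sample-SD oracle on the generated matrix
  hg <- gen_height_map("gaussian_field", amplitude = 0.5, seed = 4)
  expect_equal(sd(as.vector(hg$heights)), 0.5, tolerance = 1e-6)
  expect_equal(rq_roughness(hg), 0.5, tolerance = 0.01)
})

test_that("wound series truth follows the stated front kinematics", {
  ws <- gen_wound_series(initial_width = 200, front_velocity = 10,
                         timepoints = c(0, 5, 10, 12), seed = 1)
  tr <- ws$ground_truth$per_object_truth
  expect_equal(tr$fraction[1], 1)
  expect_equal(tr$width_um, c(200, 100, 0, 0))
  expect_equal(tr$fraction[3], 0)
  # closure within 18 h when the velocity is set from the initial width
  ws18 <- gen_wound_series(initial_width = 360, front_velocity = 10,
                           timepoints = seq(0, 24, 6), seed = 2)
  tr18 <- ws18$ground_truth$per_object_truth
  expect_equal(tr18$fraction[tr18$time_h == 18], 0)
  expect_error(gen_wound_series(timepoints = c(1, 2)), "start at 0")
  expect_error(gen_wound_series(front_velocity = -1), ">= 0")
})

test_that("generator parameter validation catches unresolvable fibers", {
  expect_error(gen_fiber_image(5, diameter_mean = 80, pixel_size = 50),
               "resolution")
})
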