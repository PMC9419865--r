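# Fiber segmentation, diameters, pores, orientation, roughness

test_that("segmentation recovers a noise-free synthetic mat (IoU >= 0.95)", {
  fb <- gen_fiber_image(40, image_size = 512, noise_sd = 0, seed = 2)
  truth <- fb$image >= 0.5
  mask <- segment_fibers(fb$image)
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.95)
})

test_that("blank images raise an empty-segmentation error", {
  expect_error(segment_fibers(matrix(0, 64, 64)), "empty segmentation")
})

test_that("contrast polarity flag makes segmentation polarity-symmetric", {
  fb <- gen_fiber_image(20, image_size = 256, noise_sd = 0, seed = 5)
  m1 <- segment_fibers(fb$image)
  m2 <- segment_fibers(max(fb$image) - fb$image,
                       config = list(polarity = "dark"))
  expect_identical(m1, m2)
})

test_that("a straight ribbon measures its constructed width within 1 px", {
  img <- ribbon_image(256, 128, 128.3, 0.2, 10)
  d <- fiber_diameters(img >= 0.5, pixel_size = 50)
  expect_lt(abs(d$mean / 50 - 10), 1)
})

test_that("crossing ribbons exclude junction samples and stay within 1 px", {
  img <- pmax(ribbon_image(256, 128, 128, 0.3, 10),
              ribbon_image(256, 128, 128, -0.9, 10))
  d <- fiber_diameters(img >= 0.5, pixel_size = 1)
  expect_gt(d$n_excluded, 0)
  expect_lt(abs(d$mean - 10), 1)
})

test_that("diameter estimate is invariant under 90-degree rotation", {
  fb <- gen_fiber_image(30, image_size = 256, noise_sd = 0, seed = 7)
  mask <- fb$image >= 0.5
  d1 <- fiber_diameters(mask, 50)
  d2 <- fiber_diameters(t(mask)[ncol(mask):1, ], 50)
  expect_lt(abs(d1$mean - d2$mean), 50)          # <= 1 px mean shift
})

test_that("an interior circular hole yields its equivalent diameter", {
  mask <- !disc_mask(128, 64, 64, 20)
  p <- pore_sizes(mask, pixel_size = 1000)       # 1 um/px
  expect_equal(p$n, 1L)
  expect_lt(abs(p$equivalent_diameters - 40), 1)
})

test_that("a mask without interior pores warns and returns empty", {
  mask <- matrix(FALSE, 32, 32); mask[, 10:20] <- TRUE
  expect_warning(p <- pore_sizes(mask, 50), "no interior pores")
  expect_equal(p$n, 0L)
  expect_error(pore_sizes(matrix(TRUE, 8, 8), 50), "no background")
})

test_that("mean pore size decreases with fiber density", {
  means <- vapply(c(30, 60, 120), function(nf) {
    fb <- gen_fiber_image(nf, image_size = 512, noise_sd = 0, seed = 11)
    pore_sizes(fb$image >= 0.5, fb$pixel_size)$mean
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("parallel stripes are near-perfectly anisotropic", {
  img <- matrix(rep(sin(2 * pi * (1:256) / 16), each = 256), 256)
  o <- orientation_anisotropy(img)
  expect_gte(o$anisotropy_S, 0.95)
})

test_that("an isotropic mat scores S <= 0.1", {
  fb <- gen_fiber_image(300, orientation_kappa = 0, image_size = 512,
                        seed = 13)
  o <- orientation_anisotropy(fb$image)
  expect_lte(o$anisotropy_S, 0.1)
})

test_that("anisotropy increases strictly with orientation concentration", {
  # sparse mats: heavy fiber coverage saturates the image and erases the
  # orientation signal regardless of kappa
  S <- vapply(c(0, 2, 8), function(kappa) {
    fb <- gen_fiber_image(40, orientation_kappa = kappa, image_size = 512,
                          seed = 17)
    orientation_anisotropy(fb$image)$anisotropy_S
  }, 0)
  expect_true(all(diff(S) > 0))
})

test_that("anisotropy is translation invariant and rotation equivariant", {
  img <- matrix(rep(sin(2 * pi * (1:256) / 16), each = 256), 256)
  o1 <- orientation_anisotropy(img)
  shifted <- img[, c(30:256, 1:29)]
  o2 <- orientation_anisotropy(shifted)
  expect_equal(o2$anisotropy_S, o1$anisotropy_S, tolerance = 1e-6)
  # transpose rotates the stripes by 90 degrees
  o3 <- orientation_anisotropy(t(img))
  expect_equal((o3$peak_angle_rad - o1$peak_angle_rad) %% pi, pi / 2,
               tolerance = 0.05)
  expect_error(orientation_anisotropy(img, annulus = c(1.45, 1.5)),
               "invalid annulus")
})

test_that("roughness is zero for planes and A/sqrt(2) for sinusoids", {
  hp <- gen_height_map("plane", tilt = c(0.3, -0.2))
  expect_lt(rq_roughness(hp), 1e-12)
  hs <- gen_height_map("sinusoid", amplitude = 2, correlation_length = 1,
                       pixel_size = 0.1, map_size = 300)
  expect_equal(rq_roughness(hs), 2 / sqrt(2), tolerance = 0.01)
})

test_that("Rq is invariant under adding any plane", {
  hg <- gen_height_map("gaussian_field", amplitude = 0.4, seed = 19)
  r1 <- rq_roughness(hg)
  n <- nrow(hg$heights)
  tilt <- outer(seq_len(n), seq_len(n), function(i, j) 0.01 * i - 0.02 * j + 3)
  expect_equal(rq_roughness(height_map(hg$heights + tilt, hg$pixel_size)),
               r1, tolerance = 1e-9)
})

test_that("maps generated at a 17-fold amplitude ratio give a 17-fold Rq", {
  h1 <- gen_height_map("gaussian_field", amplitude = 0.51, seed = 23)
  h2 <- gen_height_map("gaussian_field", amplitude = 0.03, seed = 24)
  expect_equal(rq_roughness(h1) / rq_roughness(h2), 17, tolerance = 0.05)
})
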