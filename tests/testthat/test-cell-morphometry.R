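# Nucleus/cell segmentation, shape features, spacing, heights, fold change

test_that("nucleus segmentation counts well-separated nuclei exactly", {
  m <- gen_monolayer_image(12, seed = 4)
  nuc <- segment_nuclei(m$nucleus_channel, pixel_size = m$pixel_size)
  expect_equal(length(setdiff(unique(as.vector(nuc$labels)), 0L)), 12)
})

test_that("two touching discs are split into two labels", {
  img <- matrix(0.05, 128, 128)
  img[disc_mask(128, 50, 64, 18)] <- 0.9
  img[disc_mask(128, 82, 64, 18)] <- 0.9
  nuc <- segment_nuclei(img)
  expect_equal(length(setdiff(unique(as.vector(nuc$labels)), 0L)), 2)
})

test_that("a blank nucleus channel raises an empty-segmentation error", {
  expect_error(segment_nuclei(matrix(0, 64, 64)), "empty segmentation")
})

test_that("seeded cell segmentation yields one cell per nucleus", {
  m <- gen_monolayer_image(15, seed = 6)
  nuc <- segment_nuclei(m$nucleus_channel, pixel_size = m$pixel_size)
  cells <- segment_cells(m$cell_channel, nuc)
  n_nuc <- length(setdiff(unique(as.vector(nuc$labels)), 0L))
  n_cell <- length(setdiff(unique(as.vector(cells$labels)), 0L))
  expect_equal(n_cell, n_nuc)
})

test_that("segmented cells overlap the truth labels (mean IoU >= 0.8)", {
  m <- gen_monolayer_image(15, noise_sd = 0, seed = 8)
  nuc <- segment_nuclei(m$nucleus_channel, pixel_size = m$pixel_size)
  cells <- segment_cells(m$cell_channel, nuc)
  tr <- m$cell_labels
  ious <- vapply(seq_len(15), function(i) {
    # match by the truth centroid's segmented label
    idx <- which(tr == i)
    lab <- as.vector(cells$labels)[idx]
    lab <- lab[lab > 0]
    if (!length(lab)) return(0)
    j <- as.integer(names(which.max(table(lab))))
    sum(tr == i & cells$labels == j) / sum(tr == i | cells$labels == j)
  }, 0)
  expect_gte(mean(ious), 0.8)
})

test_that("analytic shapes give their known feature values", {
  fd <- shape_features(label_image(disc_mask(201, 101, 101, 50) * 1L,
                                   1, "cell"))
  expect_lte(fd$eccentricity, 0.05)
  expect_gte(fd$compactness, 0.95)
  expect_lte(fd$compactness, 1.05)
  fe <- shape_features(label_image(
    ellipse_mask(301, 151, 151, 100, 50, 0.4) * 1L, 1, "cell"))
  expect_equal(fe$eccentricity, 0.866, tolerance = 0.02 / 0.866)
  g <- grid_xy(201)
  sq <- (g$x >= 51 & g$x <= 150 & g$y >= 51 & g$y <= 150) * 1L
  fs <- shape_features(label_image(sq, 1, "cell"))
  expect_equal(fs$compactness, pi / 4, tolerance = 0.03 / (pi / 4))
})

test_that("features obey the magnification scale law", {
  mask <- ellipse_mask(101, 51, 51, 30, 18, 0.7) * 1L
  big <- mask[rep(seq_len(101), each = 2), rep(seq_len(101), each = 2)]
  f1 <- shape_features(label_image(mask, 1, "cell"))
  f2 <- shape_features(label_image(big, 1, "cell"))
  expect_equal(f2$area / f1$area, 4, tolerance = 0.02)
  expect_equal(f2$perimeter / f1$perimeter, 2, tolerance = 0.03)
  expect_lt(abs(f2$eccentricity - f1$eccentricity), 0.03)
  expect_lt(abs(f2$compactness - f1$compactness), 0.03)
})

test_that("segmentation + features recover per-cell truth areas within 5%", {
  rel_err <- vapply(1:10, function(s) {
    m <- gen_monolayer_image(8, noise_sd = 0, seed = 100 + s)
    nuc <- segment_nuclei(m$nucleus_channel, pixel_size = m$pixel_size)
    cells <- segment_cells(m$cell_channel, nuc)
    f <- shape_features(cells)
    tr <- m$ground_truth$per_object_truth
    # match segmented objects to truth by centroid proximity
    err <- vapply(seq_len(nrow(f)), function(i) {
      j <- which.min((tr$centroid_x_um - f$centroid_x[i])^2 +
                     (tr$centroid_y_um - f$centroid_y[i])^2)
      abs(f$area[i] - tr$area_um2[j]) / tr$area_um2[j]
    }, 0)
    mean(err)
  }, 0)
  expect_lt(max(rel_err), 0.05)
})

test_that("nucleus matching produces per-cell nucleus areas and nc ratio", {
  m <- gen_monolayer_image(10, noise_sd = 0, seed = 9, nucleus_frac = 0.25)
  nuc <- segment_nuclei(m$nucleus_channel, pixel_size = m$pixel_size)
  cells <- segment_cells(m$cell_channel, nuc)
  f <- shape_features(cells, nuclei = nuc)
  expect_true(all(is.finite(f$nucleus_area)))
  expect_equal(mean(f$nc_ratio), 0.25, tolerance = 0.15)
})

test_that("internuclear distances reproduce constructed geometry", {
  d <- internuclear_distances(rbind(c(0, 0), c(3, 4)))
  expect_equal(unname(d$distances), c(5, 5))
  grid_pts <- as.matrix(expand.grid(x = seq(0, 30, 10), y = seq(0, 30, 10)))
  dg <- internuclear_distances(grid_pts)
  expect_true(all(dg$distances == 10))
  expect_error(internuclear_distances(rbind(c(0, 0))), "insufficient")
})

test_that("internuclear distances are rigid-motion invariant", {
  set.seed(42)
  pts <- matrix(runif(20, 0, 100), ncol = 2)
  d0 <- internuclear_distances(pts)$distances
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  d1 <- internuclear_distances(pts %*% Rm + 13.7)$distances
  expect_equal(sort(d1), sort(d0), tolerance = 1e-9)
})

test_that("cell height measures a synthetic dome apex", {
  n <- 200
  g <- grid_xy(n)
  r2 <- ((g$x - 100)^2 + (g$y - 100)^2) / 70^2
  dome <- pmax(10 * (1 - r2), 0)
  expect_equal(cell_height(height_map(dome, 0.1)), 10, tolerance = 0.02)
  expect_equal(cell_height(height_map(matrix(2.5, 50, 50), 0.1)), 0)
})

test_that("height ratio of two generated maps matches the apex ratio", {
  mk <- function(apex) {
    g <- grid_xy(160)
    pmax(apex * (1 - ((g$x - 80)^2 + (g$y - 80)^2) / 60^2), 0)
  }
  r <- cell_height(height_map(mk(15.56), 0.1)) /
    cell_height(height_map(mk(8.99), 0.1))
  expect_equal(r, 15.56 / 8.99, tolerance = 0.05)
})

test_that("z-stack occupancy height uses slice spacing", {
  occ <- array(FALSE, dim = c(4, 4, 10))
  occ[2, 2, 1:6] <- TRUE
  expect_equal(cell_height_zstack(occ, slice_spacing = 0.5), 2.5)
})

test_that("fold change has exact limits and bootstrap CI coverage", {
  a <- c(1, 2, 3, 4)
  expect_equal(fold_change(a, a, n_boot = 100)$ratio, 1)
  fc <- fold_change(a, 2 * a, n_boot = 100)
  expect_equal(fc$ratio, 0.5)
  expect_equal(fold_change(2 * a, a, n_boot = 50)$ratio,
               1 / fold_change(a, 2 * a, n_boot = 50)$ratio)
  expect_error(fold_change(a, rep(0, 4)), "undefined ratio")
  expect_error(fold_change(numeric(0), a), "non-empty")
})

test_that("synthetic groups at a 6.8 ratio are estimated within 10%", {
  rng <- nanomech:::.local_rng(77)
  s2 <- log(1 + 0.1^2)
  a <- 0.68 * rng$rlnorm(30, -s2 / 2, sqrt(s2))
  b <- 0.10 * rng$rlnorm(30, -s2 / 2, sqrt(s2))
  fc <- fold_change(a, b, seed = 1)
  expect_equal(fc$ratio, 6.8, tolerance = 0.10)
  expect_true(fc$ci[1] < fc$ratio && fc$ratio < fc$ci[2])
})
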