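#' Height map container
#'
#' @param heights 2D numeric matrix of heights (um).
#' @param pixel_size Lateral pixel size (um/px).
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size) {
  if (!is.matrix(heights) || !all(is.finite(heights)))
    stop("heights must be a finite numeric matrix")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(heights = heights, pixel_size = pixel_size),
            class = "height_map")
}

# axial von Mises sampler (Best & Fisher): angles theta in (-pi/2, pi/2],
# concentration kappa applies to the doubled angles; kappa = 0 is uniform.
.r_axial_angles <- function(rng, n, kappa) {
  if (kappa <= 0) return(rng$runif(n, -pi / 2, pi / 2))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- rng$runif(3)
    zz <- cos(pi * u[1])
    ff <- (1 + r * zz) / (r + zz)
    cc <- kappa * (r - ff)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(ff)
      i <- i + 1
    }
  }
  out / 2
}

#' Generate a synthetic random fiber mat image
#'
#' Renders `n_fibers` straight fibers (full-image chords) with normally
#' distributed widths and axially von Mises distributed orientations, with
#' anti-aliased edges, fiber-over-fiber occlusion (max blending) and
#' additive Gaussian grey noise. Per-fiber true diameter and angle are
#' stored in the ground truth.
#'
#' @param n_fibers Number of fibers.
#' @param diameter_mean,diameter_sd Normal width distribution (nm); the mean
#'   must exceed 2x the pixel size so fibers are resolvable.
#' @param orientation_kappa Axial concentration (0 = uniform orientation).
#' @param pixel_size nm per pixel.
#' @param image_size Image side (px); square images.
#' @param noise_sd Additive Gaussian noise SD (grey units; fibers render at
#'   1, background at 0).
#' @param seed Integer seed.
#' @return List with `image` (matrix, rows = y), `pixel_size` and
#'   `ground_truth` (per-fiber truth columns: `diameter_nm`, `angle_rad`).
#' @export
gen_fiber_image <- function(n_fibers, diameter_mean = 622, diameter_sd = 31,
                            orientation_kappa = 0, pixel_size = 50,
                            image_size = 1024, noise_sd = 0.02, seed = 1) {
  if (diameter_mean <= 2 * pixel_size)
    stop("resolution error: diameter_mean must exceed 2 * pixel_size")
  rng <- .local_rng(seed)
  d_nm <- rng$rnorm(n_fibers, diameter_mean, diameter_sd)
  d_nm <- pmax(d_nm, 2 * pixel_size + 1e-9)
  theta <- .r_axial_angles(rng, n_fibers, orientation_kappa)
  x0 <- rng$runif(n_fibers, 1, image_size)
  y0 <- rng$runif(n_fibers, 1, image_size)
  xg <- matrix(rep(seq_len(image_size), each = image_size),
               nrow = image_size)               # column index
  yg <- matrix(rep(seq_len(image_size), times = image_size),
               nrow = image_size)               # row index
  img <- matrix(0, image_size, image_size)
  hw_px <- d_nm / pixel_size / 2
  for (i in seq_len(n_fibers)) {
    s <- sin(theta[i]); cs <- cos(theta[i])
    dist <- abs((xg - x0[i]) * s - (yg - y0[i]) * cs)
    img <- pmax(img, pmin(pmax(hw_px[i] + 0.5 - dist, 0), 1))
  }
  if (noise_sd > 0)
    img <- img + matrix(rng$rnorm(image_size^2, sd = noise_sd),
                        image_size, image_size)
  truth <- data.frame(fiber = seq_len(n_fibers), diameter_nm = d_nm,
                      angle_rad = theta, x0 = x0, y0 = y0)
  list(image = img, pixel_size = pixel_size,
       ground_truth = ground_truth("fiber_image",
         parameters = list(n_fibers = n_fibers, diameter_mean = diameter_mean,
                           diameter_sd = diameter_sd,
                           orientation_kappa = orientation_kappa,
                           pixel_size = pixel_size, image_size = image_size,
                           noise_sd = noise_sd),
         seed = seed, per_object_truth = truth))
}

#' Generate a synthetic two-channel cell monolayer image
#'
#' Non-overlapping elliptical cells (channel 2) each containing a concentric
#' elliptical nucleus (channel 1), placed by minimum-distance rejection
#' sampling. Ellipses give closed-form truth for area, eccentricity and
#' centroid. Per-cell mean intensity is the group mean times an optional
#' lognormal factor.
#'
#' @param n_cells Number of cells (>= 1).
#' @param mean_area Mean cell area (um^2); per-cell areas vary by `area_cv`.
#' @param eccentricity_target Ellipse eccentricity of every cell (0 = circle).
#' @param intensity_mean Vector of per-group mean grey values; cells are
#'   assigned to groups round-robin.
#' @param intensity_cv Lognormal coefficient of variation of per-cell
#'   intensity (0 = exact group means).
#' @param area_cv Normal CV of per-cell area.
#' @param nucleus_frac Nucleus area as a fraction of cell area.
#' @param pixel_size um per pixel.
#' @param image_size Image side (px); `NULL` picks a side giving ~4x the
#'   total cell area.
#' @param noise_sd Additive Gaussian noise SD on both channels.
#' @param seed Integer seed.
#' @param max_tries Total placement attempts before a capacity error.
#' @return List with `nucleus_channel`, `cell_channel` (matrices),
#'   `cell_labels`, `nucleus_labels` (integer matrices), `pixel_size` and
#'   `ground_truth` whose per-object table holds per-cell truth.
#' @export
gen_monolayer_image <- function(n_cells, mean_area = 400,
                                eccentricity_target = 0.5,
                                intensity_mean = 0.6, intensity_cv = 0,
                                area_cv = 0.1, nucleus_frac = 0.25,
                                pixel_size = 0.5, image_size = NULL,
                                noise_sd = 0.01, seed = 1,
                                max_tries = 200 * n_cells) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  rng <- .local_rng(seed)
  areas <- pmax(rng$rnorm(n_cells, mean_area, area_cv * mean_area),
                0.2 * mean_area)
  q <- sqrt(1 - eccentricity_target^2)           # minor/major axis ratio
  a_um <- sqrt(areas / (pi * q)); b_um <- q * a_um
  phi <- rng$runif(n_cells, 0, pi)
  if (is.null(image_size))   # packing treats cells as circles of the major
    image_size <- ceiling(sqrt(4 * sum(areas) / q) / pixel_size)  # radius
  L_um <- image_size * pixel_size
  cx <- cy <- numeric(n_cells)
  placed <- 0; tries <- 0
  while (placed < n_cells) {
    tries <- tries + 1
    if (tries > max_tries)
      stop(sprintf(paste0("packing capacity exceeded after %d tries: reduce",
                          " n_cells (%d) or mean_area (%.0f um^2)"),
                   tries - 1, n_cells, mean_area))
    i <- placed + 1
    p <- rng$runif(2, a_um[i] + pixel_size, L_um - a_um[i] - pixel_size)
    ok <- TRUE
    if (placed > 0) {
      dd <- sqrt((cx[seq_len(placed)] - p[1])^2 +
                 (cy[seq_len(placed)] - p[2])^2)
      ok <- all(dd >= a_um[seq_len(placed)] + a_um[i] + pixel_size)
    }
    if (ok) { cx[i] <- p[1]; cy[i] <- p[2]; placed <- i }
  }
  g <- rep(seq_along(intensity_mean), length.out = n_cells)
  I <- intensity_mean[g]
  if (intensity_cv > 0) {
    s2 <- log(1 + intensity_cv^2)
    I <- I * rng$rlnorm(n_cells, meanlog = -s2 / 2, sdlog = sqrt(s2))
  }
  cell_lab <- nuc_lab <- matrix(0L, image_size, image_size)
  nf <- sqrt(nucleus_frac)
  for (i in seq_len(n_cells)) {
    for (nucleus in c(FALSE, TRUE)) {
      aa <- if (nucleus) a_um[i] * nf else a_um[i]
      bb <- if (nucleus) b_um[i] * nf else b_um[i]
      r0 <- max(1L, floor((cy[i] - aa) / pixel_size))
      r1 <- min(image_size, ceiling((cy[i] + aa) / pixel_size) + 1L)
      c0 <- max(1L, floor((cx[i] - aa) / pixel_size))
      c1 <- min(image_size, ceiling((cx[i] + aa) / pixel_size) + 1L)
      rows <- r0:r1; cols <- c0:c1
      xx <- (matrix(rep(cols, each = length(rows)),
                    nrow = length(rows)) - 0.5) * pixel_size - cx[i]
      yy <- (matrix(rep(rows, times = length(cols)),
                    nrow = length(rows)) - 0.5) * pixel_size - cy[i]
      u <- xx * cos(phi[i]) + yy * sin(phi[i])
      v <- -xx * sin(phi[i]) + yy * cos(phi[i])
      inside <- (u / aa)^2 + (v / bb)^2 <= 1
      tgt <- if (nucleus) "nuc_lab" else "cell_lab"
      m <- get(tgt)
      sub <- m[rows, cols]; sub[inside] <- i
      m[rows, cols] <- sub
      assign(tgt, m)
    }
  }
  nuc_ch <- 0.1 + 0.7 * (nuc_lab > 0)
  cell_ch <- matrix(0.05, image_size, image_size)
  cell_ch[cell_lab > 0] <- I[cell_lab[cell_lab > 0]]
  if (noise_sd > 0) {
    nuc_ch <- nuc_ch + matrix(rng$rnorm(image_size^2, sd = noise_sd),
                              image_size, image_size)
    cell_ch <- cell_ch + matrix(rng$rnorm(image_size^2, sd = noise_sd),
                                image_size, image_size)
  }
  truth <- data.frame(cell = seq_len(n_cells), group = g,
                      area_um2 = areas,
                      area_px = as.vector(table(factor(cell_lab[cell_lab > 0],
                                                       seq_len(n_cells)))),
                      eccentricity = eccentricity_target,
                      centroid_x_um = cx, centroid_y_um = cy,
                      nucleus_area_um2 = areas * nucleus_frac,
                      intensity = I, major_um = a_um, minor_um = b_um,
                      angle = phi)
  list(nucleus_channel = nuc_ch, cell_channel = cell_ch,
       cell_labels = cell_lab, nucleus_labels = nuc_lab,
       pixel_size = pixel_size,
       ground_truth = ground_truth("monolayer_image",
         parameters = list(n_cells = n_cells, mean_area = mean_area,
                           eccentricity_target = eccentricity_target,
                           intensity_mean = intensity_mean,
                           intensity_cv = intensity_cv, area_cv = area_cv,
                           nucleus_frac = nucleus_frac,
                           pixel_size = pixel_size, image_size = image_size,
                           noise_sd = noise_sd),
         seed = seed, per_object_truth = truth))
}

#' Generate a synthetic AFM-like height map
#'
#' `plane`: tilted plane of zero intrinsic roughness. `sinusoid`:
#' \eqn{h = A \sin(2\pi x / \lambda)} along one axis (Rq = A/sqrt(2) over
#' many periods). `gaussian_field`: Gaussian white noise smoothed to the
#' requested correlation length and rescaled so the height SD equals
#' `amplitude`.
#'
#' @param kind `"plane"`, `"sinusoid"` or `"gaussian_field"`.
#' @param amplitude Height amplitude / SD (um), >= 0.
#' @param correlation_length Sinusoid period or smoothing length (um).
#' @param pixel_size um per pixel.
#' @param map_size Side length (px).
#' @param tilt Plane slopes (um height per um lateral), length 2.
#' @param seed Integer seed.
#' @return A [height_map] with attribute `ground_truth` (carries `rq_true`).
#' @export
gen_height_map <- function(kind = c("plane", "sinusoid", "gaussian_field"),
                           amplitude = 0.5, correlation_length = 2,
                           pixel_size = 0.1, map_size = 256,
                           tilt = c(0.05, -0.02), seed = 1) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("amplitude must be >= 0")
  x_um <- (seq_len(map_size) - 0.5) * pixel_size
  h <- switch(kind,
    plane = outer(x_um, x_um, function(y, x) tilt[1] * x + tilt[2] * y),
    sinusoid = matrix(rep(amplitude * sin(2 * pi * x_um / correlation_length),
                          each = map_size), nrow = map_size),
    gaussian_field = {
      rng <- .local_rng(seed)
      m <- matrix(rng$rnorm(map_size^2), map_size, map_size)
      sig_px <- correlation_length / pixel_size
      if (sig_px > 0.3)
        m <- .gaussian_smooth(m, sig_px)
      # remove the LS plane before scaling so the height SD (and hence the
      # plane-removed Rq) equals the requested amplitude
      X <- cbind(1, rep(seq_len(map_size), each = map_size),
                 rep(seq_len(map_size), times = map_size))
      m <- matrix(stats::lm.fit(X, as.vector(m))$residuals,
                  map_size, map_size)
      m / stats::sd(as.vector(m)) * amplitude
    })
  rq_true <- switch(kind, plane = 0, sinusoid = amplitude / sqrt(2),
                    gaussian_field = amplitude)
  hm <- height_map(h, pixel_size)
  attr(hm, "ground_truth") <- ground_truth("height_map",
    parameters = list(kind = kind, amplitude = amplitude,
                      correlation_length = correlation_length,
                      pixel_size = pixel_size, map_size = map_size,
                      tilt = tilt, rq_true = rq_true),
    seed = seed)
  hm
}

.gaussian_smooth <- function(m, sigma_px) {
  k_half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-k_half, k_half), sd = sigma_px)
  k2 <- outer(k, k); k2 <- k2 / sum(k2)
  as.matrix(EBImage::filter2(EBImage::Image(m), k2, boundary = "circular"))
}

#' Generate a synthetic scratch-wound time series
#'
#' Cell regions render as high-variance Gaussian texture, the wound as a
#' low-variance vertical band whose width shrinks by `2 * front_velocity *
#' t` (two advancing fronts). True wound area and fraction per timepoint are
#' stored in the ground truth.
#'
#' @param initial_width Wound width at t = 0 (um).
#' @param front_velocity Per-front closure speed (um/h), >= 0.
#' @param timepoints Hours, ascending, first must be 0.
#' @param pixel_size um per pixel.
#' @param image_size Rows, cols of each frame (px); the wound runs along
#'   rows (scratch axis = 1).
#' @param texture_sd_cell,texture_sd_wound Grey-noise SD in the cell and
#'   wound regions.
#' @param replicates Independent images per timepoint (averaged downstream).
#' @param seed Integer seed.
#' @return A `wound_series`: `timepoints`, `images` (list; each element is a
#'   list of replicate matrices), `pixel_size`, `scratch_axis`, plus
#'   `ground_truth` with per-timepoint truth.
#' @export
gen_wound_series <- function(initial_width = 300, front_velocity = 10,
                             timepoints = seq(0, 24, 6), pixel_size = 2,
                             image_size = c(256, 256),
                             texture_sd_cell = 0.15,
                             texture_sd_wound = 0.015,
                             replicates = 1, seed = 1) {
  if (front_velocity < 0) stop("front_velocity must be >= 0")
  if (is.unsorted(timepoints) || timepoints[1] != 0)
    stop("timepoints must be ascending and start at 0")
  rng <- .local_rng(seed)
  nr <- image_size[1]; nc <- image_size[2]
  x_um <- (seq_len(nc) - 0.5) * pixel_size
  cx <- nc * pixel_size / 2
  images <- vector("list", length(timepoints))
  truth <- data.frame(time_h = timepoints, width_um = NA_real_,
                      area_um2 = NA_real_, fraction = NA_real_)
  area0 <- NA_real_
  for (k in seq_along(timepoints)) {
    wk <- max(0, initial_width - 2 * front_velocity * timepoints[k])
    wound_cols <- abs(x_um - cx) < wk / 2
    reps <- lapply(seq_len(replicates), function(r) {
      img <- 0.5 + matrix(rng$rnorm(nr * nc, sd = texture_sd_cell), nr, nc)
      if (any(wound_cols))
        img[, wound_cols] <- 0.5 + rng$rnorm(nr * sum(wound_cols),
                                             sd = texture_sd_wound)
      img
    })
    images[[k]] <- reps
    area_k <- sum(wound_cols) * pixel_size * nr * pixel_size
    if (k == 1) {
      if (area_k <= 0) stop("initial wound width must cover >= 1 pixel")
      area0 <- area_k
    }
    truth$width_um[k] <- wk
    truth$area_um2[k] <- area_k
    truth$fraction[k] <- area_k / area0
  }
  structure(list(timepoints = timepoints, images = images,
                 pixel_size = pixel_size, scratch_axis = 1,
                 ground_truth = ground_truth("wound_series",
                   parameters = list(initial_width = initial_width,
                                     front_velocity = front_velocity,
                                     pixel_size = pixel_size,
                                     image_size = image_size,
                                     texture_sd_cell = texture_sd_cell,
                                     texture_sd_wound = texture_sd_wound,
                                     replicates = replicates),
                   seed = seed, per_object_truth = truth)),
            class = "wound_series")
}
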