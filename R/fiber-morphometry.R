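#' Segment fibers from a grey-scale image
#'
#' Adaptive (local-mean) thresholding, small-object removal and a small
#' morphological closing. Set `config$polarity = "dark"` for images where
#' fibers are darker than the background.
#'
#' @param image Numeric matrix (single channel).
#' @param config Optional list: `polarity` ("bright"/"dark"), `window`
#'   (adaptive window half-size px, default 15), `offset` (threshold offset,
#'   default 0.02), `min_area` (px, default 20), `close_size` (brush size
#'   for hole closing, default 3).
#' @return Logical matrix, `TRUE` = fiber.
#' @export
segment_fibers <- function(image, config = list()) {
  if (!is.matrix(image)) stop("image must be a single-channel matrix")
  if ((config$polarity %||% "bright") == "dark") image <- max(image) - image
  w <- config$window %||% 15
  off <- config$offset %||% 0.02
  x <- EBImage::Image(image)
  mask <- EBImage::thresh(x, w = w, h = w, offset = off)
  cs <- config$close_size %||% 3
  mask <- EBImage::closing(mask, EBImage::makeBrush(cs, shape = "box"))
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= (config$min_area %||% 20))
  out <- matrix(as.integer(lab) %in% keep, nrow = nrow(image))
  if (!any(out)) stop("empty segmentation: no fiber foreground found")
  out
}

#' Fiber diameter distribution from a binary mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning), computes the Euclidean
#' distance transform, and samples the local fiber diameter as `2 * EDT` at
#' every skeleton pixel, excluding pixels within one local radius of
#' skeleton branch points (fiber crossings). No sub-pixel correction is
#' applied: the discretization bias of 2*EDT is orientation dependent
#' (about +0.5 px for axis-aligned ribbons, about -0.2 px for diagonal
#' ones) and averages out over randomly oriented fibers.
#'
#' @param mask Logical matrix from [segment_fibers].
#' @param pixel_size nm per pixel.
#' @param exclusion_factor Multiplier on the local radius used for the
#'   branch-point exclusion zone (default 1).
#' @return List: `diameters` (nm, one per retained skeleton pixel), `mean`,
#'   `sd`, `n`, `n_excluded`.
#' @export
fiber_diameters <- function(mask, pixel_size, exclusion_factor = 1) {
  if (!any(mask)) stop("empty mask")
  skel <- thin_zhang_suen(matrix(as.integer(mask), nrow = nrow(mask)))
  if (!any(skel > 0)) stop("degenerate geometry: skeleton is empty")
  edt <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  xn <- skeleton_crossing_number(skel)
  branch <- xn >= 3
  sk_idx <- which(skel > 0)
  r_local <- edt[sk_idx]
  if (any(branch)) {
    d_branch <- as.matrix(EBImage::distmap(EBImage::Image(1 - branch * 1)))
    keep <- d_branch[sk_idx] > exclusion_factor * (r_local + 1)
  } else keep <- rep(TRUE, length(sk_idx))
  d_px <- 2 * r_local[keep]
  diam <- d_px * pixel_size
  list(diameters = diam, mean = mean(diam), sd = stats::sd(diam),
       n = length(diam), n_excluded = sum(!keep))
}

#' Pore-size distribution from a binary fiber mask
#'
#' Connected components of the background are taken as projected pores;
#' components touching the image border are excluded. Equivalent diameter
#' is \eqn{2\sqrt{A/\pi}}.
#'
#' @param mask Logical matrix, `TRUE` = fiber.
#' @param pixel_size nm per pixel.
#' @return List: `equivalent_diameters` (um), `mean`, `sd`, `n`. Empty with
#'   a warning when every background component touches the border.
#' @export
pore_sizes <- function(mask, pixel_size) {
  if (all(mask)) stop("mask has no background")
  lab <- EBImage::bwlabel(EBImage::Image((!mask) * 1))
  lab <- as.matrix(lab)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  sizes <- tabulate(lab[lab > 0])
  keep <- setdiff(which(sizes > 0), border)
  if (!length(keep)) {
    warning("no interior pores: all background components touch the border")
    return(list(equivalent_diameters = numeric(0), mean = NA_real_,
                sd = NA_real_, n = 0L))
  }
  d_um <- 2 * sqrt(sizes[keep] / pi) * pixel_size / 1000
  list(equivalent_diameters = d_um, mean = mean(d_um), sd = stats::sd(d_um),
       n = length(d_um))
}

#' Orientation anisotropy by 2D FFT
#'
#' A Hann window is applied, the 2D power spectrum computed, and power
#' integrated over an annulus of spatial frequencies into 180 angular bins.
#' Spectrum angles are rotated by 90 degrees to real-space fiber
#' orientation. The anisotropy order parameter S is the resultant length of
#' the power-weighted doubled-angle mean vector: 0 for isotropic mats, 1
#' for perfectly aligned fibers.
#'
#' @param image Numeric matrix.
#' @param annulus Inner/outer annulus radii as fractions of the Nyquist
#'   frequency (default c(0.1, 0.9)).
#' @param n_bins Number of angular bins over \[0, pi).
#' @return List: `angular_power` (data.frame angle_rad/power),
#'   `anisotropy_S`, `peak_angle_rad`.
#' @export
orientation_anisotropy <- function(image, annulus = c(0.1, 0.9),
                                   n_bins = 180) {
  if (!is.matrix(image)) stop("image must be a single-channel matrix")
  nr <- nrow(image); nc <- ncol(image)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  wimg <- (image - mean(image)) * outer(hann(nr), hann(nc))
  P <- Mod(stats::fft(wimg))^2
  fy <- (seq_len(nr) - 1) / nr; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (seq_len(nc) - 1) / nc; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  FY <- matrix(rep(fy, times = nc), nr, nc)
  FX <- matrix(rep(fx, each = nr), nr, nc)
  r <- sqrt(FX^2 + FY^2)
  sel <- r >= annulus[1] * 0.5 & r <= annulus[2] * 0.5
  if (!any(sel) || sum(P[sel]) <= 0)
    stop("invalid annulus: no spectral power inside the annulus")
  # spectral angle is perpendicular to the real-space fiber axis
  theta <- (atan2(FY[sel], FX[sel]) + pi / 2) %% pi
  p <- P[sel]
  bins <- floor(theta / pi * n_bins) + 1
  bins[bins > n_bins] <- n_bins
  pow <- vapply(seq_len(n_bins), function(b) sum(p[bins == b]), 0)
  centers <- (seq_len(n_bins) - 0.5) * pi / n_bins
  zc <- sum(p * cos(2 * theta)); zs <- sum(p * sin(2 * theta))
  S <- sqrt(zc^2 + zs^2) / sum(p)
  list(angular_power = data.frame(angle_rad = centers, power = pow),
       anisotropy_S = S,
       peak_angle_rad = (atan2(zs, zc) / 2) %% pi)
}

#' RMS roughness after plane removal
#'
#' Fits a least-squares plane to the height map and returns the
#' root-mean-square of the residual heights (the Rq / RMSD roughness).
#'
#' @param hm A [height_map] (or plain matrix, then `pixel_size` is taken
#'   as 1).
#' @return Rq in the height unit of the map (um).
#' @export
rq_roughness <- function(hm) {
  h <- if (inherits(hm, "height_map")) hm$heights else hm
  if (nrow(h) < 3 || ncol(h) < 3) stop("height map must be at least 3x3")
  nr <- nrow(h); nc <- ncol(h)
  X <- cbind(1, rep(seq_len(nc), each = nr), rep(seq_len(nr), times = nc))
  res <- stats::lm.fit(X, as.vector(h))$residuals
  sqrt(mean(res^2))
}
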