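#' Labelled segmentation mask
#'
#' @param labels Integer matrix, 0 = background, objects numbered from 1.
#' @param pixel_size um per pixel.
#' @param channel Channel of origin, `"nucleus"` or `"cell"`.
#' @return An object of class `label_image`.
#' @export
label_image <- function(labels, pixel_size = 1,
                        channel = c("nucleus", "cell")) {
  channel <- match.arg(channel)
  if (any(labels < 0)) stop("labels must be non-negative")
  structure(list(labels = matrix(as.integer(labels), nrow = nrow(labels)),
                 pixel_size = pixel_size, channel = channel),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("Label image (%s channel): %d objects, %dx%d px at %.3g um/px\n",
              x$channel, length(setdiff(unique(as.vector(x$labels)), 0L)),
              nrow(x$labels), ncol(x$labels), x$pixel_size))
  invisible(x)
}

#' Segment nuclei from a DAPI-like channel
#'
#' Gaussian smoothing, global Otsu threshold, distance-transform watershed
#' to split touching nuclei, and a minimum-area filter.
#'
#' @param nucleus_channel Numeric matrix.
#' @param config Optional list: `sigma` (blur SD px, default 2), `min_area`
#'   (px, default 30), `tolerance` (watershed tolerance, default 1),
#'   `threshold` (absolute grey threshold overriding Otsu).
#' @param pixel_size um per pixel, stamped on the result.
#' @return A [label_image] (nucleus channel).
#' @export
segment_nuclei <- function(nucleus_channel, config = list(), pixel_size = 1) {
  x <- .normalize01(nucleus_channel)
  xs <- as.matrix(EBImage::gblur(EBImage::Image(x),
                                 sigma = config$sigma %||% 2))
  thr <- config$threshold %||% EBImage::otsu(EBImage::Image(xs))
  mask <- xs > thr
  if (!any(mask)) stop("empty segmentation: no nuclei found")
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = config$tolerance %||% 1)
  lab <- as.matrix(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= (config$min_area %||% 30))
  lab[!(lab %in% keep)] <- 0L
  if (!any(lab > 0)) stop("empty segmentation: no nuclei above minimum area")
  lab <- .relabel(lab)
  label_image(lab, pixel_size, "nucleus")
}

#' Segment cells by nucleus-seeded propagation
#'
#' Voronoi-like propagation (EBImage::propagate) of the nucleus seeds over
#' the smoothed cell channel, constrained to the foreground mask, giving
#' exactly one cell per seed. Nuclei falling outside the cell foreground
#' are dropped with a warning.
#'
#' @param cell_channel Numeric matrix (e.g. F-actin).
#' @param nuclei A [label_image] of nucleus seeds.
#' @param config Optional list: `sigma` (default 2), `threshold` (absolute
#'   foreground threshold overriding Otsu), `lambda` (propagate
#'   regularization, default 1e-4).
#' @return A [label_image] (cell channel) with labels matching the seeds.
#' @export
segment_cells <- function(cell_channel, nuclei, config = list()) {
  stopifnot(inherits(nuclei, "label_image"))
  x <- .normalize01(cell_channel)
  xs <- as.matrix(EBImage::gblur(EBImage::Image(x),
                                 sigma = config$sigma %||% 2))
  thr <- config$threshold %||% EBImage::otsu(EBImage::Image(xs))
  fg <- xs > thr
  seeds <- nuclei$labels
  fg <- fg | seeds > 0
  lab <- EBImage::propagate(EBImage::Image(xs), EBImage::Image(seeds),
                            mask = fg, lambda = config$lambda %||% 1e-4)
  lab <- as.matrix(lab)
  seed_ids <- setdiff(unique(as.vector(seeds)), 0L)
  got <- setdiff(unique(as.vector(lab)), 0L)
  lost <- setdiff(seed_ids, got)
  if (length(lost))
    warning(length(lost), " nuclei outside the cell foreground were dropped")
  label_image(lab, nuclei$pixel_size, "cell")
}

#' Per-object shape and intensity features
#'
#' Computes, per labelled object: area, perimeter (polygon length through
#' every 4th traced contour point, accurate for both smooth and polygonal
#' digital shapes), eccentricity from the second-moment ellipse
#' (\eqn{e = \sqrt{1 - (\lambda_{minor}/\lambda_{major})^2}}-convention on
#' axis lengths), compactness (circularity \eqn{4\pi A/P^2}, 1 = circle),
#' equivalent diameter, centroid, mean grey value, and - when a nucleus
#' label image is supplied - the matched nucleus area and
#' nucleus:cell area ratio (matched by nucleus-centroid containment).
#'
#' @param labels A [label_image] (or plain integer matrix).
#' @param intensity_image Optional numeric matrix for `mean_grey`.
#' @param nuclei Optional nucleus [label_image] for `nucleus_area`/`nc_ratio`.
#' @param pixel_size um per pixel (taken from `labels` when it is a
#'   [label_image]).
#' @return data.frame, one row per object; `compactness_reliable` is FALSE
#'   for objects of fewer than 5 pixels.
#' @export
shape_features <- function(labels, intensity_image = NULL, nuclei = NULL,
                           pixel_size = NULL) {
  if (inherits(labels, "label_image")) {
    pixel_size <- pixel_size %||% labels$pixel_size
    labels <- labels$labels
  }
  pixel_size <- pixel_size %||% 1
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (!length(ids)) stop("no objects in label image")
  nr <- nrow(labels)
  idx_by_id <- split(which(labels > 0), labels[labels > 0])
  contours <- EBImage::ocontour(EBImage::Image(labels))
  out <- do.call(rbind, lapply(ids, function(i) {
    idx <- idx_by_id[[as.character(i)]]
    r <- (idx - 1) %% nr + 1
    cc <- (idx - 1) %/% nr + 1
    A <- length(idx)
    cen_r <- mean(r); cen_c <- mean(cc)
    mrr <- mean((r - cen_r)^2) + 1 / 12   # pixel-patch second moment
    mcc <- mean((cc - cen_c)^2) + 1 / 12
    mrc <- mean((r - cen_r) * (cc - cen_c))
    tr <- mrr + mcc; det2 <- sqrt(max((mrr - mcc)^2 + 4 * mrc^2, 0))
    l_maj <- (tr + det2) / 2; l_min <- (tr - det2) / 2
    ecc <- if (l_maj > 0) sqrt(max(0, 1 - l_min / l_maj)) else 0
    P <- .contour_perimeter(contours[[i]])
    comp <- if (P > 0) 4 * pi * A / P^2 else NA_real_
    data.frame(object_id = i,
               area = A * pixel_size^2,
               perimeter = P * pixel_size,
               eccentricity = ecc,
               compactness = comp,
               compactness_reliable = A >= 5,
               equivalent_diameter = 2 * sqrt(A / pi) * pixel_size,
               centroid_x = cen_c * pixel_size,
               centroid_y = cen_r * pixel_size,
               mean_grey = if (!is.null(intensity_image))
                 mean(intensity_image[idx]) else NA_real_)
  }))
  if (!is.null(nuclei)) {
    nl <- if (inherits(nuclei, "label_image")) nuclei$labels else nuclei
    nuc_feats <- shape_features(label_image(nl, pixel_size, "nucleus"))
    out$nucleus_area <- NA_real_
    for (k in seq_len(nrow(nuc_feats))) {
      rr <- round(nuc_feats$centroid_y[k] / pixel_size)
      cc <- round(nuc_feats$centroid_x[k] / pixel_size)
      rr <- min(max(rr, 1), nrow(labels)); cc <- min(max(cc, 1), ncol(labels))
      host <- labels[rr, cc]
      if (host > 0) {
        j <- which(out$object_id == host)
        out$nucleus_area[j] <- nuc_feats$area[k]
      }
    }
    out$nc_ratio <- out$nucleus_area / out$area
  }
  rownames(out) <- NULL
  out
}

# Perimeter of the polygon through every 4th contour point (closed), plus
# pi: contour points sit on object pixels ~0.5 px inside the true boundary,
# and insetting a convex boundary by d shortens it by exactly 2*pi*d.
.contour_perimeter <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(4)                    # single-pixel object: unit square
  stride <- if (n >= 16) 4 else 1
  i <- seq(1, n, by = stride)
  p <- pts[i, , drop = FALSE]
  d <- sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2))
  sum(d) + pi
}

.normalize01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

.relabel <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_along(ids)) out[lab == ids[k]] <- k
  out
}

#' Nearest-neighbour internuclear distances
#'
#' @param x A nucleus [label_image], or a 2-column matrix of centroid
#'   coordinates (um).
#' @param pixel_size um per pixel when `x` is a plain label matrix.
#' @return List: `distances` (um, one per nucleus), `mean`, `sd`.
#' @export
internuclear_distances <- function(x, pixel_size = 1) {
  if (inherits(x, "label_image")) {
    f <- shape_features(x)
    cen <- cbind(f$centroid_x, f$centroid_y)
  } else if (is.matrix(x) && ncol(x) == 2) {
    cen <- x                                      # centroid coordinates (um)
  } else {
    f <- shape_features(label_image(x, pixel_size, "nucleus"))
    cen <- cbind(f$centroid_x, f$centroid_y)
  }
  if (nrow(cen) < 2) stop("insufficient objects: need >= 2 nuclei")
  D <- as.matrix(stats::dist(cen))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  list(distances = nn, mean = mean(nn), sd = stats::sd(nn))
}

#' Cell height from a height map
#'
#' The substrate reference is the mode of the height histogram; foreground
#' pixels are those above the mode by more than `background_tol`. Height =
#' 99th percentile of foreground heights minus the background mode.
#'
#' @param hm A [height_map] or numeric matrix (um).
#' @param config Optional list: `background_tol` (um band around the mode
#'   counted as substrate; default 5% of the height range), `quantile`
#'   (default 0.99).
#' @return Height (um); 0 for a flat map.
#' @export
cell_height <- function(hm, config = list()) {
  h <- if (inherits(hm, "height_map")) hm$heights else hm
  v <- as.vector(h)
  if (diff(range(v)) == 0) return(0)
  d <- stats::density(v, n = 512)
  mode_h <- d$x[which.max(d$y)]
  tol <- config$background_tol %||% (0.05 * diff(range(v)))
  background <- abs(v - mode_h) <= tol
  if (!any(background)) stop("reference undefined: no substrate pixels found")
  fore <- v > mode_h + tol
  if (!any(fore)) return(0)
  unname(stats::quantile(v[fore], config$quantile %||% 0.99) - mode_h)
}

#' Cell height from a confocal z-stack occupancy mask
#'
#' @param occupancy 3D logical array (x, y, slice), `TRUE` where cell
#'   material is present.
#' @param slice_spacing um between slices.
#' @param substrate_slice Index of the substrate slice (default 1).
#' @return Height (um): (top occupied slice - substrate slice) x spacing.
#' @export
cell_height_zstack <- function(occupancy, slice_spacing,
                               substrate_slice = 1) {
  occ <- apply(occupancy, 3, any)
  if (!any(occ)) return(0)
  (max(which(occ)) - substrate_slice) * slice_spacing
}

#' Fold change of per-cell mean intensities between two groups
#'
#' Ratio of group means with a seeded bootstrap percentile confidence
#' interval.
#'
#' @param group_a,group_b Per-cell mean grey values (numerator /
#'   denominator).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return List: `ratio`, `ci` (length 2), `n_a`, `n_b`.
#' @export
fold_change <- function(group_a, group_b, n_boot = 2000, conf = 0.95,
                        seed = 1) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  if (mean(group_b) == 0) stop("undefined ratio: denominator group mean is 0")
  ratio <- mean(group_a) / mean(group_b)
  rng <- .local_rng(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    a <- group_a[rng$sample(length(group_a), replace = TRUE)]
    b <- group_b[rng$sample(length(group_b), replace = TRUE)]
    mean(a) / mean(b)
  }, 0)
  alpha <- (1 - conf) / 2
  list(ratio = ratio,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n_a = length(group_a), n_b = length(group_b))
}
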