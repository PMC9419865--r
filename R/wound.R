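#' Segment the wound region of a scratch-assay frame
#'
#' Computes a local-variance texture map (box window), thresholds the
#' low-variance region (Otsu on the variance map: variance mixes linearly
#' across the wound edge, so the midpoint threshold puts the boundary at
#' the true edge), and returns the largest connected low-variance
#' component spanning at least half of the scratch axis. A homogeneous
#' frame is classified globally: all-wound when its texture is below
#' `homogeneous_sd_max`, otherwise confluent (empty mask).
#'
#' @param image Numeric matrix (brightfield-like).
#' @param config Optional list: `window` (box window size px, odd, default
#'   15), `sd_threshold` (absolute local-SD threshold; default Otsu on the
#'   variance map), `scratch_axis` (1 = wound runs along rows, default),
#'   `min_span` (fraction of the scratch axis the wound must span, default
#'   0.5), `sd_ratio_min` (required ratio of outside/inside median local SD,
#'   default 2; guards against spurious wounds in confluent frames),
#'   `homogeneous_sd_max` (grey units, default 0.05: an untextured frame
#'   below this local SD counts as all wound).
#' @return Logical matrix, `TRUE` = wound (possibly all-FALSE).
#' @export
segment_wound <- function(image, config = list()) {
  w <- config$window %||% 15
  axis <- config$scratch_axis %||% 1
  k <- matrix(1 / w^2, w, w)
  x <- EBImage::Image(image)
  m1 <- as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
  m2 <- as.matrix(EBImage::filter2(x^2, k, boundary = "replicate"))
  var_map <- pmax(m2 - m1^2, 0)
  sd_map <- sqrt(var_map)
  empty <- matrix(FALSE, nrow(image), ncol(image))
  # homogeneous frame: no texture contrast to threshold; classify globally
  q_lo <- stats::quantile(sd_map, 0.01); q_hi <- stats::quantile(sd_map, 0.99)
  if (q_hi < 2 * max(q_lo, .Machine$double.eps)) {
    if (stats::median(sd_map) < (config$homogeneous_sd_max %||% 0.05))
      return(!empty)
    return(empty)
  }
  thr <- if (!is.null(config$sd_threshold)) config$sd_threshold^2 else
    (EBImage::otsu(EBImage::Image(.normalize01(var_map))) *
       diff(range(var_map)) + min(var_map))
  low <- var_map < thr
  if (!any(low)) return(empty)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(low * 1)))
  ids <- setdiff(unique(as.vector(lab)), 0L)
  span_len <- if (axis == 1) nrow(image) else ncol(image)
  spans <- vapply(ids, function(i) {
    pos <- if (axis == 1) ((which(lab == i) - 1) %% nrow(lab)) + 1
           else ((which(lab == i) - 1) %/% nrow(lab)) + 1
    (max(pos) - min(pos) + 1) / span_len
  }, 0)
  cand <- ids[spans >= (config$min_span %||% 0.5)]
  if (!length(cand)) return(empty)
  sizes <- vapply(cand, function(i) sum(lab == i), 0)
  wound <- lab == cand[which.max(sizes)]
  outside <- !wound
  if (any(outside) && mean(wound) < 0.9) {
    ratio <- stats::median(sd_map[outside]) /
      max(stats::median(sd_map[wound]), .Machine$double.eps)
    if (ratio < (config$sd_ratio_min %||% 2)) return(empty)
  }
  wound
}

#' Wound-closure kinetics from a time series
#'
#' Segments every frame (replicates averaged), normalizes wound areas to
#' t = 0, and estimates the per-front migration velocity
#' \eqn{v = [W(t_i) - W(t_{i+1})] / [2 (t_{i+1} - t_i)]} where W is the
#' wound width (area / wound length along the scratch axis); the factor 2
#' accounts for the two advancing fronts. The total gap-closure rate
#' (2v-equivalent) is also reported.
#'
#' @param series A `wound_series` (see [gen_wound_series]), or a list with
#'   `timepoints`, `images` (list of per-timepoint replicate lists or plain
#'   matrices), `pixel_size` and `scratch_axis`.
#' @param config Optional list: `closure_threshold` (wound fraction counted
#'   as closed, default 0.01) plus any [segment_wound] options.
#' @return List of class `wound_result`: `timepoints`, `areas` (um^2),
#'   `fractions` (fractions[1] is 1 exactly), `widths` (um),
#'   `closure_time` (h or NA), `velocity` (per-front um/h),
#'   `gap_closure_rate` (um/h).
#' @export
wound_kinetics <- function(series, config = list()) {
  tp <- series$timepoints
  px <- series$pixel_size
  config$scratch_axis <- config$scratch_axis %||% series$scratch_axis %||% 1
  axis <- config$scratch_axis
  n <- length(tp)
  areas <- widths <- numeric(n)
  for (k in seq_len(n)) {
    reps <- series$images[[k]]
    if (is.matrix(reps)) reps <- list(reps)
    a_reps <- w_reps <- numeric(length(reps))
    for (r in seq_along(reps)) {
      m <- segment_wound(reps[[r]], config)
      a_reps[r] <- sum(m) * px^2
      if (any(m)) {
        pos <- if (axis == 1) ((which(m) - 1) %% nrow(m)) + 1
               else ((which(m) - 1) %/% nrow(m)) + 1
        len <- (max(pos) - min(pos) + 1) * px
        w_reps[r] <- a_reps[r] / len
      } else w_reps[r] <- 0
    }
    areas[k] <- mean(a_reps)
    widths[k] <- mean(w_reps)
  }
  if (areas[1] <= 0)
    stop("undefined fraction: no wound detected at t = 0")
  fractions <- areas / areas[1]
  thr <- config$closure_threshold %||% 0.01
  closed <- which(fractions <= thr)
  closure_time <- if (length(closed)) tp[min(closed)] else NA_real_
  # velocity from intervals up to (and including) the closing interval
  last <- if (length(closed)) min(closed) else n
  v_int <- if (last >= 2)
    (widths[seq_len(last - 1)] - widths[2:last]) /
      (2 * diff(tp[seq_len(last)])) else numeric(0)
  velocity <- if (length(v_int)) mean(v_int) else 0
  structure(list(timepoints = tp, areas = areas, fractions = fractions,
                 widths = widths, closure_time = closure_time,
                 velocity = velocity, gap_closure_rate = 2 * velocity),
            class = "wound_result")
}

#' @export
print.wound_result <- function(x, ...) {
  cat("Wound-closure kinetics\n")
  print(data.frame(time_h = x$timepoints, area_um2 = signif(x$areas, 4),
                   fraction = signif(x$fractions, 4)))
  cat(sprintf("  per-front velocity: %.3g um/h (gap closure %.3g um/h)\n",
              x$velocity, x$gap_closure_rate))
  cat(sprintf("  closure time: %s\n",
              if (is.na(x$closure_time)) "not reached" else
                paste0(x$closure_time, " h")))
  invisible(x)
}
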