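#' Ground-truth record attached to every synthetic artifact
#'
#' @param kind One of `force_curve`, `fiber_image`, `monolayer_image`,
#'   `height_map`, `wound_series`.
#' @param parameters Flat named list of generator parameters.
#' @param seed RNG seed the artifact was generated with.
#' @param per_object_truth Optional per-object truth table (data.frame).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(kind, parameters, seed, per_object_truth = NULL) {
  kinds <- c("force_curve", "fiber_image", "monolayer_image", "height_map",
             "wound_series")
  if (!kind %in% kinds) stop("unknown ground-truth kind: ", kind)
  structure(list(kind = kind, parameters = parameters, seed = as.integer(seed),
                 per_object_truth = per_object_truth),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth for a synthetic %s (seed %d)\n", x$kind, x$seed))
  p <- x$parameters
  cat(paste0("  ", names(p), " = ",
             vapply(p, function(v) paste(format(v), collapse = ","), ""),
             collapse = "\n"), "\n")
  if (!is.null(x$per_object_truth))
    cat(sprintf("  per-object truth: %d rows x %d cols\n",
                nrow(x$per_object_truth), ncol(x$per_object_truth)))
  invisible(x)
}

#' Generate a synthetic JKR-type force curve with known truth
#'
#' Produces an approach + retract cycle from the composite forward model
#' (JKR contact + membrane spring), with additive Gaussian force noise and a
#' linear baseline drift. The true contact point and mechanical parameters
#' are recorded in the attached [ground_truth].
#'
#' @param model_params A [contact_params] object; its `z0` is ignored — the
#'   contact point is placed at `contact_offset`.
#' @param z_range Piezo travel (um); the grid runs from 0 to `z_range`.
#' @param n_points Points per segment (>= 50).
#' @param noise_sd Gaussian force noise SD (nN).
#' @param drift_slope Baseline drift (nN/um), added on top of the model's own
#'   baseline.
#' @param contact_offset True contact point (um along the grid).
#' @param seed Integer seed; identical parameters + seed reproduce the curve
#'   bit-for-bit.
#' @param region,substrate,sample_id Metadata stamped on the curve.
#' @return A [force_curve] with attribute `ground_truth`.
#' @export
gen_force_curve <- function(model_params, z_range = 1.4, n_points = 500,
                            noise_sd = 0, drift_slope = 0, contact_offset = 0,
                            seed = 1, region = "cytoplasm",
                            substrate = "TCPS", sample_id = "synthetic") {
  stopifnot(inherits(model_params, "contact_params"))
  if (n_points < 50) stop("n_points must be >= 50")
  if (contact_offset < 0 || contact_offset >= z_range)
    stop("contact_offset must lie inside [0, z_range)")
  p <- model_params
  p$z0 <- contact_offset
  p$baseline_slope <- p$baseline_slope + drift_slope
  z <- seq(0, z_range, length.out = n_points)
  f_app <- composite_forward(z, p, branch = "loading")
  f_ret <- composite_forward(rev(z), p, branch = "unloading")
  rng <- .local_rng(seed)
  f_app <- f_app + rng$rnorm(n_points, sd = noise_sd)
  f_ret <- f_ret + rng$rnorm(n_points, sd = noise_sd)
  curve <- force_curve(c(z, rev(z)), c(f_app, f_ret),
                       c(rep("approach", n_points), rep("retract", n_points)),
                       probe_radius_um = p$R * 1e6,
                       region = region, substrate = substrate,
                       sample_id = sample_id)
  attr(curve, "ground_truth") <- ground_truth(
    "force_curve",
    parameters = list(E = p$E, nu = p$nu, w = p$w, K_m = p$K_m, R = p$R,
                      z0 = contact_offset, z_range = z_range,
                      n_points = n_points, noise_sd = noise_sd,
                      drift_slope = drift_slope,
                      baseline_offset = p$baseline_offset,
                      baseline_slope = p$baseline_slope),
    seed = seed)
  curve
}

# Seed-local RNG: draws never touch (or depend on) the global RNG state.
.local_rng <- function(seed) {
  state <- NULL
  local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    out <- fun(...)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(rnorm = function(...) draw(stats::rnorm, ...),
       runif = function(...) draw(stats::runif, ...),
       sample = function(...) draw(base::sample, ...),
       rlnorm = function(...) draw(stats::rlnorm, ...),
       draw = draw)
}
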