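#' Contact-model parameter set
#'
#' Bundles the parameters of the adhesive contact model used throughout the
#' AFM module: a JKR sphere-on-half-space contact (Young's modulus `E`, work
#' of adhesion `w`) in series with a linear membrane spring `K_m` that
#' represents the stretched cell membrane, plus the piezo-frame nuisance
#' parameters (contact point `z0` and a linear force baseline).
#'
#' @param E Young's modulus of the indented body (Pa).
#' @param nu Poisson ratio; the default 0.5 treats the cell as incompressible.
#' @param w Work of adhesion (J/m^2); 0 gives adhesionless Hertz contact.
#' @param K_m Membrane stiffness (N/m); 0 disables the membrane term.
#' @param R Probe radius (m).
#' @param z0 Contact point (um, in the piezo frame of the curve).
#' @param baseline_offset Force baseline at the contact point (nN).
#' @param baseline_slope Baseline drift (nN/um), referenced to `z0`.
#' @return An object of class `contact_params`.
#' @export
contact_params <- function(E, nu = 0.5, w = 0, K_m = 0, R,
                           z0 = 0, baseline_offset = 0, baseline_slope = 0) {
  if (!is.finite(E) || E <= 0) stop("invalid parameter: E must be > 0")
  if (!is.finite(R) || R <= 0) stop("invalid parameter: R must be > 0")
  if (nu < 0 || nu > 0.5) stop("invalid parameter: nu must lie in [0, 0.5]")
  if (w < 0) stop("invalid parameter: w must be >= 0")
  if (K_m < 0) stop("invalid parameter: K_m must be >= 0")
  structure(list(E = E, nu = nu, w = w, K_m = K_m, R = R, z0 = z0,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope),
            class = "contact_params")
}

#' @export
print.contact_params <- function(x, ...) {
  cat("Contact model parameters\n")
  cat(sprintf("  E   = %.4g Pa (nu = %.2f)\n", x$E, x$nu))
  cat(sprintf("  w   = %.4g J/m^2\n", x$w))
  cat(sprintf("  K_m = %.4g N/m\n", x$K_m))
  cat(sprintf("  R   = %.4g m,  z0 = %.4g um\n", x$R, x$z0))
  cat(sprintf("  baseline = %.4g nN + %.4g nN/um * (z - z0)\n",
              x$baseline_offset, x$baseline_slope))
  invisible(x)
}

# reduced modulus E* = E / (1 - nu^2)
.estar <- function(E, nu) E / (1 - nu^2)

#' Hertz contact force of a rigid sphere on an elastic half-space
#'
#' \eqn{F = (4/3) E/(1-\nu^2) \sqrt{R} \, \delta^{3/2}} for positive
#' indentation depth, 0 otherwise. This is the adhesionless (w = 0) limit of
#' the JKR model.
#'
#' @param delta Indentation depth (m); values <= 0 return zero force.
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio.
#' @param R Probe radius (m).
#' @return Force (N), same length as `delta`.
#' @export
hertz_force <- function(delta, E, nu = 0.5, R) {
  if (!is.finite(E) || E <= 0) stop("invalid parameter: E must be > 0")
  if (!is.finite(R) || R <= 0) stop("invalid parameter: R must be > 0")
  f <- (4 / 3) * .estar(E, nu) * sqrt(R) * pmax(delta, 0)^1.5
  f[delta <= 0] <- 0
  f
}

#' JKR loading branch, parametric in the contact radius
#'
#' For contact radius `a` the classical JKR relations for a rigid sphere on
#' an adhesive elastic half-space are
#' \deqn{F(a) = \frac{4 E^* a^3}{3R} - \sqrt{8 \pi w E^* a^3}, \qquad
#'       \delta(a) = \frac{a^2}{R} - \sqrt{\frac{2 \pi w a}{E^*}}}
#' with \eqn{E^* = E/(1-\nu^2)}. The force minimum over the branch is the
#' pull-off force \eqn{-\frac{3}{2}\pi w R}.
#'
#' @param a_grid Contact radii (m), strictly positive and increasing. If
#'   `NULL`, a default grid from the pull-off radius to the radius reaching
#'   `delta_max` is used.
#' @param params A [contact_params] object (`K_m`, `z0` and baseline are
#'   ignored here; this is the bare contact law).
#' @param delta_max Maximum indentation (m) used to build the default grid.
#' @param n Number of grid points for the default grid.
#' @return A data.frame with columns `a` (m), `delta` (m) and `force` (N).
#' @export
jkr_forward <- function(a_grid = NULL, params, delta_max = 1e-6, n = 400) {
  stopifnot(inherits(params, "contact_params"))
  es <- .estar(params$E, params$nu)
  w <- params$w; R <- params$R
  if (is.null(a_grid)) {
    a_lo <- if (w > 0) (9 * pi * w * R^2 / (8 * es))^(1 / 3) else
      sqrt(R * delta_max) * 1e-3
    a_hi <- .jkr_a_upper(delta_max, es, w, R)
    a_grid <- seq(a_lo, a_hi, length.out = n)
  }
  if (any(a_grid <= 0)) stop("a_grid must be strictly positive")
  if (is.unsorted(a_grid, strictly = TRUE)) stop("a_grid must be increasing")
  force <- (4 * es * a_grid^3) / (3 * R) - sqrt(8 * pi * w * es * a_grid^3)
  delta <- a_grid^2 / R - sqrt(2 * pi * w * a_grid / es)
  data.frame(a = a_grid, delta = delta, force = force)
}

# Contact radius whose delta(a) exceeds delta_max. The closed form is
# continuous in (E, w, delta_max) so that objective functions built on the
# resulting grid stay smooth; the growth loop is a rarely-hit safeguard.
.jkr_a_upper <- function(delta_max, es, w, R) {
  if (w <= 0) return(sqrt(R * max(delta_max, .Machine$double.eps)) * 1.2)
  a0 <- (2 * pi * w * R^2 / es)^(1 / 3)
  a <- sqrt(2 * R * max(delta_max, 0) + 3 * a0^2)
  d <- function(a) a^2 / R - sqrt(2 * pi * w * a / es)
  while (d(a) <= delta_max) a <- a * 1.05
  a
}

# characteristic radii of the JKR branch
.jkr_radii <- function(es, w, R) {
  a0 <- (2 * pi * w * R^2 / es)^(1 / 3)        # delta = 0, loading branch
  a_pull <- (9 * pi * w * R^2 / (8 * es))^(1 / 3)  # dF/da = 0 (pull-off)
  list(a0 = a0, a_pull = a_pull)
}

#' Composite forward model: JKR contact + membrane spring + baseline
#'
#' Evaluates the model force along a piezo position grid. Beyond the contact
#' point (`z > z0`, indentation `delta = z - z0`):
#' \eqn{F = F_{JKR}(\delta) + K_m \delta + \mathrm{baseline}}; before contact
#' the baseline alone. \eqn{F_{JKR}(\delta)} is obtained by numerically
#' inverting the parametric JKR branch of [jkr_forward].
#'
#' @param z_grid Piezo positions (um).
#' @param params A [contact_params] object.
#' @param branch `"loading"` restricts contact to `delta >= 0` (approach);
#'   `"unloading"` follows the adhesive neck down to the pull-off radius, so
#'   the contact regime extends to the negative indentations visited during
#'   retraction before the snap-off.
#' @return Force (nN) along `z_grid`.
#' @export
composite_forward <- function(z_grid, params,
                              branch = c("loading", "unloading")) {
  stopifnot(inherits(params, "contact_params"))
  branch <- match.arg(branch)
  delta <- (z_grid - params$z0) * 1e-6                     # m
  baseline <- params$baseline_offset +
    params$baseline_slope * (z_grid - params$z0)           # nN
  f_contact_N <- .jkr_force_of_delta(delta, params, branch)
  km_term <- params$K_m * pmax(delta, 0)                   # N
  in_contact <- !is.na(f_contact_N)
  force <- baseline
  force[in_contact] <- force[in_contact] +
    (f_contact_N[in_contact] + km_term[in_contact]) * 1e9
  force
}

# F_JKR(delta) in N via monotone spline inversion of the parametric branch;
# NA marks points outside the contact regime (pure baseline).
.jkr_force_of_delta <- function(delta, params, branch = "loading") {
  es <- .estar(params$E, params$nu)
  w <- params$w; R <- params$R
  out <- rep(NA_real_, length(delta))
  dmax <- max(delta, 0)
  if (w <= 0) {
    pos <- delta > 0
    out[pos] <- (4 / 3) * es * sqrt(R) * delta[pos]^1.5
    if (branch == "loading") out[delta == 0] <- 0
    return(out)
  }
  rr <- .jkr_radii(es, w, R)
  a_lo <- if (branch == "loading") rr$a0 else rr$a_pull
  a_hi <- .jkr_a_upper(max(dmax, 1e-12), es, w, R)
  a <- exp(seq(log(a_lo), log(a_hi), length.out = 300))
  par <- jkr_forward(a, contact_params(E = params$E, nu = params$nu, w = w,
                                       K_m = 0, R = R))
  # delta(a) is strictly increasing on [a_lo, a_hi] for both branches
  sf <- stats::splinefun(par$delta, par$force, method = "hyman")
  d_min <- par$delta[1]
  inside <- delta >= d_min & delta <= par$delta[length(a)]
  too_deep <- delta > par$delta[length(a)]
  if (any(too_deep))
    stop(sprintf("indentation %.3g m outside parametric JKR range",
                 max(delta[too_deep])))
  out[inside] <- sf(delta[inside])
  out
}
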