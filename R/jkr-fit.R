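#' Estimate the contact point of a force curve
#'
#' Default method (`"piecewise"`): grid search over candidate contact points
#' along the approach segment; each candidate is scored by the total SSE of a
#' joint least-squares fit of a line on the pre-contact region plus an
#' adhesionless composite contact basis (\eqn{\delta^{3/2}} and \eqn{\delta})
#' on the post-contact region. The candidate minimizing SSE wins. The
#' `"rov"` alternative maximizes the ratio of force variance after vs before
#' a sliding split point.
#'
#' @param curve A [force_curve] with an approach segment of >= 20 pre-contact
#'   points.
#' @param config Optional list: `method` ("piecewise" or "rov"),
#'   `max_candidates` (default 200), `min_pre` (default 20), `min_post`
#'   (default 10), `improve_frac` (default 0.95; the best piecewise SSE must
#'   be below this fraction of the baseline-only SSE or a no-contact error is
#'   raised), `rov_window` (default 15).
#' @return A list with `z0` (um), `method`, and `diagnostics` (the SSE or
#'   variance-ratio profile as a data.frame).
#' @export
estimate_contact_point <- function(curve, config = list()) {
  stopifnot(inherits(curve, "force_curve"))
  method <- config$method %||% "piecewise"
  app <- .curve_segment(curve, "approach")
  o <- order(app$z)
  z <- app$z[o]; f <- app$force[o]
  n <- length(z)
  min_pre <- config$min_pre %||% 20
  min_post <- config$min_post %||% 10
  if (n < min_pre + min_post + 2) stop("approach segment too short")
  if (method == "rov") return(.contact_point_rov(z, f, config))

  idx <- seq(min_pre + 1, n - min_post)
  maxc <- config$max_candidates %||% 200
  if (length(idx) > maxc)
    idx <- unique(round(seq(idx[1], idx[length(idx)], length.out = maxc)))
  base_fit <- stats::lm.fit(cbind(1, z), f)
  sse0 <- sum(base_fit$residuals^2)
  sse <- rep(Inf, length(idx))
  for (k in seq_along(idx)) {
    z0c <- z[idx[k]]
    d <- pmax(z - z0c, 0)
    X <- cbind(1, z, d^1.5, d)
    fit <- stats::lm.fit(X, f)
    if (!is.na(fit$coefficients[3]) && fit$coefficients[3] < 0) next
    sse[k] <- sum(fit$residuals^2)
  }
  k_best <- which.min(sse)
  improve <- config$improve_frac %||% 0.95
  # sse0 ~ 0 means the whole curve is already a perfect line (no contact)
  sse0_floor <- max(sum(f^2), 1) * 1e-20
  if (!is.finite(sse[k_best]) || sse0 <= sse0_floor ||
      sse[k_best] > improve * sse0)
    stop("no contact detected: contact model does not improve on baseline fit")
  list(z0 = z[idx[k_best]], method = "piecewise",
       diagnostics = data.frame(z0 = z[idx], sse = sse))
}

.contact_point_rov <- function(z, f, config) {
  w <- config$rov_window %||% 15
  n <- length(z)
  idx <- seq(w + 1, n - w)
  ratio <- vapply(idx, function(i) {
    v_after <- stats::var(f[(i + 1):(i + w)])
    v_before <- stats::var(f[(i - w):(i - 1)])
    v_after / max(v_before, .Machine$double.eps)
  }, 0)
  list(z0 = z[idx[which.max(ratio)]], method = "rov",
       diagnostics = data.frame(z0 = z[idx], variance_ratio = ratio))
}

#' Fit the composite JKR + membrane contact model to a force curve
#'
#' Bounded nonlinear least squares on the approach segment. The nonlinear
#' search runs over (log E, w, z0) from a deterministic list of starting
#' points; at every step the membrane stiffness and the linear baseline are
#' profiled out by constrained linear least squares, which keeps the search
#' three-dimensional and well conditioned. The contact point is initialized
#' by [estimate_contact_point] and refined inside the fit.
#'
#' @param curve A [force_curve].
#' @param config Optional list: `nu` (default 0.5), `bounds` (list with `E`
#'   = c(0.1, 1e6) Pa, `w` = c(0, 0.1) J/m^2, `K_m` = c(0, 1) N/m), `z0`
#'   (fixed contact point; skips estimation), `z0_window` (um the fit may
#'   move z0 from its initial estimate, default 0.2), `cell_height_um`
#'   (when supplied, indentations beyond 40% of it are flagged),
#'   `contact_method` passed through to [estimate_contact_point].
#' @return An object of class `jkr_fit`: fitted [contact_params], `rmse`
#'   (nN), `converged`, `beta` = K_m/(E R), `indentation_max` (um),
#'   adhesion energetics when a retract segment is present, and the data.
#' @seealso [predict.jkr_fit], [simulate.jkr_fit], [aggregate_by_region]
#' @export
jkr_fit <- function(curve, config = list()) {
  stopifnot(inherits(curve, "force_curve"))
  nu <- config$nu %||% 0.5
  bounds <- config$bounds %||% list()
  bE <- bounds$E %||% c(0.1, 1e6)
  bw <- bounds$w %||% c(0, 0.1)
  bk <- bounds$K_m %||% c(0, 1)
  R_m <- curve$probe_radius_um * 1e-6

  app <- .curve_segment(curve, "approach")
  o <- order(app$z); z <- app$z[o]; f <- app$force[o]

  if (!is.null(config$z0)) {
    z0_hat <- config$z0
  } else {
    cp_cfg <- config
    cp_cfg$method <- config$contact_method %||% "piecewise"
    z0_hat <- estimate_contact_point(curve, cp_cfg)$z0
  }
  z0_win <- config$z0_window %||% 0.2

  # Hertz-slope initial guess for E and the baseline from pre-contact points
  pre <- z <= z0_hat
  bl <- if (sum(pre) >= 2) stats::lm.fit(cbind(1, z[pre]), f[pre])$coefficients
        else c(stats::median(f), 0)
  # slope of F vs delta^{3/2} over the outer contact half: insensitive to the
  # adhesive jump-to-contact offset near delta = 0
  d0 <- pmax(z - z0_hat, 0)
  y0 <- f - (bl[1] + bl[2] * z)
  dmax <- max(d0)
  i2 <- which.min(abs(d0 - dmax)); i1 <- which.min(abs(d0 - dmax / 2))
  c_hz <- if (i2 != i1 && dmax > 0)
    (y0[i2] - y0[i1]) / (d0[i2]^1.5 - d0[i1]^1.5) else 0
  if (!is.finite(c_hz) || c_hz <= 0)
    c_hz <- sum(y0 * d0^1.5) / max(sum(d0^3), .Machine$double.eps)
  E0 <- max(min(0.75 * c_hz / sqrt(R_m) * (1 - nu^2), bE[2]), bE[1])

  w_scale <- 1e-5
  s_f <- max(stats::sd(f), 1e-9)

  # profile K_m, baseline offset and slope out by linear LS (K_m clamped to
  # its bounds); returns SSE and the profiled coefficients
  profiled <- function(E, w, z0) {
    p <- contact_params(E = E, nu = nu, w = w, K_m = 0, R = R_m, z0 = z0)
    fj <- tryCatch(composite_forward(z, p, branch = "loading"),
                   error = function(e) NULL)
    if (is.null(fj)) return(list(sse = Inf))
    d <- pmax(z - z0, 0)
    X <- cbind(d * 1e3, 1, z - z0)          # K_m in mN/m for conditioning
    y <- f - fj
    cf <- stats::lm.fit(X, y)$coefficients
    cf[is.na(cf)] <- 0
    # column was d (um) * 1e3, so cf[1] is directly K_m in N/m
    # (1 N/m = 1e3 nN/um)
    K_m <- min(max(cf[1], bk[1]), bk[2])
    resid <- y - K_m * 1e3 * d - cf[2] - cf[3] * (z - z0)
    # re-solve baseline when K_m was clamped
    if (abs(K_m - cf[1]) > 1e-15) {
      cb <- stats::lm.fit(cbind(1, z - z0), y - K_m * 1e3 * d)$coefficients
      cf[2] <- cb[1]; cf[3] <- cb[2]
      resid <- y - K_m * 1e3 * d - cf[2] - cf[3] * (z - z0)
    }
    list(sse = sum((resid / s_f)^2), K_m = K_m, b0 = unname(cf[2]),
         b1 = unname(cf[3]), resid = resid)
  }

  obj <- function(th) {
    out <- profiled(exp(th[1]), th[2] * w_scale, th[3])
    if (!is.finite(out$sse)) 1e12 else out$sse
  }

  starts <- list(c(log(E0), 0, z0_hat),
                 c(log(max(E0 * 0.3, bE[1])), 1, z0_hat),
                 c(log(min(E0 * 3, bE[2])), 0.3, z0_hat),
                 c(log(E0), 0.1, z0_hat),
                 c(log(max(E0 / 30, bE[1])), 0.5, z0_hat))
  lower <- c(log(bE[1]), bw[1] / w_scale, z0_hat - z0_win)
  upper <- c(log(bE[2]), bw[2] / w_scale, z0_hat + z0_win)

  best <- NULL
  conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 400, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  # polish the winner with a fine-step pass; if fine steps cannot improve
  # the fit it is stationary, which counts as convergence even when the
  # line search terminated abnormally
  if (!is.null(best)) {
    pre_val <- best$value
    pol <- tryCatch(
      stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 300, factr = 10,
                                  ndeps = c(1e-5, 1e-5, 1e-5))),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= best$value) {
      best <- pol
      if (pol$convergence == 0 ||
          (pre_val - pol$value) <= 1e-6 * max(pre_val, 1e-300))
        conv <- TRUE
    }
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, data = curve,
                          message = "all starts failed"), class = "jkr_fit"))

  # on degenerate noise-free problems the line search can terminate
  # abnormally at an essentially exact solution; any converged start with
  # the same best SSE counts
  conv <- conv || best$convergence == 0
  th <- best$par
  E_hat <- exp(th[1]); w_hat <- th[2] * w_scale; z0_fit <- th[3]
  prof <- profiled(E_hat, w_hat, z0_fit)
  params <- contact_params(E = E_hat, nu = nu, w = w_hat, K_m = prof$K_m,
                           R = R_m, z0 = z0_fit,
                           baseline_offset = prof$b0, baseline_slope = prof$b1)
  rmse <- sqrt(mean(prof$resid^2))
  ind_max <- max(z) - z0_fit
  warn <- character()
  if (!is.null(config$cell_height_um) &&
      ind_max > 0.4 * config$cell_height_um)
    warn <- c(warn, sprintf(
      "max indentation %.3f um exceeds 40%% of the supplied cell height", ind_max))

  adh <- if (any(curve$segment == "retract"))
    adhesion_energetics(curve, z0 = z0_fit) else NULL

  structure(list(params = params, rmse = rmse,
                 converged = conv,
                 beta = params$K_m / (params$E * R_m),
                 indentation_max = ind_max,
                 w_pulloff = adh$w_pulloff, hysteresis_energy = adh$hysteresis_energy,
                 zero_adhesion = adh$zero_adhesion,
                 sse = best$value, z0_initial = z0_hat,
                 warnings = warn, data = curve,
                 fitted_z = z, fitted = f - prof$resid, resid = prof$resid),
            class = "jkr_fit")
}

#' @export
print.jkr_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("JKR fit: FAILED (", x$message, ")\n"); return(invisible(x))
  }
  p <- x$params
  cat(sprintf("JKR + membrane fit (%s on %s)\n",
              x$data$region, x$data$substrate))
  cat(sprintf("  E = %.4g Pa, w = %.3g J/m^2, K_m = %.3g N/m, beta = %.4g\n",
              p$E, p$w, p$K_m, x$beta))
  cat(sprintf("  z0 = %.4f um, rmse = %.3g nN, converged = %s\n",
              p$z0, x$rmse, x$converged))
  if (!is.null(x$w_pulloff))
    cat(sprintf("  adhesion: w_pulloff = %.3g J/m^2, hysteresis = %.3g J\n",
                x$w_pulloff, x$hysteresis_energy))
  for (w in x$warnings) cat("  warning: ", w, "\n")
  invisible(x)
}

#' @export
summary.jkr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.jkr_fit")
}

#' @export
print.summary.jkr_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.null(f$params)) {
    cat(sprintf("  max indentation: %.4f um; SSE (scaled): %.4g\n",
                f$indentation_max, f$sse))
    cat(sprintf("  residual quartiles (nN): %s\n",
                paste(signif(stats::quantile(f$resid), 3), collapse = " ")))
  }
  invisible(x)
}

#' @export
coef.jkr_fit <- function(object, ...) {
  p <- object$params
  c(E = p$E, nu = p$nu, w = p$w, K_m = p$K_m, z0 = p$z0,
    baseline_offset = p$baseline_offset, baseline_slope = p$baseline_slope,
    beta = object$beta)
}

#' Predict model force at piezo positions
#'
#' @param object A [jkr_fit].
#' @param z Piezo positions (um); defaults to the fitted approach grid.
#' @param branch Contact branch, see [composite_forward].
#' @param ... Unused.
#' @return Force (nN).
#' @export
predict.jkr_fit <- function(object, z = NULL, branch = "loading", ...) {
  if (is.null(z)) z <- object$fitted_z
  composite_forward(z, object$params, branch = branch)
}

#' @export
residuals.jkr_fit <- function(object, ...) object$resid

#' Simulate force curves from a fitted contact model
#'
#' Draws new synthetic curves from the fitted parameters with Gaussian force
#' noise equal to the fit's residual RMSE — a parametric bootstrap of the
#' measurement.
#'
#' @param object A [jkr_fit].
#' @param nsim Number of curves.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of [force_curve] objects.
#' @export
simulate.jkr_fit <- function(object, nsim = 1, seed = 1, ...) {
  p <- object$params
  zr <- max(object$fitted_z)
  lapply(seq_len(nsim), function(i)
    gen_force_curve(p, z_range = zr, n_points = length(object$fitted_z),
                    noise_sd = object$rmse, contact_offset = p$z0,
                    seed = seed + i - 1, region = object$data$region,
                    substrate = object$data$substrate))
}

#' @export
plot.jkr_fit <- function(x, ...) {
  ret <- .curve_segment(x$data, "retract")
  plot(x$data$z, x$data$force, col = ifelse(x$data$segment == "approach",
                                            "grey30", "grey70"),
       pch = 16, cex = 0.4, xlab = "piezo z (um)", ylab = "force (nN)",
       main = "JKR + membrane contact fit", ...)
  graphics::lines(x$fitted_z, x$fitted, col = "red3", lwd = 2)
  graphics::abline(v = x$params$z0, lty = 2, col = "blue3")
  graphics::legend("topleft", bty = "n",
                   legend = c("approach", "retract", "fit", "contact point"),
                   col = c("grey30", "grey70", "red3", "blue3"),
                   pch = c(16, 16, NA, NA), lty = c(NA, NA, 1, 2))
  invisible(x)
}

#' Adhesion energetics from the retract segment
#'
#' `w_pulloff` converts the depth of the retract force minimum below the
#' baseline into a work of adhesion through the JKR pull-off identity
#' \eqn{F_{pull} = -\frac{3}{2}\pi w R}, i.e.
#' \eqn{w = 2 |F_{min} - baseline| / (3 \pi R)}. `hysteresis_energy`
#' integrates the approach-retract force loop over the overlapping range
#' (trapezoidal rule).
#'
#' @param curve A [force_curve] with a retract segment.
#' @param z0 Optional contact point (um); when given, the hysteresis
#'   integral is restricted to indentations z >= z0 minus the adhesive tail.
#' @param baseline_frac Fraction of the most-retracted points used to fit
#'   the retract baseline line (default 0.2).
#' @return List: `w_pulloff` (J/m^2), `hysteresis_energy` (J),
#'   `zero_adhesion` flag, `baseline` coefficients.
#' @export
adhesion_energetics <- function(curve, z0 = NULL, baseline_frac = 0.2) {
  stopifnot(inherits(curve, "force_curve"))
  ret <- .curve_segment(curve, "retract")
  if (!length(ret$z)) stop("retract segment required for adhesion analysis")
  o <- order(ret$z); zr <- ret$z[o]; fr <- ret$force[o]
  n <- length(zr)
  # baseline from the far (pre-contact) region of the approach segment when
  # present: on retraction the adhesive neck can extend far below the
  # contact point and contaminate the retract's own far region
  appr <- .curve_segment(curve, "approach")
  if (length(appr$z)) {
    oa0 <- order(appr$z); zb <- appr$z[oa0]; fb <- appr$force[oa0]
  } else { zb <- zr; fb <- fr }
  nb <- max(2, round(baseline_frac * length(zb)))
  blfit <- stats::lm.fit(cbind(1, zb[seq_len(nb)]), fb[seq_len(nb)])
  bl <- blfit$coefficients
  resid_sd <- stats::sd(blfit$residuals)
  i_min <- which.min(fr - (bl[1] + bl[2] * zr))
  depth <- unname((bl[1] + bl[2] * zr[i_min]) - fr[i_min])   # nN
  R_m <- curve$probe_radius_um * 1e-6
  zero <- depth <= 3 * resid_sd + 1e-12
  w_pull <- if (zero) 0 else 2 * (depth * 1e-9) / (3 * pi * R_m)

  app <- .curve_segment(curve, "approach")
  oa <- order(app$z); za <- app$z[oa]; fa <- app$force[oa]
  lo <- max(min(za), min(zr)); hi <- min(max(za), max(zr))
  if (!is.null(z0)) lo <- max(lo, z0)
  zi <- za[za >= lo & za <= hi]
  hyst <- 0
  if (length(zi) > 2) {
    f_ret_i <- stats::approx(zr, fr, xout = zi, rule = 2)$y
    f_app_i <- fa[za >= lo & za <= hi]
    dz <- diff(zi)
    gap <- f_app_i - f_ret_i
    hyst <- sum((gap[-1] + gap[-length(gap)]) / 2 * dz) * 1e-15  # nN um -> J
  }
  list(w_pulloff = w_pull, hysteresis_energy = hyst, zero_adhesion = zero,
       baseline = unname(bl))
}

#' Summarize contact-fit results by substrate and cellular region
#'
#' @param results List of [jkr_fit] objects (failed fits are dropped with a
#'   warning).
#' @return A data.frame with one row per (substrate, region) group: n and
#'   mean/SD of E, K_m, beta, w_pulloff and hysteresis energy. SD is NA for
#'   n = 1; groups with n < 3 carry `low_n = TRUE`.
#' @export
aggregate_by_region <- function(results) {
  if (!length(results)) stop("empty result list")
  ok <- vapply(results, function(r) !is.null(r$params), TRUE)
  if (any(!ok)) warning(sum(!ok), " failed fits dropped from aggregation")
  results <- results[ok]
  if (!length(results)) stop("empty result list after dropping failed fits")
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(substrate = r$data$substrate, region = r$data$region,
               E = r$params$E, K_m = r$params$K_m, beta = r$beta,
               w_pulloff = r$w_pulloff %||% NA_real_,
               hysteresis = r$hysteresis_energy %||% NA_real_)))
  vars <- c("E", "K_m", "beta", "w_pulloff", "hysteresis")
  groups <- unique(df[c("substrate", "region")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- df[df$substrate == groups$substrate[i] & df$region == groups$region[i], ]
    row <- data.frame(substrate = groups$substrate[i],
                      region = groups$region[i], n = nrow(g),
                      low_n = nrow(g) < 3)
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(g[[v]])
      row[[paste0(v, "_sd")]] <- if (nrow(g) > 1) stats::sd(g[[v]]) else NA_real_
    }
    row
  }))
  rownames(out) <- NULL
  out
}
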