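# shared fixture builders (all fixtures are generated in code)

PROBE_R <- 2.6e-6   # m; 5.2 um diameter colloidal probe

# pixel-index grids for constructed masks
grid_xy <- function(n) {
  list(x = matrix(rep(seq_len(n), each = n), n),
       y = matrix(rep(seq_len(n), times = n), n))
}

disc_mask <- function(n, cx, cy, r) {
  g <- grid_xy(n)
  (g$x - cx)^2 + (g$y - cy)^2 <= r^2
}

ellipse_mask <- function(n, cx, cy, a, b, phi = 0) {
  g <- grid_xy(n)
  u <- (g$x - cx) * cos(phi) + (g$y - cy) * sin(phi)
  v <- -(g$x - cx) * sin(phi) + (g$y - cy) * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

# anti-aliased infinite ribbon through (cx, cy) at angle theta, width w px
ribbon_image <- function(n, cx, cy, theta, w) {
  g <- grid_xy(n)
  d <- abs((g$x - cx) * sin(theta) - (g$y - cy) * cos(theta))
  pmin(pmax(w / 2 + 0.5 - d, 0), 1)
}

# quick noise-free curve from given parameters
quick_curve <- function(E, w = 0, K_m = 0, noise_sd = 0, seed = 1,
                        n_points = 400, z0 = 1, z_range = 1.4, ...) {
  gen_force_curve(contact_params(E = E, w = w, K_m = K_m, R = PROBE_R),
                  z_range = z_range, n_points = n_points,
                  noise_sd = noise_sd, contact_offset = z0, seed = seed, ...)
}
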