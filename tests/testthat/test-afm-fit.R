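# Contact-point estimation, model fitting, adhesion energetics, aggregation

test_that("contact point is recovered within one grid step on clean curves", {
  cv <- quick_curve(E = 200, n_points = 400)
  dz <- 1.4 / 399
  est <- estimate_contact_point(cv)
  expect_lt(abs(est$z0 - 1), dz + 1e-12)
  expect_true(is.data.frame(est$diagnostics))
})

test_that("contact-point estimate is translation equivariant", {
  cv <- quick_curve(E = 200, n_points = 300, noise_sd = 0.001, seed = 3)
  z0a <- estimate_contact_point(cv)$z0
  shifted <- cv
  shifted$z <- cv$z + 0.37
  z0b <- estimate_contact_point(shifted)$z0
  expect_equal(z0b - z0a, 0.37, tolerance = 1e-12)
})

test_that("a pure-baseline curve raises a no-contact error", {
  z <- seq(0, 1.4, length.out = 200)
  cv <- force_curve(z, 0.01 + 0.002 * z, rep("approach", 200),
                    probe_radius_um = 2.6)
  expect_error(estimate_contact_point(cv), "no contact")
})

test_that("rov contact detector lands near the contact point under noise", {
  cv <- quick_curve(E = 400, n_points = 400, noise_sd = 0.0005, seed = 9)
  est <- estimate_contact_point(cv, config = list(method = "rov"))
  expect_lt(abs(est$z0 - 1), 0.1)
})

test_that("noise-free curves at the reported moduli refit within 1%", {
  for (E in c(30.73, 118.1)) {
    fit <- jkr_fit(quick_curve(E = E, n_points = 500))
    expect_true(fit$converged)
    expect_lt(abs(fit$params$E - E) / E, 0.01)
  }
})

test_that("membrane-to-bulk ratio is recovered within 2% at both ratios", {
  for (beta in c(1.37, 0.0314)) {
    p <- contact_params(E = 100, w = 1e-5, K_m = beta * 100 * PROBE_R,
                        R = PROBE_R)
    cv <- gen_force_curve(p, z_range = 1.4, n_points = 500,
                          contact_offset = 1, seed = 2)
    fit <- jkr_fit(cv)
    expect_lt(abs(fit$beta - beta) / beta, 0.02)
    expect_equal(fit$beta, fit$params$K_m / (fit$params$E * PROBE_R))
  }
})

test_that("fitting a Hertz curve with the full model keeps w and K_m tiny", {
  fit <- jkr_fit(quick_curve(E = 250, n_points = 400))
  expect_lt(fit$params$w, 0.01 * 0.1)      # <= 1% of the w upper bound
  expect_lt(fit$params$K_m, 0.01 * 1)      # <= 1% of the K_m upper bound
})

test_that("median modulus error stays below 10% at 5% force noise", {
  f_max <- composite_forward(
    1.4, contact_params(E = 200, w = 0, K_m = 0, R = PROBE_R, z0 = 1))
  errs <- vapply(1:15, function(s) {
    fit <- jkr_fit(quick_curve(E = 200, noise_sd = 0.05 * f_max,
                               n_points = 300, seed = s))
    abs(fit$params$E - 200) / 200
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("results are invariant to declaring z in nm instead of um", {
  cv <- quick_curve(E = 150, n_points = 300)
  cv_nm <- force_curve(cv$z * 1000, cv$force, cv$segment,
                       probe_radius_um = cv$probe_radius_um, z_unit = "nm")
  f1 <- jkr_fit(cv); f2 <- jkr_fit(cv_nm)
  expect_equal(f2$params$E, f1$params$E, tolerance = 1e-8)
})

test_that("indentations past 40% of a supplied cell height are flagged", {
  fit <- jkr_fit(quick_curve(E = 200, n_points = 300),
                 config = list(cell_height_um = 0.5))
  expect_match(fit$warnings, "40%")
  fit2 <- jkr_fit(quick_curve(E = 200, n_points = 300),
                  config = list(cell_height_um = 5))
  expect_length(fit2$warnings, 0)
})

test_that("pull-off work of adhesion is recovered within 2%", {
  p <- contact_params(E = 100, w = 1e-4, K_m = 0, R = PROBE_R)
  cv <- gen_force_curve(p, z_range = 1.4, n_points = 400,
                        contact_offset = 1, seed = 5)
  ae <- adhesion_energetics(cv)
  expect_false(ae$zero_adhesion)
  expect_equal(ae$w_pulloff, 1e-4, tolerance = 0.02)
  expect_gt(ae$hysteresis_energy, 0)
})

test_that("a reversible curve gives zero hysteresis and zero adhesion", {
  z <- seq(0, 1.4, length.out = 200)
  p <- contact_params(E = 200, w = 0, K_m = 0, R = PROBE_R, z0 = 1)
  f <- composite_forward(z, p)
  cv <- force_curve(c(z, rev(z)), c(f, rev(f)),
                    rep(c("approach", "retract"), each = 200),
                    probe_radius_um = 2.6)
  ae <- adhesion_energetics(cv)
  expect_true(ae$zero_adhesion)
  expect_identical(ae$w_pulloff, 0)
  expect_equal(ae$hysteresis_energy, 0, tolerance = 1e-15)
})

test_that("adhesion outputs are homogeneous of degree one in force", {
  p <- contact_params(E = 100, w = 5e-5, K_m = 0, R = PROBE_R)
  cv <- gen_force_curve(p, z_range = 1.4, n_points = 300,
                        contact_offset = 1, seed = 6)
  cv2 <- cv
  cv2$force <- 2 * cv$force
  a1 <- adhesion_energetics(cv); a2 <- adhesion_energetics(cv2)
  expect_equal(a2$w_pulloff, 2 * a1$w_pulloff, tolerance = 1e-9)
  expect_equal(a2$hysteresis_energy, 2 * a1$hysteresis_energy,
               tolerance = 1e-9)
})

test_that("fit object methods behave like a standard model fit", {
  cv <- quick_curve(E = 150, w = 1e-5, n_points = 300)
  fit <- jkr_fit(cv)
  expect_s3_class(fit, "jkr_fit")
  cf <- coef(fit)
  expect_named(cf, c("E", "nu", "w", "K_m", "z0", "baseline_offset",
                     "baseline_slope", "beta"))
  expect_length(residuals(fit), 300)
  pr <- predict(fit)
  expect_equal(pr, fit$fitted, tolerance = 1e-6)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "force_curve")
  expect_output(print(fit), "JKR")
  expect_output(print(summary(fit)), "residual quartiles")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("aggregation by region summarizes and flags small groups", {
  mk <- function(E, region, substrate, seed)
    jkr_fit(quick_curve(E = E, n_points = 300, seed = seed,
                        region = region, substrate = substrate))
  f1 <- mk(30, "junction", "NCCI", 1)
  f2 <- mk(30, "junction", "NCCI", 1)
  f3 <- mk(10, "cytoplasm", "NCCI", 2)
  agg <- aggregate_by_region(list(f1, f2, f3))
  jn <- agg[agg$region == "junction", ]
  expect_equal(jn$n, 2)
  expect_true(jn$low_n)
  expect_equal(jn$E_sd, 0)                       # identical fits
  cy <- agg[agg$region == "cytoplasm", ]
  expect_equal(cy$n, 1)
  expect_true(is.na(cy$E_sd))                    # SD undefined at n = 1
  # group ordering matches the generator truths (E_junction > E_cytoplasm)
  expect_gt(jn$E_mean, cy$E_mean)
  expect_error(aggregate_by_region(list()), "empty")
})
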