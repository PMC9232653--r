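test_that("PA and EHSS reproduce the analytic single-sphere cross section", {
  for (r in c(1.0, 2.9)) {
    m <- single_bead(r)
    pa <- ccs_pa(m, radii = r, n_orientations = 60, n_samples = 2e4, seed = 5)
    eh <- ccs_ehss(m, radii = r, n_orientations = 60, n_impact_points = 2e4,
                   seed = 5)
    expect_lt(abs(pa$value - pi * r^2), 3 * max(pa$standard_error, 1e-3))
    expect_lt(abs(eh$value - pi * r^2), 3 * max(eh$standard_error,
                                                0.01 * pi * r^2))
  }
})

test_that("two-sphere PA matches the orientation-quadrature oracle", {
  for (d in c(2, 5, 9)) {
    m <- two_beads(d, r = 2.9)
    pa <- ccs_pa(m, radii = 2.9, n_orientations = 400, n_samples = 2e4, seed = 2)
    oracle <- two_sphere_pa_oracle(2.9, d)
    expect_lt(abs(pa$value - oracle), 3 * max(pa$standard_error, 0.002 * oracle))
  }
})

test_that("PA agrees with the 0.1-Angstrom rasterization oracle on small models", {
  ori <- fixed_orientations(40)
  for (m in list(build_duplex(8, label = "d8"),
                 two_beads(6),
                 make_bead_model(rnorm(30, sd = 6), rnorm(30, sd = 6),
                                 rnorm(30, sd = 6), label = "blob30"))) {
    expect_lte(nrow(m$beads), 50)
    pa <- ccs_pa(m, radii = 2.9, n_samples = 2e5, seed = 3, orientations = ori)
    oracle <- raster_pa_oracle(m, 2.9, ori, px = 0.1)
    expect_lt(abs(pa$value - oracle) / oracle, 0.005)
  }
})

test_that("EHSS never falls below PA and exceeds it strictly on concave bodies", {
  set.seed(14)
  models <- list(
    build_duplex(6),
    build_bundle(bundle_spec(6, bp_per_helix = 4)),
    make_bead_model(rnorm(40, sd = 8), rnorm(40, sd = 8), rnorm(40, sd = 8)))
  for (m in models) {
    pa <- ccs_pa(m, n_orientations = 150, n_samples = 5e3, seed = 9)
    eh <- ccs_ehss(m, n_orientations = 150, n_impact_points = 5e3, seed = 9)
    expect_gte(eh$value, pa$value - 3 * (pa$standard_error + eh$standard_error))
  }
  # a concave cup: ring of spheres forming a pocket that multiply
  # scatters trajectories
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  cup <- make_bead_model(
    x = c(5 * cos(th), 5 * cos(th), 0),
    y = c(5 * sin(th), 5 * sin(th), 0),
    z = c(rep(0, 12), rep(3.5, 12), 0),
    radius = 2.0, label = "cup")
  pa <- ccs_pa(cup, radii = 2.0, n_orientations = 300, n_samples = 1e4, seed = 4)
  eh <- ccs_ehss(cup, radii = 2.0, n_orientations = 300, n_impact_points = 1e4,
                 seed = 4)
  expect_gt(eh$value, pa$value + 3 * (pa$standard_error + eh$standard_error))
  # strictly positive margin is reproducible under the seed
  eh2 <- ccs_ehss(cup, radii = 2.0, n_orientations = 300, n_impact_points = 1e4,
                  seed = 4)
  expect_identical(eh$value, eh2$value)
})

test_that("CCS scales as the square of a uniform dilation", {
  m <- build_bundle(bundle_spec(6, bp_per_helix = 5))
  f <- 1.7
  scaled <- m
  scaled$beads$x <- m$beads$x * f
  scaled$beads$y <- m$beads$y * f
  scaled$beads$z <- m$beads$z * f
  pa1 <- ccs_pa(m, radii = 2.9, n_orientations = 200, n_samples = 1e4, seed = 6)
  pa2 <- ccs_pa(scaled, radii = 2.9 * f, n_orientations = 200,
                n_samples = 1e4, seed = 6)
  expect_lt(abs(pa2$value - f^2 * pa1$value),
            3 * (f^2 * pa1$standard_error + pa2$standard_error))
  eh1 <- ccs_ehss(m, radii = 2.9, n_orientations = 150, n_impact_points = 8e3,
                  seed = 6)
  eh2 <- ccs_ehss(scaled, radii = 2.9 * f, n_orientations = 150,
                  n_impact_points = 8e3, seed = 6)
  expect_lt(abs(eh2$value - f^2 * eh1$value),
            3 * (f^2 * eh1$standard_error + eh2$standard_error))
})

test_that("estimators are invariant to rotation and translation", {
  m <- build_duplex(10)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- m
  xyz <- as.matrix(m$beads[, c("x", "y", "z")]) %*% R
  moved$beads$x <- xyz[, 1] + 40
  moved$beads$y <- xyz[, 2] - 13
  moved$beads$z <- xyz[, 3] + 7
  a <- ccs_pa(m, n_orientations = 250, n_samples = 1e4, seed = 8)
  b <- ccs_pa(moved, n_orientations = 250, n_samples = 1e4, seed = 9)
  expect_lt(abs(a$value - b$value),
            3 * (a$standard_error + b$standard_error) + 0.002 * a$value)
})

test_that("PA error shrinks like one over the square root of the sampling effort", {
  m <- single_bead(2.9)
  # iid orientations so the standard-error model applies
  se_small <- ccs_pa(m, n_orientations = 50, n_samples = 2e3, seed = 10,
                     quasi = FALSE)$standard_error
  se_big <- ccs_pa(m, n_orientations = 800, n_samples = 2e3, seed = 10,
                   quasi = FALSE)$standard_error
  expect_gt(se_small / se_big, 4 / 2.0)
  expect_lt(se_small / se_big, 4 * 2.0)
})

test_that("CCS results are seed-reproducible and validate their inputs", {
  m <- build_duplex(5)
  a <- ccs_pa(m, n_orientations = 50, n_samples = 2e3, seed = 12)
  b <- ccs_pa(m, n_orientations = 50, n_samples = 2e3, seed = 12)
  expect_identical(a$value, b$value)
  c_ <- ccs_pa(m, n_orientations = 50, n_samples = 2e3, seed = 13)
  expect_false(identical(a$value, c_$value))
  expect_error(ccs_pa(m, n_orientations = 0), "sampling")
  expect_error(ccs_pa(m, radii = c(P = 2.9)), "no collision radius")
})

test_that("TJM rescaling is a recorded deterministic transform of PA", {
  m <- single_bead(2.9)
  pa <- ccs_pa(m, n_orientations = 40, n_samples = 2e3, seed = 1)
  expect_equal(tjm_rescale(pa, scale = 1, exponent = 1)$value, pa$value)
  r <- tjm_rescale(pa, scale = 1.3)
  expect_equal(r$value, 1.3 * pa$value)
  expect_equal(r$method, "TJM-rescaled")
  expect_equal(unname(r$coefficients["scale"]), 1.3)
  expect_error(tjm_rescale(r, scale = 1.0), "PA results")
  expect_error(tjm_rescale(pa), "coefficients")
})
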