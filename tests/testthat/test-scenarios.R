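test_that("noisy homogeneous IC is seeded, bounded and centred", {
  p <- generic_params()
  ss <- homogeneous_steady_state(p)
  g <- grid_1d(10000, 1)
  a <- 0.05
  ic1 <- noisy_homogeneous_ic(ss, g, noise_amplitude = a, seed = 77)
  ic2 <- noisy_homogeneous_ic(ss, g, noise_amplitude = a, seed = 77)
  expect_identical(ic1$P, ic2$P)
  expect_true(all(ic1$P >= ss[["P"]] * (1 - a) - 1e-12))
  expect_true(all(ic1$P <= ss[["P"]] * (1 + a) + 1e-12))
  # non-Pax6 species exactly at steady state
  expect_equal(unique(ic1$F), ss[["F"]])
  expect_equal(unique(ic1$B), ss[["B"]])
  # CLT bound on the uniform noise mean: 3 * a / sqrt(3 n)
  eps <- ic1$P / ss[["P"]] - 1
  expect_lt(abs(mean(eps)), 3 * a / sqrt(3 * 10000))
  expect_error(noisy_homogeneous_ic(ss, g, noise_amplitude = 0.5, seed = 1),
               "0.2")
})

test_that("pre-pattern IC grades Pax6 along the requested axis", {
  p <- generic_params()
  g <- grid_1d(50, 1)
  lin <- prepattern_ic(g, p, high_value = 2, low_value = 0.5,
                       profile = "linear", noise_amplitude = 0)
  expect_equal(lin$P[1], 0.5, tolerance = 0.04)
  expect_equal(lin$P[50], 2, tolerance = 0.04)
  stp <- prepattern_ic(g, p, high_value = 2, low_value = 0.5,
                       profile = "step", noise_amplitude = 0)
  expect_equal(sort(unique(stp$P)), c(0.5, 2))

  msk <- explant_mask(40, 20, 1)
  pre <- prepattern_ic(msk, p, high_value = 2, low_value = 0.5,
                       axis = "short", profile = "linear",
                       noise_amplitude = 0)
  # polarisation vector of the generated field points along the short
  # (y) axis: angle within 5 degrees of +/- 90
  ang <- polarisation_index(pre$P, msk)$angle
  expect_lt(abs(abs(ang) - 90), 5)
})

test_that("explant masks have the requested geometry", {
  r <- 10
  circ <- explant_mask(2 * r, 2 * r, 0.25, shape = "ellipse")
  area <- sum(circ$mask) * 0.25^2
  expect_equal(area, pi * r^2, tolerance = 0.05 * pi * r^2)

  cap <- explant_mask(40, 20, 0.5, shape = "capsule")
  pa <- turingov:::principal_axes(cap, cap$dx)
  expect_equal(pa$major / pa$minor, 2, tolerance = 0.1)
  expect_equal(abs(pa$angle) %% 180, 0, tolerance = 2)
  # measured extents near the request
  expect_equal(pa$major, 40, tolerance = 1)
  expect_equal(pa$minor, 20, tolerance = 1)

  # refining the raster shrinks the area error
  a1 <- abs(sum(explant_mask(20, 20, 1, shape = "ellipse")$mask) * 1 - pi * 100)
  a2 <- abs(sum(explant_mask(20, 20, 0.25, shape = "ellipse")$mask) * 0.0625 -
              pi * 100)
  expect_lt(a2, a1)
  expect_error(explant_mask(10, 2, 1), "coarse")
  expect_error(explant_mask(10, 20, 0.5), "long_axis")
})

test_that("Shh gradients are monotone, invertible and vanish at zero peak", {
  g <- grid_1d(60, 1)
  s0 <- shh_gradient(g, peak = 0)
  expect_true(all(s0$S == 0))
  s1 <- shh_gradient(g, peak = 1, form = "linear")
  expect_true(all(diff(s1$S) <= 0))
  expect_equal(s1$S[1], 1, tolerance = 0.02)
  expect_equal(s1$S[30], 0.5, tolerance = 1 / 60 + 0.02)
  s2 <- shh_gradient(g, peak = 1, inverted = TRUE)
  expect_true(all(diff(s2$S) >= 0))
  # inverting twice restores the original
  expect_equal(shh_gradient(g, peak = 1, inverted = FALSE)$S, s1$S)
  se <- shh_gradient(g, peak = 2, form = "exponential")
  expect_equal(se$S[1] / se$S[60], exp(2), tolerance = 0.15)
  msk <- explant_mask(40, 20, 1)
  sm <- shh_gradient(msk, peak = 1, axis = "long")
  expect_true(all(sm$S >= 0))
})

test_that("scenario configs round-trip through YAML and build correctly", {
  cfg <- scenario_config(
    variant = "B",
    geometry = list(type = "grid1d", n_points = 24, dx = 1,
                    boundary = "zero_flux"),
    ic = list(type = "noisy_homogeneous", noise_amplitude = 0.05),
    seed = 42, t_end = 50, snapshot_interval = 10)
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$variant, cfg$variant)
  expect_equal(cfg2$geometry, cfg$geometry)
  expect_equal(cfg2$ic, cfg$ic)
  expect_equal(cfg2$seed, cfg$seed)

  b1 <- build_scenario(cfg)
  b2 <- build_scenario(cfg2)
  expect_identical(b1$initial, b2$initial)
  expect_s3_class(b1$geometry, "ov_grid")

  # invalid combinations are rejected
  expect_error(scenario_config(variant = "A",
    geometry = list(type = "grid1d", n_points = 10, dx = 1),
    ic = list(type = "noisy_homogeneous")), "fixed_pax6_source")
  expect_error(scenario_config(variant = "D",
    geometry = list(type = "grid1d", n_points = 10, dx = 1),
    ic = list(type = "noisy_homogeneous")), "Shh")
})

test_that("canonical configs exist, build, and carry the right structure", {
  nms <- canonical_config_names()
  expect_length(nms, 9)
  cfg <- canonical_config("modelB_denovo")
  expect_equal(cfg$variant, "B")
  expect_equal(cfg$ic$type, "noisy_homogeneous")
  expect_equal(cfg$geometry$type, "grid1d")
  expect_null(cfg$shh)

  dbl <- canonical_config("modelD_double_lof")
  expect_equal(dbl$variant, "D")
  expect_equal(dbl$lof, "double_lof")
  b <- build_scenario(dbl)
  expect_equal(b$params$beta, 0)
  expect_equal(b$params$gamma, 0)
  expect_s3_class(b$geometry, "ov_mask")

  inv <- canonical_config("modelD_shh_inverted")
  expect_true(isTRUE(inv$shh$inverted))
})
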