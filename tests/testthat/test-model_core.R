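species_names_vec <- function() c("P", "F", "T", "C", "B")

test_that("pax6 activity implements saturating inhibition by receptor signalling", {
  expect_equal(pax6_activity(1.0, 0.0, 5.0), 1.0)
  expect_equal(pax6_activity(2.0, 1.0, 1.0), 1.0)
  expect_equal(pax6_activity(1.0, 1e12, 1.0), 0.0, tolerance = 1e-9)
  # monotone: non-increasing in B, non-decreasing in P
  B <- seq(0, 5, by = 0.25)
  act <- pax6_activity(rep(1, length(B)), B, beta = 2)
  expect_true(all(diff(act) <= 0))
  P <- seq(0, 5, by = 0.25)
  act2 <- pax6_activity(P, rep(1, length(P)), beta = 2)
  expect_true(all(diff(act2) >= 0))
  expect_error(pax6_activity(1:3, 1:2, 1), "shape")
  expect_error(pax6_activity(1, 1, -0.5), "non-negative")
})

test_that("reaction rates reproduce elementary mass-action limits", {
  g <- grid_1d(4, 1)
  p0 <- decay_params()
  zero <- uniform_state(c(0, 0, 0, 0, 0), g)
  r <- reaction_rates(zero, p0, variant = "B")
  expect_true(all(abs(unlist(r)) == 0))

  # pure association: F = T = 1, k_on = 2, everything else off
  p <- model_parameters(rho_P = 0, sigma_P = 0, n_hill = 2, K_hill = 1,
                        rho_F = 0, rho_T = 0, delta_P = 0, delta_F = 0,
                        delta_T = 0, delta_C = 0, k_on = 2, k_off = 0,
                        k_b = 0, k_u = 0, R_tot = 1, beta = 0, gamma = 0,
                        D_F = 0, D_T = 0, D_C = 0)
  st <- uniform_state(c(0, 1, 1, 0, 0), g)
  r <- reaction_rates(st, p, variant = "B")
  expect_equal(unique(r$C), 2)
  expect_equal(unique(r$F), -2)
  expect_equal(unique(r$T), -2)
  expect_equal(unique(r$P), 0)
  expect_equal(unique(r$B), 0)
})

test_that("variant A freezes Pax6 and variant D with zero Shh equals variant B", {
  g <- grid_1d(6, 0.5)
  p <- generic_params()
  set.seed(42)
  st <- field_state(P = runif(6, 0.5, 2), F = runif(6, 0, 1),
                    T = runif(6, 0, 1), C = runif(6, 0, 1),
                    B = runif(6, 0, 0.9))
  rA <- reaction_rates(st, p, variant = "A")
  expect_true(all(rA$P == 0))
  rB <- reaction_rates(st, p, variant = "B")
  expect_true(any(rB$P != 0))
  # non-Pax6 rows identical between A and B
  for (nm in c("F", "T", "C", "B")) expect_equal(rA[[nm]], rB[[nm]])
  zeroS <- shh_field(rep(0, 6))
  rD <- reaction_rates(st, p, shh = zeroS, variant = "D")
  expect_identical(rD, rB)
  expect_error(reaction_rates(st, p, variant = "D"), "Shh")
})

test_that("homogeneous steady state zeroes the reaction rates", {
  p <- generic_params()
  ss <- homogeneous_steady_state(p)
  expect_lt(attr(ss, "residual"), 1e-10)
  expect_gt(ss[["P"]], 0)
  # receptor isotherm holds exactly
  expect_equal(ss[["B"]],
               p$R_tot * p$k_b * ss[["T"]] / (p$k_b * ss[["T"]] + p$k_u),
               tolerance = 1e-12)
  # all-production-off collapses to the zero state
  p0 <- decay_params()
  ss0 <- homogeneous_steady_state(p0)
  expect_equal(unname(ss0[species_names_vec()]), rep(0, 5), tolerance = 1e-12)
})

test_that("steady state agrees with an independent multiroot solve", {
  skip_if_not_installed("pracma")
  p <- generic_params()
  ss <- homogeneous_steady_state(p)
  g1 <- grid_1d(3, 1)
  fun <- function(x) {
    st <- uniform_state(x, g1)
    vapply(reaction_rates(st, p, variant = "B"), function(f) f[1], numeric(1))
  }
  alt <- pracma::fsolve(fun, x0 = unname(ss) * 1.3 + 0.01)$x
  expect_equal(as.numeric(alt), as.numeric(ss), tolerance = 1e-6)
})

test_that("loss-of-function mapping zeroes only the targeted couplings", {
  p <- generic_params()
  t1 <- apply_lof(p, "tgfb_lof")
  expect_equal(t1$beta, 0)
  expect_equal(t1$gamma, p$gamma)
  expect_equal(unclass(t1)[setdiff(names(t1), "beta")],
               unclass(p)[setdiff(names(p), "beta")])
  s1 <- apply_lof(p, "shh_lof")
  expect_equal(s1$gamma, 0)
  expect_equal(s1$beta, p$beta)
  d1 <- apply_lof(p, "double_lof")
  expect_equal(d1$beta, 0)
  expect_equal(d1$gamma, 0)
  # sequential single perturbations commute into the double
  expect_identical(apply_lof(apply_lof(p, "shh_lof"), "tgfb_lof"), d1)
  expect_error(apply_lof(p, "wnt_lof"))
})

test_that("mass-action closure conserves F+C and T+C+B without production or decay", {
  p <- model_parameters(rho_P = 0, sigma_P = 0, n_hill = 2, K_hill = 1,
                        rho_F = 0, rho_T = 0, delta_P = 0, delta_F = 0,
                        delta_T = 0, delta_C = 0, k_on = 3, k_off = 0.7,
                        k_b = 2, k_u = 0.5, R_tot = 1.2, beta = 1,
                        gamma = 0, D_F = 0, D_T = 0, D_C = 0)
  g <- grid_1d(5, 1)
  set.seed(7)
  st <- field_state(P = runif(5), F = runif(5), T = runif(5),
                    C = runif(5), B = runif(5, 0, 1.2))
  r <- reaction_rates(st, p, variant = "B")
  expect_equal(r$F + r$C, rep(0, 5), tolerance = 1e-14)
  expect_equal(r$T + r$C + r$B, rep(0, 5), tolerance = 1e-14)
})
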