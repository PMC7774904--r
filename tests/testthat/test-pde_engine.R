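test_that("1D Laplacian matches eigenfunction identities", {
  n <- 128; dx <- 0.25
  g <- grid_1d(n, dx, "periodic")
  L <- g$length
  expect_equal(laplacian_1d(rep(3.7, n), dx, "periodic"), rep(0, n))
  expect_equal(laplacian_1d(rep(-1.2, n), dx, "zero_flux"), rep(0, n))
  f <- sin(2 * pi * g$x / L)
  expect_equal(laplacian_1d(f, dx, "periodic"), -(2 * pi / L)^2 * f,
               tolerance = 1e-3)
  fc <- cos(pi * g$x / L)
  expect_equal(laplacian_1d(fc, dx, "zero_flux"), -(pi / L)^2 * fc,
               tolerance = 1e-3)
  expect_error(laplacian_1d(c(1, 2), dx, "zero_flux"), "3 points")
})

test_that("masked 2D Laplacian is conservative and matches a dense operator", {
  msk <- explant_mask(12, 9, 1, shape = "ellipse")
  m <- msk$mask
  f0 <- matrix(2.5, nrow(m), ncol(m))
  l0 <- laplacian_2d_masked(f0, 1, msk)
  expect_true(all(l0[m] == 0))
  expect_true(all(l0[!m] == 0))

  # dense operator assembled explicitly from the stencil definition
  idx <- which(m)
  nin <- length(idx)
  A <- matrix(0, nin, nin)
  pos <- match(seq_along(m), idx)
  nr <- nrow(m)
  for (a in seq_len(nin)) {
    ij <- arrayInd(idx[a], dim(m))
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- ij[1] + d[1]; jj <- ij[2] + d[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= ncol(m) && m[ii, jj]) {
        b <- pos[(jj - 1) * nr + ii]
        A[a, b] <- A[a, b] + 1
        A[a, a] <- A[a, a] - 1
      }
    }
  }
  set.seed(11)
  f <- matrix(0, nrow(m), ncol(m)); f[m] <- runif(nin)
  expect_equal(laplacian_2d_masked(f, 1, msk)[m], as.numeric(A %*% f[m]),
               tolerance = 1e-12)
  # column sums of a symmetric zero-flux operator vanish: mass conserved
  expect_equal(colSums(A), rep(0, nin), tolerance = 1e-12)
})

test_that("pure diffusion conserves mass and relaxes to the mean", {
  msk <- explant_mask(10, 6, 0.5)
  p <- model_parameters(rho_P = 0, sigma_P = 0, n_hill = 2, K_hill = 1,
                        rho_F = 0, rho_T = 0, delta_P = 0, delta_F = 0,
                        delta_T = 0, delta_C = 0, k_on = 0, k_off = 0,
                        k_b = 0, k_u = 0.1, R_tot = 1, beta = 0, gamma = 0,
                        D_F = 0.5, D_T = 0, D_C = 1)
  set.seed(3)
  blank <- matrix(0, nrow(msk$mask), ncol(msk$mask))
  Finit <- blank; Finit[msk$mask] <- runif(sum(msk$mask))
  st <- field_state(P = blank, F = Finit, T = blank, C = Finit * 2, B = blank)
  res <- integrate_model(p, st, msk, variant = "B",
                         settings = solver_settings(t_end = 200,
                                                    snapshot_interval = 50))
  fin <- final_state(res)
  m <- msk$mask
  expect_equal(sum(fin$F[m]), sum(Finit[m]), tolerance = 1e-8)
  expect_equal(sum(fin$C[m]), sum(2 * Finit[m]), tolerance = 1e-8)
  # long-time limit approaches the spatial mean
  expect_lt(diff(range(fin$F[m])), 1e-3 * mean(Finit[m]))
})

test_that("zero dynamics returns the initial state unchanged", {
  g <- grid_1d(16, 1)
  p <- model_parameters(rho_P = 0, sigma_P = 0, n_hill = 2, K_hill = 1,
                        rho_F = 0, rho_T = 0, delta_P = 0, delta_F = 0,
                        delta_T = 0, delta_C = 0, k_on = 0, k_off = 0,
                        k_b = 0, k_u = 0, R_tot = 1, beta = 0, gamma = 0,
                        D_F = 0, D_T = 0, D_C = 0)
  set.seed(5)
  st <- field_state(P = runif(16), F = runif(16), T = runif(16),
                    C = runif(16), B = runif(16))
  res <- integrate_model(p, st, g, variant = "B",
                         settings = solver_settings(t_end = 10,
                                                    snapshot_interval = 5,
                                                    integrator = "euler",
                                                    dt = 0.1))
  expect_identical(final_state(res)$P, st$P)
  expect_identical(final_state(res)$F, st$F)
})

test_that("explicit Euler rejects a time step violating the stability bound", {
  g <- grid_1d(16, 0.5)
  p <- generic_params()   # D_C = 1, bound = 0.25^2... dx^2/(4 Dmax) = 0.0625
  ss <- homogeneous_steady_state(p)
  st <- uniform_state(unname(ss), g)
  expect_error(
    integrate_model(p, st, g, variant = "B",
                    settings = solver_settings(t_end = 1,
                                               snapshot_interval = 1,
                                               integrator = "euler",
                                               dt = 0.1)),
    "stability bound")
})

test_that("lsoda and the explicit Euler oracle agree on a coarse run", {
  g <- grid_1d(32, 1)
  p <- generic_params()
  ss <- homogeneous_steady_state(p)
  set.seed(9)
  st <- noisy_homogeneous_ic(ss, g, noise_amplitude = 0.1, seed = 9)
  t_end <- 30
  res_l <- integrate_model(p, st, g, variant = "B",
                           settings = solver_settings(t_end = t_end,
                                                      snapshot_interval = t_end,
                                                      rtol = 1e-10,
                                                      atol = 1e-12))
  res_e <- integrate_model(p, st, g, variant = "B",
                           settings = solver_settings(t_end = t_end,
                                                      snapshot_interval = t_end,
                                                      integrator = "euler",
                                                      dt = 0.02))
  fl <- final_state(res_l); fe <- final_state(res_e)
  for (nm in c("P", "F", "T", "C", "B"))
    expect_equal(fe[[nm]], fl[[nm]], tolerance = 1e-4)
})

test_that("identical configuration and seed reproduce identical snapshots", {
  cfgfile <- tempfile(fileext = ".yaml")
  p <- generic_params()
  g <- grid_1d(24, 1)
  ss <- homogeneous_steady_state(p)
  run <- function() {
    st <- noisy_homogeneous_ic(ss, g, noise_amplitude = 0.05, seed = 123)
    integrate_model(p, st, g, variant = "B",
                    settings = solver_settings(t_end = 20,
                                               snapshot_interval = 5,
                                               seed = 123))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$snapshots, r2$snapshots)
})
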