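test_that("decay constants derive from the nuclide half-lives", {
  lu <- nuclide_properties("Lu177")
  ac <- nuclide_properties("Ac225")
  expect_equal(signif(lu$lambda_dec, 4), 1.197e-6)
  expect_equal(signif(ac$lambda_dec, 4), 8.087e-7)
  expect_equal(decay_constant(lu$half_life_s), lu$lambda_dec)
})

test_that("zero forcing and no-binding equilibria behave analytically", {
  vm <- tiny_map(n = 16, pixel_um = 25)
  pars <- ligand_params("Lu177")
  tg <- default_time_grid(TD = 86400, n = 15)

  # zero AIF -> identically zero fields
  z <- solve_crd(vm, aif_model(amplitudes = 0, rates = 1e-4), pars, tg)
  expect_equal(max(abs(z$Ci)), 0)
  expect_equal(max(abs(z$Cb)), 0)
  expect_equal(max(abs(z$Cint)), 0)

  # k_on = 0, lambda = 0, constant Cv = c: Ci equilibrates to c
  pars0 <- ligand_params("Lu177", k_on = 0, lambda_dec = 0)
  const_aif <- aif_model(amplitudes = 0.5, rates = 1e-12)
  tg_long <- default_time_grid(TD = 40 * 86400, n = 40)
  eq <- solve_crd(vm, const_aif, pars0, tg_long)
  expect_lt(max(abs(eq$Ci[, 40] - 0.5)) / 0.5, 1e-3)
  expect_equal(max(eq$Cb), 0)
  expect_equal(max(eq$Cint), 0)
})

test_that("single-voxel solution matches a stiff ODE oracle to 1e-4", {
  skip_if_not_installed("deSolve")
  vm <- single_voxel_map(pixel_um = 10)
  pars <- ligand_params("Lu177")
  aif <- aif_model()
  TD <- 20 * 86400
  tg <- default_time_grid(TD = TD, n = 400, t_first = 1)
  sol <- solve_crd(vm, aif, pars, tg, n_substeps = 8L)

  # oracle: the exact 3-compartment ODE with the same wall-flux rate
  # (wall conductance in series with the half-cell resistance, one face)
  h_cm <- 10 * 1e-4
  robin <- 1 / (1 / pars$L_v + h_cm / (2 * pars$D_PSMA)) / h_cm
  rhs <- function(t, y, p) {
    cv <- evaluate_aif(aif, t)
    ci <- y[1]; cb <- y[2]; cint <- y[3]
    list(c(
      robin * (cv - ci) - pars$k_on * ci * (pars$R0 - cb) +
        pars$k_off * cb - pars$lambda_dec * ci,
      pars$k_on * ci * (pars$R0 - cb) -
        (pars$k_off + pars$k_int + pars$lambda_dec) * cb,
      pars$k_int * cb * pars$FV_i / pars$FV_c -
        (pars$k_rel + pars$lambda_dec) * cint
    ))
  }
  ode <- deSolve::lsoda(c(0, 0, 0), times = tg, func = rhs, parms = NULL,
                        rtol = 1e-11, atol = 1e-18)
  # error relative to each compartment's trajectory scale, over all times
  scl <- c(max(ode[, 2]), max(ode[, 3]), max(ode[, 4]))
  err <- vapply(seq_along(tg), function(k) {
    got <- c(sol$Ci[1, k], sol$Cb[1, k], sol$Cint[1, k])
    max(abs(got - ode[k, 2:4]) / scl)
  }, numeric(1))
  expect_lt(max(err), 1e-4)
})

test_that("mass budget closes and binding saturates below R0", {
  vm <- tiny_map(n = 16, pixel_um = 25)
  pars <- ligand_params("Lu177")
  sol <- solve_crd(vm, aif_model(), pars, default_time_grid(n = 40))
  b <- sol$budget
  expect_lt(abs(b$influx_nmol - b$loss_nmol - b$residual_nmol) /
              b$influx_nmol, 0.005)
  expect_lte(max(sol$Cb), pars$R0)
})

test_that("the ROI-mean time-activity curve rises once then decays", {
  vm <- test_synth_map(0.02, seed = 6, n = 64, pixel_um = 25)
  sol <- solve_crd(vm, aif_model(), ligand_params("Lu177"),
                   default_time_grid(n = 50))
  tac <- colMeans(sol$params$FV_i * (sol$Ci + sol$Cb) +
                    sol$params$FV_c * sol$Cint)
  peak <- which.max(tac)
  expect_gt(peak, 1)
  expect_lt(peak, length(tac))
  expect_true(all(diff(tac[peak:length(tac)]) <= 1e-12))
})

test_that("halving the step changes the time-integrated activity by < 1%", {
  vm <- test_synth_map(0.03, seed = 9, n = 64, pixel_um = 25)
  pars <- ligand_params("Ac225")
  tg <- default_time_grid(TD = 10 * 86400, n = 60)
  a1 <- time_integrated_activity(solve_crd(vm, aif_model(), pars, tg))
  a2 <- time_integrated_activity(
    solve_crd(vm, aif_model(), pars, tg, n_substeps = 2L))
  expect_lt(max(abs(a1 - a2)) / max(a2), 0.01)
})

test_that("pool weighting and quadrature identities hold", {
  st <- list(Ci = matrix(1, 2, 2), Cb = matrix(0, 2, 2),
             Cint = matrix(0, 2, 2), FV_i = 0.39, FV_c = 0.61)
  expect_equal(total_label_concentration(st), matrix(0.39, 2, 2))
  st0 <- list(Ci = matrix(0, 2, 2), Cb = matrix(0, 2, 2),
              Cint = matrix(0, 2, 2), FV_i = 0.39, FV_c = 0.61)
  expect_equal(total_label_concentration(st0), matrix(0, 2, 2))
  st2 <- list(Ci = matrix(0.3, 1, 1), Cb = matrix(0.02, 1, 1),
              Cint = matrix(0.1, 1, 1), FV_i = 0.39, FV_c = 0.61)
  expect_equal(total_label_concentration(st2)[1, 1],
               0.39 * 0.32 + 0.61 * 0.1)

  # constant concentration: Atilde = lambda * N * T exactly
  vm <- single_voxel_map(pixel_um = 10)
  pars <- ligand_params("Lu177", k_on = 0)
  fake <- structure(list(
    t = seq(0, 1000, by = 100),
    Ci = matrix(1, 1, 11), Cb = matrix(0, 1, 11), Cint = matrix(0, 1, 11),
    map = vm, params = pars, op_index = 2L, dim = c(1L, 2L),
    voxel_volume_ml = 1e-9), class = "crd_solution")
  at <- time_integrated_activity(fake, TD = 1000)
  N <- 0.39 * 1e-9 * 6.02214076e14
  expect_equal(at[1, 2], pars$lambda_dec * N * 1000, tolerance = 1e-12)
  expect_equal(at[1, 1], 0)
  expect_error(time_integrated_activity(fake, TD = 2000), "beyond")

  # trapezoid vs adaptive quadrature on a sampled biexponential
  tt <- default_time_grid(TD = 1e6, n = 200, t_first = 10)
  f <- function(t) 3 * exp(-t / 5e4) + 0.5 * exp(-t / 5e5)
  w <- rltsim:::trapezoid_weights(tt)
  got <- sum(w * f(tt))
  ref <- integrate(f, 0, 1e6, rel.tol = 1e-12)$value
  expect_lt(abs(got - ref) / ref, 1e-3)
})

test_that("an imposed velocity field advects the interstitial pool", {
  vm <- vessel_map({
    m <- matrix(FALSE, 9, 33); m[, 1] <- TRUE; m
  }, 20)
  pars <- ligand_params("Lu177", k_on = 0, lambda_dec = 0)
  tg <- default_time_grid(TD = 2e4, n = 20, t_first = 10)
  vel <- list(vx = matrix(0, 9, 33), vy = matrix(1e-5, 9, 33))
  s0 <- solve_crd(vm, aif_model(), pars, tg)
  s1 <- solve_crd(vm, aif_model(), pars, tg, velocity = vel)
  m0 <- matrix(NA, 9, 33); m0[s0$op_index] <- s0$Ci[, 20]
  m1 <- matrix(NA, 9, 33); m1[s1$op_index] <- s1$Ci[, 20]
  # flow away from the vessel carries ligand deeper into the domain
  expect_gt(mean(m1[, 20:33]), mean(m0[, 20:33]))
})
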